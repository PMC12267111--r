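#!/usr/bin/env Rscript
# Relate deleterious variants to ROH context: flag each carried deleterious
# variant as inside or outside a detected tract and report the mean number
# of deleterious variants per ROH.
suppressPackageStartupMessages(library(ursaroh))

gt <- read_vcf("results/sim/cohort.vcf",
               scaffold_lengths = read_scaffold_lengths(
                 "results/sim/scaffolds.tsv"))
gt <- filter_scaffolds(filter_calls(gt), min_length_bp = 1.05e6)
variants <- read_impact_tsv("results/sim/impacts.tsv")
outgroup <- read_outgroup_tsv("results/sim/outgroup.tsv")
pol <- polarize(variants, outgroup)
pol <- pol[paste(pol$scaffold, pol$pos) %in%
             paste(gt$sites$scaffold, gt$sites$pos), ]

segs <- read.table("results/roh/segments.hom.tsv", header = TRUE)
rows <- lapply(gt$samples, function(id) {
  s <- segs[segs$IID == id, ]
  seg <- data.frame(sample = rep(id, nrow(s)), scaffold = s$CHR,
                    start_bp = s$POS1, end_bp = s$POS2,
                    length_bp = s$KB * 1000,
                    n_snps = s$NSNP, n_het = s$NHET, size_class = s$CLASS)
  seg <- seg[order(seg$scaffold, seg$start_bp), ]
  st <- classify_zygosity(gt, pol, id)
  cx <- summarize_context(intersect_variants(seg, pol), st, pol$impact, seg)
  data.frame(sample = id, n_roh = cx$n_roh,
             in_roh = cx$n_in_roh, out_roh = cx$n_out_roh,
             variants_per_roh = cx$variants_per_roh,
             in_short = cx$by_size_class["short"],
             in_medium = cx$by_size_class["medium"],
             in_long = cx$by_size_class["long"])
})
ctx <- do.call(rbind, rows)
rownames(ctx) <- NULL
write.table(ctx, "results/roh_context.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("deleterious variants by ROH context:\n")
print(ctx, row.names = FALSE, digits = 3)
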