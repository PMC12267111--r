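#!/usr/bin/env Rscript
# Assemble the per-sample wide table combining diversity, ROH burden, load
# partition, and the cohort-level historic N_E.
suppressPackageStartupMessages(library(ursaroh))

d <- read.table("results/diversity.tsv", header = TRUE)
r <- read.table("results/roh/summary.tsv", header = TRUE)
l <- read.table("results/load_summary.tsv", header = TRUE)
cx <- read.table("results/roh_context.tsv", header = TRUE)
ne <- read.table("results/demography.tsv", header = TRUE)

load_wide <- do.call(rbind, lapply(split(l, l$sample), function(s)
  data.frame(sample = s$sample[1],
             potential_load = sum(s$potential),
             realized_load = sum(s$realized))))

wide <- Reduce(function(a, b) merge(a, b, by = "sample"),
               list(d[c("sample", "snp_ho", "genome_ho")],
                    r[c("sample", "f_roh", "n_roh", "sum_kb")],
                    load_wide,
                    cx[c("sample", "variants_per_roh")]))
wide$log10_ne <- ne$log10_ne

write.table(wide, "results/combined.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("combined per-sample report:\n")
print(wide, row.names = FALSE, digits = 3)
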