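#!/usr/bin/env Rscript
# Build the synthetic study cohort: a bear-like diploid genome over six
# scaffolds with one first-cousin mating loop (expected F = 1/16) and two
# outbred relatives, plus an outgroup allele table, SnpEff-style impact
# labels, and an MSMC2-style coalescence-rate trajectory from a
# piecewise-constant demographic history.
suppressPackageStartupMessages(library(ursaroh))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

base <- first_cousin_pedigree("inbred1")
ped <- pedigree_spec(
  founders = base$founders,
  matings = rbind(base$matings,
                  data.frame(parent_a = c("inA", "g1"),
                             parent_b = c("inB", "inA"),
                             child = c("out1", "out2"))),
  focal_samples = c("inbred1", "out1", "out2"))

cfg <- sim_config(ped, n_scaffolds = 6, scaffold_length_bp = 40e6,
                  genotype_error_rate = 5e-4, missing_rate = 0.01,
                  seed = 20260405)
sim <- simulate_pedigree_genomes(cfg)

write_vcf(sim$genotypes, file.path(out, "cohort.vcf"))
write_truth_bed(sim$truth, file.path(out, "truth_tracts.bed"))
write_impact_tsv(sim$variants, file.path(out, "impacts.tsv"))
write_outgroup_tsv(sim$outgroup, file.path(out, "outgroup.tsv"))
write_scaffold_lengths(sim$scaffold_lengths, file.path(out, "scaffolds.tsv"))

# 240 Mb genome: expansion from N_E 20k (old) to 80k, then a recent crash
ne_history <- data.frame(t_start = c(0, 2e3, 2e4),
                         t_end = c(2e3, 2e4, 1e7),
                         ne = c(5e3, 8e4, 2e4))
traj <- simulate_lambda(ne_history, mu = 1e-8,
                        boundaries = round(exp(seq(log(10), log(2e5),
                                                   length.out = 29))))
write_msmc(traj, file.path(out, "lambda.final.txt"))

tf <- truth_fraction(sim$truth, sim$scaffold_lengths,
                     samples = ped$focal_samples)
cat("cohort written to", out, "\n")
cat(sprintf("  %d sites x %d samples on %d scaffolds\n",
            nrow(sim$genotypes$sites), length(ped$focal_samples),
            cfg$n_scaffolds))
cat("  truth autozygous fractions:\n")
print(round(tf, 4))
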