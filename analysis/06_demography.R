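#!/usr/bin/env Rscript
# Distill the coalescence-rate trajectory into one historic N_E: geometric
# mean of lambda over the interior time segments, converted with
# N_E = (1/lambda) / (2 mu) at mu = 1e-8.
suppressPackageStartupMessages(library(ursaroh))

traj <- parse_msmc("results/sim/lambda.final.txt")
est <- geometric_mean_ne(traj, mu = 1e-8)
write.table(est, "results/demography.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d of %d lambda entries kept\n", est$n_entries_used,
            nrow(traj)))
cat(sprintf("geometric mean lambda = %.2f -> historic N_E = %.0f (log10 = %.2f)\n",
            est$geo_mean_lambda, est$ne, est$log10_ne))
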