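# Small in-code fixtures shared across test files.

# Genotype table on one scaffold from a dosage vector (0/1/2/NA).
make_gt <- function(g, pos = NULL, scaffold = "s1", sample = "ind1",
                    scaffold_length = NULL, ref = "A", alt = "G") {
  g <- as.matrix(g)
  n <- nrow(g)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(scaffold_length))
    scaffold_length <- stats::setNames(max(pos) + 1000, scaffold)
  sites <- data.frame(scaffold = scaffold, pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n))
  samples <- if (ncol(g) == length(sample)) sample else
    paste0("ind", seq_len(ncol(g)))
  genotype_table(sites, g, samples = samples,
                 scaffold_lengths = scaffold_length)
}

# Tiny cohort config used by end-to-end tests: four unrelated couples and
# one first-cousin loop, small genome so tests stay fast.
small_cohort_config <- function(seed = 42, n_scaffolds = 4,
                                scaffold_length_bp = 10e6, ...) {
  ped <- first_cousin_pedigree("inbred1")
  extra <- data.frame(parent_a = c("inA", "g1"), parent_b = c("inB", "inA"),
                      child = c("out1", "out2"))
  ped2 <- pedigree_spec(
    founders = ped$founders,
    matings = rbind(ped$matings, extra),
    focal_samples = c("inbred1", "out1", "out2"))
  sim_config(ped2, n_scaffolds = n_scaffolds,
             scaffold_length_bp = scaffold_length_bp, seed = seed, ...)
}
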