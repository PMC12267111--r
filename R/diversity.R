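#' SNP heterozygosity of one sample
#'
#' Proportion of heterozygous calls among the species' variable sites: the
#' sites that are polymorphic across the whole cohort after filtering
#' (any heterozygote, or both homozygote classes present, among non-missing
#' calls). The sample's own missing calls are excluded from the
#' denominator.
#'
#' @param x a `genotype_table` restricted to retained, biallelic SNVs.
#' @param sample sample id.
#' @return fraction in `[0, 1]`.
#' @export
snp_heterozygosity <- function(x, sample) {
  g <- sample_calls(x, sample)
  v <- variable_sites(x)
  gv <- g[v]
  denom <- sum(!is.na(gv))
  if (denom == 0) stop("no non-missing calls at variable sites for ", sample)
  sum(gv == 1L, na.rm = TRUE) / denom
}

#' Which sites are variable across the cohort
#'
#' @param x a `genotype_table`.
#' @return logical vector over sites.
#' @export
variable_sites <- function(x) {
  g <- x$geno
  any_het <- rowSums(g == 1L, na.rm = TRUE) > 0
  any_ref <- rowSums(g == 0L, na.rm = TRUE) > 0
  any_alt <- rowSums(g == 2L, na.rm = TRUE) > 0
  any_het | (any_ref & any_alt)
}

#' Genome-wide heterozygosity of one sample
#'
#' Heterozygous calls per mapped-genome base: the count of heterozygous
#' sites divided by `mapped_length_bp`, which defaults downstream to the
#' summed length of retained scaffolds (a callable-sites total may be
#' passed instead).
#'
#' @param x a `genotype_table`.
#' @param sample sample id.
#' @param mapped_length_bp denominator in bp (> 0).
#' @return fraction in `[0, 1]`.
#' @export
genome_heterozygosity <- function(x, sample, mapped_length_bp) {
  if (mapped_length_bp <= 0) stop("mapped_length_bp must be > 0")
  g <- sample_calls(x, sample)
  sum(g == 1L, na.rm = TRUE) / mapped_length_bp
}

#' Per-sample diversity summary
#'
#' @param x a `genotype_table`.
#' @param samples sample ids (default all).
#' @param mapped_length_bp denominator for genome-wide heterozygosity;
#'   defaults to the summed retained-scaffold length.
#' @return data.frame: `sample`, `snp_ho`, `genome_ho`, `n_var_sites`,
#'   `mapped_length_bp`.
#' @export
summarize_diversity <- function(x, samples = x$samples,
                                mapped_length_bp = NULL) {
  if (is.null(mapped_length_bp)) mapped_length_bp <- retained_genome_length(x)
  nv <- sum(variable_sites(x))
  out <- lapply(samples, function(id) {
    data.frame(sample = id,
               snp_ho = snp_heterozygosity(x, id),
               genome_ho = genome_heterozygosity(x, id, mapped_length_bp),
               n_var_sites = nv,
               mapped_length_bp = mapped_length_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
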