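#' In-memory multi-sample genotype table
#'
#' The central container for diploid genotype data: a site table (scaffold,
#' 1-based position, ref and alt alleles) plus per-call genotype, quality
#' (GQ) and depth (DP) matrices with one row per site and one column per
#' sample. Genotypes are coded as the alternate-allele dosage: `0` hom-ref,
#' `1` het, `2` hom-alt, `NA` missing. All internal coordinates are 1-based
#' inclusive; BED exports convert to 0-based half-open.
#'
#' @param sites data.frame with columns `scaffold`, `pos`, `ref`, `alt`.
#'   `alt` may contain comma-separated alleles (multiallelic sites are kept
#'   and flagged; [filter_calls()] removes them).
#' @param geno integer matrix, sites x samples, values 0/1/2/NA.
#' @param samples character vector of sample ids (column order of `geno`).
#' @param gq,dp optional numeric matrices with the same shape as `geno`.
#'   When `NULL` the calls are treated as passing any GQ/DP filter.
#' @param scaffold_lengths optional named numeric vector of scaffold
#'   lengths in bp; required for genome-length denominators downstream.
#' @param sort if `TRUE` (default) sites are sorted by (scaffold, pos);
#'   if `FALSE` unsorted input is an error.
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(sites, geno, samples, gq = NULL, dp = NULL,
                           scaffold_lengths = NULL, sort = TRUE) {
  stopifnot(is.data.frame(sites),
            all(c("scaffold", "pos", "ref", "alt") %in% names(sites)))
  geno <- as.matrix(geno)
  if (nrow(sites) != nrow(geno))
    stop("site table and genotype matrix row counts differ")
  if (length(samples) != ncol(geno))
    stop("sample ids and genotype matrix column counts differ")
  sites$scaffold <- as.character(sites$scaffold)
  sites$pos <- as.integer(sites$pos)

  ord <- order(sites$scaffold, sites$pos)
  if (is.unsorted(ord)) {
    if (!sort) stop("sites are not sorted by (scaffold, pos)")
    sites <- sites[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
    if (!is.null(gq)) gq <- as.matrix(gq)[ord, , drop = FALSE]
    if (!is.null(dp)) dp <- as.matrix(dp)[ord, , drop = FALSE]
  } else {
    if (!is.null(gq)) gq <- as.matrix(gq)
    if (!is.null(dp)) dp <- as.matrix(dp)
  }
  dup <- duplicated(sites[c("scaffold", "pos")])
  if (any(dup))
    stop("duplicate positions within scaffold: e.g. ",
         sites$scaffold[dup][1], ":", sites$pos[dup][1])
  rownames(sites) <- NULL
  dimnames(geno) <- list(NULL, samples)
  if (!is.null(gq)) dimnames(gq) <- NULL
  if (!is.null(dp)) dimnames(dp) <- NULL

  structure(
    list(sites = sites, geno = geno, samples = as.character(samples),
         gq = gq, dp = dp, scaffold_lengths = scaffold_lengths),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$sites), "sites x", length(x$samples),
      "samples on", length(unique(x$sites$scaffold)), "scaffold(s)\n")
  if (!is.null(x$scaffold_lengths))
    cat("  scaffold lengths known for", length(x$scaffold_lengths),
        "scaffold(s);", format(sum(x$scaffold_lengths), big.mark = ","),
        "bp total\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(nrow(x$sites), length(x$samples))

n_sites <- function(x) nrow(x$sites)

## Keep rows of every parallel matrix in lockstep.
subset_sites <- function(x, keep) {
  x$sites <- x$sites[keep, , drop = FALSE]
  rownames(x$sites) <- NULL
  x$geno <- x$geno[keep, , drop = FALSE]
  if (!is.null(x$gq)) x$gq <- x$gq[keep, , drop = FALSE]
  if (!is.null(x$dp)) x$dp <- x$dp[keep, , drop = FALSE]
  x
}

#' Identify biallelic SNVs in a site table
#'
#' A site is a biallelic SNV when both ref and alt are single bases and the
#' alt field holds exactly one allele. Symbolic or multi-base alleles
#' (indels) and comma-separated alt fields (multiallelic) fail the test.
#'
#' @param sites data.frame with `ref` and `alt` columns.
#' @return logical vector, one element per site.
#' @export
is_biallelic_snv <- function(sites) {
  ref <- as.character(sites$ref)
  alt <- as.character(sites$alt)
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}

#' Genotype call codes for one sample
#'
#' @param x a `genotype_table`.
#' @param sample sample id.
#' @return integer vector of dosages (0/1/2/NA) along the site table.
#' @export
sample_calls <- function(x, sample) {
  stopifnot(inherits(x, "genotype_table"))
  if (!sample %in% x$samples) stop("unknown sample: ", sample)
  x$geno[, sample]
}
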