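#' Write simulator side-tables to disk
#'
#' Plain-text exports of the simulator outputs: truth tracts as BED
#' (0-based half-open, converted from the internal 1-based inclusive
#' coordinates), impact annotations and outgroup alleles as TSV, scaffold
#' lengths as a two-column TSV.
#'
#' @param truth truth-tract data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  d <- data.frame(truth$scaffold, truth$start_bp - 1L, truth$end_bp,
                  truth$sample, truth$origin_founder)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @param variants annotated-variant data.frame.
#' @export
write_impact_tsv <- function(variants, path) {
  utils::write.table(
    variants[c("scaffold", "pos", "ref", "alt", "impact",
               "functional_category")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @param outgroup outgroup allele data.frame.
#' @export
write_outgroup_tsv <- function(outgroup, path) {
  utils::write.table(outgroup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @param scaffold_lengths named vector of lengths.
#' @export
write_scaffold_lengths <- function(scaffold_lengths, path) {
  utils::write.table(
    data.frame(names(scaffold_lengths), as.integer(scaffold_lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an impact-annotation TSV
#'
#' @param path TSV with header `scaffold`, `pos`, `ref`, `alt`, `impact`
#'   (and optionally `functional_category`).
#' @return data.frame.
#' @export
read_impact_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read an outgroup-allele TSV
#'
#' @param path TSV with header `scaffold`, `pos`, `allele`.
#' @return data.frame.
#' @export
read_outgroup_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
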