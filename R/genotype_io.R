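#' Read a multi-sample VCF into a genotype table
#'
#' Parses the GT field (plus GQ and DP when present) of a VCF via
#' \pkg{vcfR}. Indels and multiallelic records are retained but flagged by
#' [is_biallelic_snv()] so that [filter_calls()] can remove them; phased and
#' unphased genotype separators are treated identically.
#'
#' @param path path to a VCF (plain text or bgzipped).
#' @param scaffold_lengths optional named vector of scaffold lengths; when
#'   absent, contig lengths are taken from `##contig` header lines if
#'   present.
#' @param sort re-sort unsorted input (`TRUE`, default) or fail (`FALSE`).
#' @return a [genotype_table()].
#' @export
read_vcf <- function(path, scaffold_lengths = NULL, sort = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  sites <- data.frame(scaffold = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  geno <- parse_gt_codes(gt_raw)
  gq <- dp <- NULL
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("GQ" %in% fmt_keys)
    gq <- suppressWarnings(apply(vcfR::extract.gt(v, "GQ"), 2, as.numeric))
  if ("DP" %in% fmt_keys)
    dp <- suppressWarnings(apply(vcfR::extract.gt(v, "DP"), 2, as.numeric))
  if (is.null(gq) || is.null(dp))
    warning("GQ and/or DP absent from FORMAT; such calls pass any GQ/DP filter")
  if (nrow(sites) == 1L) {
    geno <- matrix(geno, nrow = 1, dimnames = list(NULL, colnames(gt_raw)))
    if (!is.null(gq)) gq <- matrix(gq, nrow = 1)
    if (!is.null(dp)) dp <- matrix(dp, nrow = 1)
  }

  if (is.null(scaffold_lengths)) {
    meta <- v@meta
    ctg <- grep("^##contig=", meta, value = TRUE)
    if (length(ctg)) {
      ids <- sub('.*ID=([^,>]+).*', '\\1', ctg)
      lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', '\\1', ctg)))
      if (!anyNA(lens)) scaffold_lengths <- stats::setNames(lens, ids)
    }
  }

  genotype_table(sites, geno, samples = colnames(gt_raw),
                 gq = gq, dp = dp,
                 scaffold_lengths = scaffold_lengths, sort = sort)
}

## "0/1", "0|1", ".", "./." -> dosage codes; any non-REF index counts as alt
parse_gt_codes <- function(gt) {
  code_one <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }
  u <- unique(as.vector(gt))
  map <- vapply(u, code_one, integer(1))
  m <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  m
}

#' Write a genotype table as a multi-sample VCF
#'
#' Emits a minimal VCFv4.2 file with GT, GQ and DP per genotype and
#' `##contig` header lines when scaffold lengths are known. Round-trips
#' through [read_vcf()].
#'
#' @param x a `genotype_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ursaroh",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
             con)
  if (!is.null(x$scaffold_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(x$scaffold_lengths),
                       as.integer(x$scaffold_lengths)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", x$samples), collapse = "\t"), con)

  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$geno + 1L],
                   nrow = nrow(x$geno))
  gt_str[is.na(x$geno)] <- "./."
  gq <- if (is.null(x$gq)) matrix(99L, nrow(x$geno), ncol(x$geno)) else x$gq
  dp <- if (is.null(x$dp)) matrix(30L, nrow(x$geno), ncol(x$geno)) else x$dp
  cells <- matrix(paste(gt_str, as.integer(gq), as.integer(dp), sep = ":"),
                  nrow = nrow(x$geno))
  cells[is.na(x$geno)] <- "./.:.:."
  body <- do.call(paste, c(
    list(x$sites$scaffold, x$sites$pos, ".", x$sites$ref, x$sites$alt,
         ".", "PASS", ".", "GT:GQ:DP"),
    lapply(seq_len(ncol(cells)), function(j) cells[, j]),
    sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Apply per-call quality filters and drop non-SNV sites
#'
#' Genotype calls failing `GQ > gq_min` or the open depth interval
#' `dp_low < DP < dp_high` are set to missing (both bounds strict). Sites
#' that are indels or multiallelic are then removed entirely for all
#' samples. Calls with no GQ/DP values pass the corresponding filter.
#'
#' @param x a `genotype_table`.
#' @param gq_min genotype-quality threshold; calls must exceed it (default 20).
#' @param dp_low,dp_high open depth interval; calls must fall strictly
#'   inside (defaults 4 and 300).
#' @return the filtered `genotype_table`.
#' @export
filter_calls <- function(x, gq_min = 20, dp_low = 4, dp_high = 300) {
  stopifnot(inherits(x, "genotype_table"))
  bad <- matrix(FALSE, nrow(x$geno), ncol(x$geno))
  if (!is.null(x$gq)) bad <- bad | (!is.na(x$gq) & x$gq <= gq_min)
  if (!is.null(x$dp)) bad <- bad | (!is.na(x$dp) &
                                      (x$dp <= dp_low | x$dp >= dp_high))
  x$geno[bad] <- NA_integer_
  subset_sites(x, is_biallelic_snv(x$sites))
}

#' Restrict a genotype table to retained scaffolds
#'
#' Either keeps scaffolds at or above a minimum length or an explicit name
#' list, mirroring the two selection styles used for assemblies with and
#' without a clean autosome demarcation. The summed length of retained
#' scaffolds becomes the denominator for F_ROH and genome-wide
#' heterozygosity.
#'
#' @param x a `genotype_table` with known `scaffold_lengths`.
#' @param min_length_bp keep scaffolds with length `>= min_length_bp`.
#' @param keep explicit character vector of scaffold names (overrides
#'   `min_length_bp`).
#' @return the filtered table; `attr(, "retained_length_bp")` also recorded
#'   in `x$scaffold_lengths`.
#' @export
filter_scaffolds <- function(x, min_length_bp = NULL, keep = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(keep)) {
    if (is.null(min_length_bp))
      stop("provide min_length_bp or an explicit scaffold list")
    if (is.null(x$scaffold_lengths))
      stop("scaffold lengths unknown; cannot filter by length")
    keep <- names(x$scaffold_lengths)[x$scaffold_lengths >= min_length_bp]
  }
  if (!length(keep)) stop("no scaffolds retained")
  if (!is.null(x$scaffold_lengths))
    x$scaffold_lengths <- x$scaffold_lengths[names(x$scaffold_lengths) %in% keep]
  subset_sites(x, x$sites$scaffold %in% keep)
}

#' Total length of retained scaffolds
#'
#' @param x a `genotype_table`.
#' @return numeric, sum of scaffold lengths in bp.
#' @export
retained_genome_length <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(x$scaffold_lengths)) stop("scaffold lengths unknown")
  sum(as.numeric(x$scaffold_lengths))
}

#' Read a two-column scaffold-length table
#'
#' @param path TSV with scaffold name and length columns (no header).
#' @return named numeric vector of lengths.
#' @export
read_scaffold_lengths <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("scaffold", "length"),
                         stringsAsFactors = FALSE)
  if (any(d$length <= 0)) stop("non-positive scaffold length")
  stats::setNames(as.numeric(d$length), d$scaffold)
}
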