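#' ROH detection parameters (PLINK --homozyg semantics)
#'
#' Defaults reproduce the settings used for the bear cohorts: scanning
#' windows allowing at most 5 heterozygous and 5 missing calls, a 5%
#' window-hit threshold per SNP, final segments of at least 100 kb with at
#' most 1 heterozygote, at most 50 kb per SNP, and a maximal inter-SNP gap
#' of 500 kb. `window_snp` and `min_snp` both default to the calibrated
#' L value (see [l_parameter()]).
#'
#' @param window_snp SNPs per scanning window (the L value).
#' @param window_het max heterozygous calls per hit window.
#' @param window_missing max missing calls per hit window.
#' @param window_threshold min fraction of overlapping windows that must be
#'   hits for a SNP to pass.
#' @param min_snp min SNPs in a final segment (the L value).
#' @param min_kb min final-segment length in kb.
#' @param density_kb max kb per SNP within a segment.
#' @param gap_kb max gap between consecutive SNPs in a segment, in kb.
#' @param seg_het max heterozygous calls inside a final segment.
#' @return a `roh_params` list.
#' @export
roh_params <- function(window_snp = 63L, window_het = 5L, window_missing = 5L,
                       window_threshold = 0.05, min_snp = window_snp,
                       min_kb = 100, density_kb = 50, gap_kb = 500,
                       seg_het = 1L) {
  p <- list(window_snp = as.integer(window_snp),
            window_het = as.integer(window_het),
            window_missing = as.integer(window_missing),
            window_threshold = window_threshold,
            min_snp = as.integer(min_snp),
            min_kb = min_kb, density_kb = density_kb, gap_kb = gap_kb,
            seg_het = as.integer(seg_het))
  if (any(unlist(p[c("window_snp", "min_snp")]) < 1) ||
      any(unlist(p[c("min_kb", "density_kb", "gap_kb")]) <= 0))
    stop("ROH parameters must be positive")
  if (p$window_threshold <= 0 || p$window_threshold > 1)
    stop("window_threshold must lie in (0, 1]")
  structure(p, class = "roh_params")
}

#' Minimum-SNP calibration for ROH windows (L parameter)
#'
#' Sets the minimum number of SNPs per window and per final segment so that
#' the expected number of chance runs of homozygosity across the whole
#' dataset is bounded by `alpha`:
#' \deqn{L = \lceil \ln(\alpha / (n_s n_i)) / \ln(1 - h) \rceil}
#' where \eqn{n_s} is the number of genotyped SNPs, \eqn{n_i} the number of
#' individuals, and \eqn{h} the mean heterozygosity across SNPs.
#'
#' @param n_snps total SNPs genotyped in the species dataset.
#' @param n_individuals number of individuals genotyped.
#' @param mean_het mean heterozygosity across all SNPs (0 < h < 1).
#' @param alpha tolerated proportion of false-positive ROH (default 0.05).
#' @return positive integer L, rounded up.
#' @export
l_parameter <- function(n_snps, n_individuals, mean_het, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (mean_het <= 0 || mean_het >= 1)
    stop("mean_het must lie strictly in (0, 1)")
  L <- ceiling(log(alpha / (n_snps * n_individuals)) / log(1 - mean_het))
  as.integer(L)
}

#' Detect runs of homozygosity for one sample
#'
#' Re-implementation of PLINK's sliding-window ROH scan. Per scaffold:
#' (1) every window of `window_snp` consecutive SNPs is a *hit* when it
#' contains at most `window_het` heterozygous and `window_missing` missing
#' calls; (2) each SNP passes when the proportion of windows covering it
#' that are hits reaches `window_threshold` (SNPs near scaffold ends use
#' the number of windows actually overlapping them as denominator);
#' (3) maximal runs of passing SNPs form candidate segments; (4) candidates
#' are split wherever the gap between consecutive SNPs exceeds `gap_kb` and
#' wherever the running heterozygote count would exceed `seg_het` (so each
#' final segment carries at most `seg_het` heterozygous calls), segment
#' ends are trimmed to the outermost homozygous non-missing call, and the
#' pieces are kept only if they hold at least `min_snp` SNPs, span at least
#' `min_kb`, and average at most `density_kb` per SNP. Segment span runs
#' from first to last SNP. The het-split and end-trim mirror PLINK, whose
#' lenient window threshold otherwise lets candidate runs absorb
#' heterozygote-rich flanks that would disqualify every real segment.
#'
#' @param x a `genotype_table`.
#' @param params a [roh_params()].
#' @param sample sample id.
#' @return data.frame of segments: `sample`, `scaffold`, `start_bp`,
#'   `end_bp` (1-based inclusive), `length_bp`, `n_snps`, `n_het`,
#'   `size_class`.
#' @export
detect_roh <- function(x, params, sample) {
  stopifnot(inherits(x, "genotype_table"), inherits(params, "roh_params"))
  g_all <- sample_calls(x, sample)
  out <- lapply(split(seq_len(nrow(x$sites)), x$sites$scaffold),
                function(idx) {
                  scan_scaffold(x$sites$pos[idx], g_all[idx], params)
                })
  scafs <- rep(names(out), vapply(out, nrow, integer(1)))
  seg <- do.call(rbind, out)
  if (is.null(seg) || nrow(seg) == 0) {
    return(data.frame(sample = character(), scaffold = character(),
                      start_bp = integer(), end_bp = integer(),
                      length_bp = integer(), n_snps = integer(),
                      n_het = integer(), size_class = character(),
                      stringsAsFactors = FALSE))
  }
  seg <- data.frame(sample = sample, scaffold = scafs, seg,
                    stringsAsFactors = FALSE)
  ## classes are only defined from the 100 kb floor up; shorter segments
  ## (possible when min_kb is set below 100) stay unclassified
  seg$size_class <- ifelse(
    seg$length_bp >= 100e3,
    vapply(pmax(seg$length_bp, 100e3), classify_length, character(1)),
    NA_character_)
  seg <- seg[order(seg$scaffold, seg$start_bp), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

## Core scan for one scaffold; vectorized with cumulative sums.
scan_scaffold <- function(pos, g, p) {
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      length_bp = integer(), n_snps = integer(),
                      n_het = integer())
  n <- length(pos)
  Lw <- p$window_snp
  if (n < Lw) return(empty)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)

  chet <- c(0L, cumsum(het))
  cmis <- c(0L, cumsum(mis))
  nw <- n - Lw + 1L
  w <- seq_len(nw)
  hit <- (chet[w + Lw] - chet[w]) <= p$window_het &
    (cmis[w + Lw] - cmis[w]) <= p$window_missing

  chit <- c(0L, cumsum(hit))
  j <- seq_len(n)
  lo <- pmax(1L, j - Lw + 1L)
  hi <- pmin(nw, j)
  pass <- (chit[hi + 1L] - chit[lo]) / (hi - lo + 1L) >= p$window_threshold

  r <- rle(pass)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  cand <- cbind(run_start[r$values], run_end[r$values])
  if (!nrow(cand)) return(empty)

  segs <- list()
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]; b <- cand[k, 2]
    ## split where inter-SNP gap exceeds the maximum
    if (b > a) {
      gaps <- which(diff(pos[a:b]) > p$gap_kb * 1000) + a - 1L
      starts <- c(a, gaps + 1L)
      ends <- c(gaps, b)
    } else {
      starts <- a; ends <- b
    }
    for (q in seq_along(starts)) {
      pieces <- split_by_het(starts[q], ends[q], het, p$seg_het)
      for (pc in pieces) {
        i0 <- trim_start(pc[1], pc[2], het, mis)
        if (is.na(i0)) next
        i1 <- trim_end(i0, pc[2], het, mis)
        ns <- i1 - i0 + 1L
        if (ns < p$min_snp) next
        len <- pos[i1] - pos[i0] + 1L
        if (len < p$min_kb * 1000) next
        if (len / ns > p$density_kb * 1000) next
        nh <- chet[i1 + 1L] - chet[i0]
        segs[[length(segs) + 1L]] <- c(pos[i0], pos[i1], len, ns, nh)
      }
    }
  }
  if (!length(segs)) return(empty)
  m <- do.call(rbind, segs)
  data.frame(start_bp = m[, 1], end_bp = m[, 2], length_bp = m[, 3],
             n_snps = m[, 4], n_het = m[, 5])
}

## Greedy left-to-right split of SNP run [a, b] so that no piece carries
## more than max_het heterozygous calls; the het that would overflow a
## piece is dropped between pieces.
split_by_het <- function(a, b, het, max_het) {
  pieces <- list()
  cur <- a
  count <- 0L
  for (j in a:b) {
    if (het[j]) {
      count <- count + 1L
      if (count > max_het) {
        if (cur <= j - 1L) pieces[[length(pieces) + 1L]] <- c(cur, j - 1L)
        cur <- j + 1L
        count <- 0L
      }
    }
  }
  if (cur <= b) pieces[[length(pieces) + 1L]] <- c(cur, b)
  pieces
}

## Trim segment ends inward to the outermost homozygous non-missing call.
trim_start <- function(i0, i1, het, mis) {
  while (i0 <= i1 && (het[i0] || mis[i0])) i0 <- i0 + 1L
  if (i0 > i1) NA_integer_ else i0
}
trim_end <- function(i0, i1, het, mis) {
  while (i1 >= i0 && (het[i1] || mis[i1])) i1 <- i1 - 1L
  i1
}

#' Assign an ROH length class
#'
#' Short `[100, 400)` kb, medium `[400, 800)` kb, long `[800, Inf)` kb.
#' Lengths below the 100 kb detection floor are an error.
#'
#' @param length_bp segment length in bp.
#' @return `"short"`, `"medium"` or `"long"`.
#' @export
classify_length <- function(length_bp) {
  if (length_bp < 100e3)
    stop("segment below the 100 kb detection floor: ", length_bp, " bp")
  if (length_bp < 400e3) "short" else if (length_bp < 800e3) "medium" else "long"
}

#' Per-sample ROH summary statistics
#'
#' @param segments ROH data.frame from [detect_roh()] for one sample.
#' @param retained_genome_length_bp denominator for F_ROH: summed length of
#'   the retained scaffolds.
#' @return one-row data.frame: `sample`, `f_roh`, `n_roh`, `sum_kb`,
#'   `mean_kb`, `n_short`, `n_medium`, `n_long`.
#' @export
summarize_roh <- function(segments, retained_genome_length_bp) {
  if (retained_genome_length_bp <= 0) stop("retained genome length must be > 0")
  id <- if (nrow(segments)) unique(segments$sample) else NA_character_
  if (length(id) > 1) stop("segments from more than one sample")
  ## detector contract: non-overlapping within scaffold
  for (sc in unique(segments$scaffold)) {
    s <- segments[segments$scaffold == sc, , drop = FALSE]
    s <- s[order(s$start_bp), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start_bp[-1] <= s$end_bp[-nrow(s)]))
      stop("overlapping ROH segments on ", sc)
  }
  total_bp <- sum(as.numeric(segments$length_bp))
  n <- nrow(segments)
  cls <- table(factor(segments$size_class,
                      levels = c("short", "medium", "long")))
  data.frame(sample = id,
             f_roh = total_bp / retained_genome_length_bp,
             n_roh = n,
             sum_kb = total_bp / 1000,
             mean_kb = if (n > 0) total_bp / 1000 / n else 0,
             n_short = as.integer(cls["short"]),
             n_medium = as.integer(cls["medium"]),
             n_long = as.integer(cls["long"]),
             stringsAsFactors = FALSE)
}

#' Percentage of ROH tracts per length class
#'
#' @param class_counts named (or ordered short/medium/long) integer vector
#'   of tract counts per class.
#' @param digits rounding for the percentages (default 2, matching how such
#'   tables are usually reported).
#' @return named numeric vector of percentages summing to ~100.
#' @export
class_percentages <- function(class_counts, digits = 2) {
  stopifnot(length(class_counts) == 3)
  if (is.null(names(class_counts)))
    names(class_counts) <- c("short", "medium", "long")
  round(100 * class_counts / sum(class_counts), digits)
}

#' Export ROH segments as a PLINK .hom-style table or BED
#'
#' @param segments ROH data.frame.
#' @param path output path.
#' @param format `"hom"` (1-based TSV with summary columns) or `"bed"`
#'   (0-based half-open).
#' @return `path`, invisibly.
#' @export
write_roh <- function(segments, path, format = c("hom", "bed")) {
  format <- match.arg(format)
  if (format == "hom") {
    d <- data.frame(FID = segments$sample, IID = segments$sample,
                    CHR = segments$scaffold,
                    POS1 = segments$start_bp, POS2 = segments$end_bp,
                    KB = segments$length_bp / 1000, NSNP = segments$n_snps,
                    NHET = segments$n_het, CLASS = segments$size_class)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    d <- data.frame(segments$scaffold, segments$start_bp - 1L,
                    segments$end_bp, segments$sample)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
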