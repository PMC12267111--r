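#' Flag variants inside or outside ROH segments
#'
#' A variant is `in_roh` when its position falls within a segment span on
#' the same scaffold, endpoints inclusive (1-based coordinates). Implemented
#' as a sorted sweep with `findInterval`, equivalent to an interval-tree
#' lookup; segments must be non-overlapping and sorted per scaffold.
#'
#' @param segments ROH data.frame for one sample ([detect_roh()] output).
#' @param variants data.frame with `scaffold` and `pos` columns.
#' @return logical vector along `variants`: `TRUE` = inside an ROH. The
#'   index of the covering segment row is attached as
#'   `attr(, "segment_index")` (NA outside).
#' @export
intersect_variants <- function(segments, variants) {
  flag <- logical(nrow(variants))
  segidx <- rep(NA_integer_, nrow(variants))
  for (sc in unique(variants$scaffold)) {
    rows <- which(segments$scaffold == sc)
    if (!length(rows)) next
    s <- segments[rows, , drop = FALSE]
    if (is.unsorted(s$start_bp, strictly = TRUE) ||
        (nrow(s) > 1 && any(s$start_bp[-1] <= s$end_bp[-nrow(s)])))
      stop("segments unsorted or overlapping on ", sc)
    vi <- which(variants$scaffold == sc)
    k <- findInterval(variants$pos[vi], s$start_bp)
    inside <- k >= 1 & variants$pos[vi] <= s$end_bp[pmax(k, 1L)]
    flag[vi] <- inside
    segidx[vi[inside]] <- rows[k[inside]]
  }
  attr(flag, "segment_index") <- segidx
  flag
}

#' Stratify load by ROH context
#'
#' Cross-tabulates a sample's carried deleterious variants by impact class,
#' zygosity, and whether they lie inside a detected ROH tract, and reports
#' the mean number of carried deleterious variants per ROH tract plus
#' counts by ROH size class.
#'
#' @param flags logical in/out vector from [intersect_variants()].
#' @param states zygosity factor from [classify_zygosity()], aligned with
#'   `flags`.
#' @param impacts impact classes aligned with `flags`.
#' @param segments the ROH segments the flags were computed against.
#' @param impact_levels impact classes to tabulate (default deleterious).
#' @return list with `counts` (impact x zygosity x context data.frame),
#'   `variants_per_roh`, `n_roh`, and `by_size_class` (deleterious carried
#'   variants inside short/medium/long tracts).
#' @export
summarize_context <- function(flags, states, impacts, segments,
                              impact_levels = deleterious_impacts()) {
  stopifnot(length(flags) == length(states),
            length(flags) == length(impacts))
  carried <- states %in% c("potential", "realized")
  deleterious <- impacts %in% impact_levels
  imp <- factor(impacts, levels = impact_levels)
  ctx <- factor(ifelse(flags, "in_roh", "out_roh"),
                levels = c("in_roh", "out_roh"))
  sel <- carried & deleterious
  tab <- table(impact = imp[sel], state = droplevels(states[sel]),
               context = ctx[sel])
  counts <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(counts) <- c("impact", "state", "context", "count")

  n_roh <- nrow(segments)
  n_in <- sum(sel & flags)
  segidx <- attr(flags, "segment_index")
  by_class <- if (n_roh > 0 && !is.null(segidx)) {
    cls <- factor(segments$size_class[segidx[sel & flags]],
                  levels = c("short", "medium", "long"))
    as.integer(table(cls))
  } else c(0L, 0L, 0L)
  list(counts = counts,
       variants_per_roh = if (n_roh > 0) n_in / n_roh else 0,
       n_roh = n_roh,
       n_in_roh = n_in,
       n_out_roh = sum(sel & !flags),
       by_size_class = stats::setNames(by_class,
                                       c("short", "medium", "long")))
}

#' Convert 1-based inclusive intervals to BED and back
#'
#' Internal coordinates are 1-based inclusive (VCF convention); BED is
#' 0-based half-open. `to_bed` subtracts 1 from starts; `from_bed` adds it
#' back.
#'
#' @param d data.frame with `start`/`end` (or `start_bp`/`end_bp`) columns.
#' @return the data.frame with converted coordinates.
#' @export
to_bed <- function(d) {
  sc <- intersect(c("start", "start_bp"), names(d))[1]
  d[[sc]] <- d[[sc]] - 1L
  d
}

#' @rdname to_bed
#' @export
from_bed <- function(d) {
  sc <- intersect(c("start", "start_bp"), names(d))[1]
  d[[sc]] <- d[[sc]] + 1L
  d
}
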