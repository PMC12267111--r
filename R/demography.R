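#' Read an MSMC2/PSMC' final output file
#'
#' Expects the MSMC2 final-output dialect: a header line then whitespace-
#' separated columns `time_index`, `left_time_boundary`,
#' `right_time_boundary`, `lambda`.
#'
#' @param path file path.
#' @return a `lambda_trajectory` data.frame.
#' @export
parse_msmc <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  need <- c("time_index", "left_time_boundary", "right_time_boundary",
            "lambda")
  if (!all(need %in% names(d)))
    stop("not an MSMC2 final output file (missing columns): ", path)
  if (nrow(d) == 0) stop("trajectory file has no entries: ", path)
  if (is.unsorted(d$left_time_boundary) ||
      is.unsorted(d$right_time_boundary) ||
      any(d$right_time_boundary < d$left_time_boundary))
    stop("non-monotone time boundaries in ", path)
  if (any(d$lambda <= 0)) stop("non-positive lambda in ", path)
  d <- d[need]
  class(d) <- c("lambda_trajectory", "data.frame")
  d
}

#' Write a lambda trajectory in MSMC2 final-output format
#'
#' @param traj a `lambda_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msmc <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Historic effective population size from a lambda trajectory
#'
#' Distills a coalescence-rate trajectory to one number: the unweighted
#' geometric mean of lambda over the retained entries, converted to
#' N_E = (1 / lambda) / (2 mu). The first and last output intervals —
#' which correspond to the leading `1*2` and trailing `1*3` groups of the
#' default MSMC2 time-segment pattern `1*2+25*1+1*2+1*3` and are the least
#' reliably estimated — are excluded by default.
#'
#' @param traj a `lambda_trajectory`.
#' @param mu per-site per-generation mutation rate (default 1e-8).
#' @param drop_first,drop_last number of leading/trailing entries to
#'   exclude (defaults 1 and 1).
#' @return data.frame: `geo_mean_lambda`, `ne`, `log10_ne`,
#'   `n_entries_used`.
#' @export
geometric_mean_ne <- function(traj, mu = 1e-8, drop_first = 1L,
                              drop_last = 1L) {
  n <- nrow(traj)
  keep <- seq_len(n)
  if (drop_first > 0) keep <- keep[-seq_len(min(drop_first, length(keep)))]
  if (drop_last > 0 && length(keep))
    keep <- keep[seq_len(max(0L, length(keep) - drop_last))]
  if (!length(keep)) stop("no lambda entries left after dropping ends")
  lam <- traj$lambda[keep]
  geo <- exp(mean(log(lam)))
  ne <- (1 / geo) / (2 * mu)
  data.frame(geo_mean_lambda = geo, ne = ne, log10_ne = log10(ne),
             n_entries_used = length(keep))
}
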