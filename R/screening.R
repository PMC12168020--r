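# Screening statistics: normalized betanin absorbance (A535/OD600), percent
# change versus a control, and the maximum specific growth rate estimated
# from OD time courses by a sliding log-linear window.

#' Normalized betanin absorbance
#'
#' nAb = A535 / OD600: absorbance of the red pigment normalized by culture
#' density, the production proxy used for colony screening.  Vectorized.
#'
#' @param a535 betanin absorbance at 535 nm.
#' @param od600 culture optical density at 600 nm; must be > 0.
#' @return a535 / od600.
#' @export
normalized_betanin <- function(a535, od600) {
  stopifnot(is.numeric(a535), is.numeric(od600),
            all(is.finite(a535)), all(is.finite(od600)))
  if (any(od600 <= 0)) stop("od600 must be > 0 for normalization", call. = FALSE)
  if (any(a535 < 0)) warning("negative a535 value(s); returned as-is",
                             call. = FALSE)
  a535 / od600
}

#' Percent change of a sample statistic versus a control
#'
#' @param sample_nab sample value(s).
#' @param control_nab control value; must be > 0.
#' @return 100 * (sample - control) / control.
#' @export
percent_change <- function(sample_nab, control_nab) {
  if (any(control_nab <= 0)) stop("control must be > 0", call. = FALSE)
  100 * (sample_nab - control_nab) / control_nab
}

#' Maximum specific growth rate from an OD time course
#'
#' Slides a window of \code{window} consecutive points (restricted to OD
#' values above \code{od_floor}) over the curve and takes the maximum
#' least-squares slope of ln(OD) versus time -- the standard µmax
#' estimator for batch growth curves.
#'
#' @param times hours, strictly increasing.
#' @param od OD values aligned with \code{times}, >= 0.
#' @param window number of points per regression window (default 5).
#' @param od_floor exclude points at or below this OD (e.g. 3x the blank
#'   standard deviation); default 0.
#' @return µmax in 1/h.
#' @export
max_growth_rate <- function(times, od, window = 5L, od_floor = 0) {
  stopifnot(length(times) == length(od), all(diff(times) > 0), all(od >= 0))
  keep <- od > od_floor
  t <- times[keep]; y <- log(od[keep])
  n <- length(t)
  if (n < window) {
    stop("fewer than ", window, " points above the OD floor", call. = FALSE)
  }
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    tt <- t[idx]; yy <- y[idx]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  max(slopes)
}

#' Rank screened strains by improvement over the control
#'
#' @param table data.frame with columns \code{strain_id}, \code{nab},
#'   \code{percent_change}.
#' @return the same rows sorted by percent_change descending (ties broken
#'   by strain_id, lexicographic), with an added logical \code{improved}
#'   column; if no strain improves, attribute \code{"no_improvement"} is
#'   set to TRUE.
#' @export
rank_hits <- function(table) {
  stopifnot(nrow(table) > 0L,
            all(c("strain_id", "percent_change") %in% names(table)))
  out <- table[order(-table$percent_change, table$strain_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$improved <- out$percent_change > 0
  rownames(out) <- NULL
  if (!any(out$improved)) attr(out, "no_improvement") <- TRUE
  out
}
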