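#' Two-channel p53/Mdm2 time series
#'
#' Container for uniformly sampled single-cell p53 and Mdm2 levels (e.g.
#' nuclear fluorescence quantifications), with an optional ATM channel.
#' ATM defaults to a constant 1: under normal conditions ATM is low and
#' constant, and the suppression weight then absorbs its scale.
#'
#' @param p53 non-negative numeric vector of p53 levels per frame.
#' @param mdm2 non-negative numeric vector of Mdm2 levels, same length.
#' @param sampling_period frame interval in hours (default 0.11 hr).
#' @param atm optional ATM channel (scalar or vector); default constant 1.
#' @return An object of class `"p53_timeseries"`: a data.frame with columns
#'   `time_hr`, `p53`, `mdm2`, `atm` and attribute `sampling_period`.
#' @export
p53_timeseries <- function(p53, mdm2, sampling_period = 0.11, atm = 1) {
  n <- length(p53)
  if (length(mdm2) != n) stop("p53 and mdm2 must have equal length", call. = FALSE)
  if (n < 3) stop("time series must have at least 3 frames", call. = FALSE)
  if (sampling_period <= 0) stop("sampling_period must be positive", call. = FALSE)
  if (any(!is.finite(p53)) || any(!is.finite(mdm2)))
    stop("channels must be finite", call. = FALSE)
  if (any(p53 < 0) || any(mdm2 < 0))
    stop("fluorescence channels must be non-negative", call. = FALSE)
  atm <- rep_len(atm, n)
  structure(data.frame(time_hr = (seq_len(n) - 1) * sampling_period,
                       p53 = p53, mdm2 = mdm2, atm = atm),
            sampling_period = sampling_period,
            class = c("p53_timeseries", "data.frame"))
}

#' @export
print.p53_timeseries <- function(x, ...) {
  cat(sprintf("p53/Mdm2 time series: %d frames, T = %g hr (%.2f hr total)\n",
              nrow(x), attr(x, "sampling_period"),
              max(x$time_hr)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' @export
plot.p53_timeseries <- function(x, ...) {
  graphics::matplot(x$time_hr, cbind(x$p53, x$mdm2), type = "l", lty = 1,
                    col = c("forestgreen", "firebrick"),
                    xlab = "time (hr)", ylab = "level (a.u.)", ...)
  graphics::legend("topright", c("p53", "Mdm2"), lty = 1,
                   col = c("forestgreen", "firebrick"), bty = "n")
  invisible(x)
}

#' Read / write a two-channel time series as CSV
#'
#' The on-disk format has columns `time_hr, p53, mdm2` and optionally
#' `atm`. The sampling period is recovered from the time column (must be
#' uniform to within 1e-6 relative).
#'
#' @param path file path.
#' @return `read_timeseries()`: a [p53_timeseries()] object.
#' @export
read_timeseries <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_hr", "p53", "mdm2")
  if (!all(need %in% names(d)))
    stop("CSV must contain columns time_hr, p53, mdm2", call. = FALSE)
  dt <- diff(d$time_hr)
  if (any(abs(dt - dt[1]) > 1e-6 * max(abs(dt[1]), 1e-12)))
    stop("time column must be uniformly sampled", call. = FALSE)
  p53_timeseries(d$p53, d$mdm2, sampling_period = dt[1],
                 atm = if ("atm" %in% names(d)) d$atm else 1)
}

#' @rdname read_timeseries
#' @param ts a [p53_timeseries()] object.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "p53_timeseries"))
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}
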