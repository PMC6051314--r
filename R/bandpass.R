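# Band-pass preprocessing of component time courses.

#' Band-pass filter specification
#'
#' A Butterworth band-pass for component time courses. The band must lie
#' strictly inside (0, Nyquist) where Nyquist = 1/(2 * tr_seconds).
#'
#' @param low_hz lower passband edge in Hz (default 0.01).
#' @param high_hz upper passband edge in Hz (default 0.15).
#' @param order design order of the band-pass prototype (default 5).
#' @param tr_seconds sampling interval in seconds.
#' @param pad_len odd-symmetric extension length at each end, in samples;
#'   default `3 * (2 * order + 1)`, enough to absorb the start-up transient
#'   on short series.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.01, high_hz = 0.15, order = 5,
                        tr_seconds = 2, pad_len = NULL) {
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf(
      "infeasible band: need 0 < low (%.4g) < high (%.4g) < Nyquist (%.4g Hz)",
      low_hz, high_hz, nyq))
  if (is.null(pad_len)) pad_len <- 3L * (2L * order + 1L)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 tr_seconds = tr_seconds, pad_len = as.integer(pad_len)),
            class = "filter_spec")
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Filters each column independently with a Butterworth band-pass of the
#' given design order, applied forward and backward (zero phase, squared
#' magnitude response). Each series is extended at both ends by an
#' odd-symmetric reflection of `pad_len` samples before filtering to
#' suppress edge transients, then trimmed back. Columns are demeaned first:
#' the mean carries no passband information and removing it exactly, rather
#' than through the filter's finite stopband attenuation, avoids slow DC
#' edge transients on short series.
#'
#' @param timecourses T x R numeric matrix (a plain vector is treated as one
#'   column).
#' @param spec a [filter_spec()].
#' @return filtered matrix of the same shape.
#' @export
bandpass <- function(timecourses, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  vec_in <- is.null(dim(timecourses))
  x <- as.matrix(timecourses)
  if (!all(is.finite(x))) stop("non-finite values in time courses")
  n <- nrow(x)
  if (n <= 3 * spec$order)
    stop("series too short to filter: need T > 3 * order")
  nyq <- 1 / (2 * spec$tr_seconds)
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  pad <- min(spec$pad_len, n - 1L)
  x <- sweep(x, 2, colMeans(x))
  out <- apply(x, 2, filtfilt_odd, b = bf$b, a = bf$a, pad = pad)
  out <- matrix(out, nrow = n, dimnames = dimnames(x))
  if (vec_in) drop(out) else out
}

# Forward-backward IIR filtering with odd-symmetric end extension.
filtfilt_odd <- function(x, b, a, pad) {
  n <- length(x)
  front <- 2 * x[1] - x[seq(pad + 1, 2)]
  back <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xe <- c(front, x, back)
  y <- signal::filter(b, a, xe)
  y <- rev(as.numeric(signal::filter(b, a, rev(as.numeric(y)))))
  y[(pad + 1):(pad + n)]
}
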