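# Static and tapered sliding-window dynamic connectivity.

#' Taper specification for sliding-window connectivity
#'
#' The window taper is a rectangle of `rect_width` samples convolved with a
#' Gaussian of standard deviation `gauss_sigma` samples (truncated at
#' `gauss_truncate_sigmas` sigmas). Note the taper's full support,
#' `rect_width + 2 * ceiling(truncate * sigma)`, exceeds the nominal
#' rectangle width: at the defaults (15, 3, 3) the taper spans 33 samples,
#' which is what determines the number of windows.
#'
#' @param rect_width rectangle width in timepoints (default 15, i.e. 30 s at
#'   TR = 2 s).
#' @param gauss_sigma Gaussian standard deviation in timepoints (default 3).
#' @param gauss_truncate_sigmas kernel truncation in sigmas (default 3).
#' @return object of class `taper_spec`.
#' @export
taper_spec <- function(rect_width = 15, gauss_sigma = 3,
                       gauss_truncate_sigmas = 3) {
  stopifnot(rect_width >= 2, gauss_sigma > 0, gauss_truncate_sigmas > 0)
  structure(list(rect_width = as.integer(rect_width),
                 gauss_sigma = gauss_sigma,
                 gauss_truncate_sigmas = gauss_truncate_sigmas),
            class = "taper_spec")
}

#' Build the window taper
#'
#' Full discrete convolution of the rectangle with the truncated Gaussian
#' kernel, normalized to sum to one. The result is symmetric and unimodal
#' with a plateau.
#'
#' @param spec a [taper_spec()].
#' @return numeric weight vector of length
#'   `rect_width + 2 * ceiling(truncate * sigma)`.
#' @export
make_taper <- function(spec) {
  stopifnot(inherits(spec, "taper_spec"))
  half <- ceiling(spec$gauss_truncate_sigmas * spec$gauss_sigma)
  kern <- stats::dnorm(seq(-half, half), sd = spec$gauss_sigma)
  rect <- rep(1, spec$rect_width)
  w <- stats::convolve(rect, rev(kern), type = "open")
  w[w < max(w) * 1e-12] <- 0  # FFT convolution noise on true zeros
  nz <- range(which(w > 0))
  w <- w[nz[1]:nz[2]]  # drop zero-weight tails (only possible as sigma -> 0)
  w / sum(w)
}

#' Sliding-window start indices
#'
#' Stride-1 placement of fully interior windows: starts `1 .. T - L + 1`
#' (1-based), giving `W = T - L + 1` windows.
#'
#' @param n_timepoints series length T.
#' @param taper_length full taper length L.
#' @return integer vector of start indices.
#' @export
sliding_window_starts <- function(n_timepoints, taper_length) {
  if (n_timepoints < taper_length)
    stop(sprintf("series length %d shorter than taper length %d",
                 n_timepoints, taper_length))
  seq_len(n_timepoints - taper_length + 1L)
}

#' Weighted Pearson correlation of a window segment
#'
#' Pairwise Pearson correlations using weighted means and covariances.
#' Columns with zero weighted variance yield correlation 0 (with a warning)
#' so downstream matrices stay finite; values are clipped to `[-1, 1]` only
#' to absorb floating-point overshoot.
#'
#' @param segment L x R numeric matrix.
#' @param weights nonnegative weight vector of length L summing to 1.
#' @return connectivity vector of length R(R-1)/2 in [pair_index()] order.
#' @export
weighted_correlation <- function(segment, weights) {
  x <- as.matrix(segment)
  if (!all(is.finite(x))) stop("non-finite values in segment")
  stopifnot(length(weights) == nrow(x), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  mu <- colSums(x * weights)
  xc <- sweep(x, 2, mu)
  cov <- crossprod(xc * weights, xc)
  v <- diag(cov)
  bad <- v <= .Machine$double.eps * max(v, 1)
  if (any(bad)) {
    warning(sprintf("%d zero-variance column(s) in window; correlations set to 0",
                    sum(bad)))
    v[bad] <- 1
  }
  d <- 1 / sqrt(v)
  cm <- cov * tcrossprod(d)
  if (any(bad)) { cm[bad, ] <- 0; cm[, bad] <- 0 }
  diag(cm) <- 1
  over <- max(abs(cm)) - 1
  if (over > 1e-10) stop("correlation overshoot beyond rounding tolerance")
  cm <- pmin(pmax(cm, -1), 1)
  vectorize_conn(cm)
}

#' Sliding-window dynamic connectivity for one subject
#'
#' Applies [weighted_correlation()] with the taper at every stride-1 start
#' index, producing the subject's W x P windowed-connectivity stack.
#'
#' @param timecourses filtered T x R matrix.
#' @param spec a [taper_spec()].
#' @param subject_id identifier carried through to the result.
#' @return object of class `windowed_connectivity`: list with `subject_id`,
#'   `window_starts`, `vectors` (W x P), and `pair_index`.
#' @export
compute_dfnc <- function(timecourses, spec = taper_spec(),
                         subject_id = NA_character_) {
  x <- as.matrix(timecourses)
  w <- make_taper(spec)
  l <- length(w)
  starts <- sliding_window_starts(nrow(x), l)
  p <- pair_index(ncol(x))
  vecs <- matrix(NA_real_, length(starts), nrow(p))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + l - 1L), , drop = FALSE]
    vecs[k, ] <- weighted_correlation(seg, w)
  }
  cn <- colnames(x)
  if (!is.null(cn)) colnames(vecs) <- pair_labels(cn)
  structure(list(subject_id = subject_id, window_starts = starts,
                 vectors = vecs, pair_index = p, taper = w),
            class = "windowed_connectivity")
}

#' Static functional network connectivity for one subject
#'
#' Plain Pearson correlation over the full (filtered) series, vectorized in
#' the same pair order as the windowed connectivity.
#'
#' @param timecourses filtered T x R matrix.
#' @return connectivity vector of length R(R-1)/2.
#' @export
compute_sfnc <- function(timecourses) {
  x <- as.matrix(timecourses)
  n <- nrow(x)
  weighted_correlation(x, rep(1 / n, n))
}
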