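#' Pair index for vectorized connectivity
#'
#' Connectivity matrices are stored as vectors over the upper triangle in
#' row-major order: (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R). For
#' R components this yields P = R(R-1)/2 pairs (1128 for R = 48).
#'
#' @param n_components number of components R (>= 2).
#' @return integer matrix with P rows and columns `i`, `j` (i < j).
#' @export
pair_index <- function(n_components) {
  if (n_components < 2) stop("pair_index() needs at least 2 components")
  p <- t(utils::combn(n_components, 2L))
  colnames(p) <- c("i", "j")
  p
}

#' Labels of the form "compI_compJ" for each pair, given component names.
#' @param comp_names character vector of component names.
#' @return character vector of length R(R-1)/2.
#' @export
pair_labels <- function(comp_names) {
  p <- pair_index(length(comp_names))
  paste(comp_names[p[, "i"]], comp_names[p[, "j"]], sep = "_")
}

#' Vectorize a symmetric connectivity matrix
#'
#' @param m symmetric matrix with unit diagonal.
#' @return numeric vector of the upper triangle in [pair_index()] order.
#' @export
vectorize_conn <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  p <- pair_index(nrow(m))
  m[p]
}

#' Rebuild a symmetric unit-diagonal matrix from a connectivity vector
#'
#' Inverse of [vectorize_conn()].
#' @param v connectivity vector of length R(R-1)/2.
#' @param diag_value value to place on the diagonal (default 1).
#' @return symmetric matrix.
#' @export
devectorize_conn <- function(v, diag_value = 1) {
  pl <- length(v)
  r <- (1 + sqrt(1 + 8 * pl)) / 2
  if (abs(r - round(r)) > 1e-8)
    stop("length ", pl, " is not R(R-1)/2 for any integer R")
  r <- as.integer(round(r))
  p <- pair_index(r)
  m <- diag(diag_value, r)
  m[p] <- v
  m[p[, c(2, 1), drop = FALSE]] <- v
  m
}
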