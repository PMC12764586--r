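#' Plan the sub-matrix partition of a contact map
#'
#' Large chromosomes are processed in sub-matrices of at most `t` bins.
#' The number of windows is `ns = ceiling(n_bins / t)` and the core size is
#' `p = ceiling(n_bins / ns)`; cores tile `[0, n_bins)` disjointly, with the
#' last core absorbing the remainder. Every window after the first is
#' extended left (and, by symmetry of the matrix, up) by `q_bp` worth of bins
#' borrowed from the previous window so that domains straddling a core
#' boundary are still seen whole by one window.
#'
#' @param n_bins total number of bins on the chromosome.
#' @param resolution bin width in bp.
#' @param t maximum core size in bins (default 5000).
#' @param q_bp overlap extension in bp (default 3 Mb).
#' @return a `PartitionPlan`: list with `n_bins`, `t`, `ns`, `p`, `q_bp`,
#'   `q_bins` and a data.frame `windows` of per-window bin ranges
#'   (`index`, `core_start_bin`, `core_end_bin`, `ext_start_bin`), all
#'   half-open, 0-based.
#' @export
plan_partition <- function(n_bins, resolution, t = 5000L, q_bp = 3e6) {
  stopifnot(n_bins >= 1, t >= 2, q_bp >= 0, resolution > 0)
  ns <- ceiling(n_bins / t)
  p <- ceiling(n_bins / ns)
  q_bins <- as.integer(ceiling(q_bp / resolution))
  core_start <- (seq_len(ns) - 1L) * p
  core_end <- pmin(core_start + p, n_bins)
  ext_start <- pmax(core_start - q_bins, 0L)
  ext_start[1] <- core_start[1]
  windows <- data.frame(
    index = seq_len(ns) - 1L,
    core_start_bin = as.integer(core_start),
    core_end_bin = as.integer(core_end),
    ext_start_bin = as.integer(ext_start)
  )
  structure(
    list(n_bins = as.integer(n_bins), t = as.integer(t), ns = as.integer(ns),
         p = as.integer(p), q_bp = q_bp, q_bins = q_bins, windows = windows),
    class = "PartitionPlan"
  )
}

#' @export
print.PartitionPlan <- function(x, ...) {
  cat(sprintf("PartitionPlan: %d bins -> %d window(s) of core %d bins, overlap %d bins\n",
              x$n_bins, x$ns, x$p, x$q_bins))
  print(x$windows, row.names = FALSE)
  invisible(x)
}

#' Extract the extended sub-matrix of a window
#'
#' Returns the symmetric principal block over bins
#' `[ext_start_bin, core_end_bin)` of the window (rows and columns alike:
#' the matrix is symmetric, so the top and left extensions coincide with the
#' square block).
#'
#' @param cm a [contact_matrix()].
#' @param window one row of a [plan_partition()] `windows` table (list or
#'   single-row data.frame with `ext_start_bin` and `core_end_bin`).
#' @return a square numeric matrix.
#' @export
extract_submatrix <- function(cm, window) {
  a <- window$ext_start_bin; b <- window$core_end_bin
  if (a < 0 || b > cm$n_bins || a >= b) {
    stop("window [", a, ",", b, ") out of range for ", cm$n_bins, " bins")
  }
  cm$values[(a + 1L):b, (a + 1L):b, drop = FALSE]
}

reflect_index <- function(i, m) {
  # half-sample symmetric reflection (d c b a | a b c d | d c b a)
  j <- (i - 1L) %% (2L * m)
  ifelse(j >= m, 2L * m - 1L - j, j) + 1L
}

conv1d_reflect <- function(M, w) {
  # convolve each column of M with kernel w, reflect boundary
  r <- (length(w) - 1L) %/% 2L
  m <- nrow(M)
  idx <- reflect_index(seq.int(1L - r, m + r), m)
  P <- M[idx, , drop = FALSE]
  out <- matrix(0, m, ncol(M))
  for (k in seq_along(w)) {
    out <- out + w[k] * P[(k - 1L) + seq_len(m), , drop = FALSE]
  }
  out
}

#' Gaussian-smooth a (sub-)matrix
#'
#' Applies an isotropic 2-D Gaussian filter (separable convolution, kernel
#' truncated at 4 sigma, half-sample reflect boundary). Smoothing suppresses
#' speckle noise while preserving the diagonal block structure that marks
#' domains. `sigma = 0` disables smoothing.
#'
#' @param M symmetric, finite, non-negative square matrix.
#' @param sigma kernel standard deviation in bins (default 1).
#' @return the smoothed matrix; symmetric and non-negative.
#' @export
gaussian_smooth <- function(M, sigma = 1.0) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(M)
  r <- max(1L, as.integer(round(4 * sigma)))
  x <- seq.int(-r, r)
  w <- exp(-x^2 / (2 * sigma^2))
  w <- w / sum(w)
  out <- conv1d_reflect(M, w)          # columns
  out <- t(conv1d_reflect(t(out), w))  # rows
  # exact symmetry can drift at machine precision through the two passes
  (out + t(out)) / 2
}
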