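#' Separable Gaussian blur
#'
#' 2-D Gaussian smoothing by separable 1-D convolution with
#' replicate-padding at the borders; the kernel half-width is
#' `ceiling(3 * sigma)`.  Works for kernels larger than the image.
#'
#' @param m numeric matrix.
#' @param sigma Gaussian sd in pixels; `sigma <= 0` returns `m` unchanged.
#' @return smoothed matrix of the same size.
#' @export
gauss_blur <- function(m, sigma) {
  stopifnot(is.matrix(m))
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  pr <- m[c(rep(1L, r), seq_len(H), rep(H, r)), , drop = FALSE]
  out1 <- matrix(0, H, W)
  for (j in seq_len(2L * r + 1L))
    out1 <- out1 + k[j] * pr[j:(j + H - 1L), , drop = FALSE]
  pc <- out1[, c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq_len(2L * r + 1L))
    out <- out + k[j] * pc[, j:(j + W - 1L), drop = FALSE]
  out
}
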