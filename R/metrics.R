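#' Band-wise peak signal-to-noise ratio
#'
#' Per band, `PSNR_b = 10 * log10(peak^2 / MSE_b)`; the summary value is the
#' mean over bands.  A band with zero MSE yields an `Inf` sentinel and is
#' excluded from the mean (with a warning) rather than poisoning it.
#'
#' @param ref,gen [hsi_cube]s or H x W x B arrays of equal shape.
#' @param peak peak signal value; default 1 for transmittance-scaled data.
#' @return list with `mean` (dB) and `per_band` (length-B vector, dB).
#' @export
psnr_hsi <- function(ref, gen, peak = 1) {
  a <- if (is_hsi_cube(ref)) ref$values else ref
  b <- if (is_hsi_cube(gen)) gen$values else gen
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  stopifnot(peak > 0)
  B <- dim(a)[3L]
  mse <- vapply(seq_len(B),
                function(k) mean((a[, , k] - b[, , k])^2), 0)
  per <- ifelse(mse == 0, Inf, 10 * log10(peak^2 / mse))
  fin <- is.finite(per)
  if (!all(fin))
    warning(sum(!fin), " band(s) with zero MSE excluded from the mean PSNR")
  list(mean = mean(per[fin]), per_band = per)
}

#' Band-wise mean absolute error
#'
#' Per band, the mean absolute difference over all pixels; the summary value
#' is the mean over bands.  Multiply by 100 (`percent = TRUE`) to report on
#' the percent scale of transmittance.
#'
#' @param ref,gen cubes or arrays of equal shape.
#' @param percent report x100.
#' @return list with `mean` and `per_band`.
#' @export
mae_hsi <- function(ref, gen, percent = FALSE) {
  a <- if (is_hsi_cube(ref)) ref$values else ref
  b <- if (is_hsi_cube(gen)) gen$values else gen
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  B <- dim(a)[3L]
  per <- vapply(seq_len(B),
                function(k) mean(abs(a[, , k] - b[, , k])), 0)
  if (percent) per <- per * 100
  list(mean = mean(per), per_band = per)
}

#' Spectral angle mapper
#'
#' The angle between generated and reference spectra viewed as vectors,
#' reported in degrees; invariant to positive per-pixel scaling.  Two modes:
#' \describe{
#'   \item{`per_pixel_mean`}{(default) the angle is computed per pixel
#'     spectrum and averaged -- the community convention for reporting.}
#'   \item{`pooled`}{a single angle from sums pooled over all pixels,
#'     `alpha = acos( sum(t r) / (sqrt(sum t^2) sqrt(sum r^2)) )`.}
#' }
#' Pixels whose spectrum is all zero in either cube are excluded
#' (`per_pixel_mean`) or contribute zero to the pooled sums; their count is
#' attached as attribute `n_zero`.
#'
#' @param ref,gen cubes or arrays of equal shape (reference first).
#' @param mode `"per_pixel_mean"` or `"pooled"`.
#' @return angle in degrees.
#' @export
sam <- function(ref, gen, mode = c("per_pixel_mean", "pooled")) {
  mode <- match.arg(mode)
  r <- if (is_hsi_cube(ref)) ref$values else ref
  t_ <- if (is_hsi_cube(gen)) gen$values else gen
  if (!identical(dim(r), dim(t_))) stop("shape mismatch")
  d <- dim(r)
  rm_ <- matrix(r, d[1L] * d[2L], d[3L])
  tm <- matrix(t_, d[1L] * d[2L], d[3L])
  rr <- rowSums(rm_^2); tt <- rowSums(tm^2); rt <- rowSums(rm_ * tm)
  zero <- rr == 0 | tt == 0
  if (mode == "per_pixel_mean") {
    cosang <- rt[!zero] / sqrt(rr[!zero] * tt[!zero])
    cosang <- pmin(pmax(cosang, -1), 1)
    out <- mean(acos(cosang)) * 180 / pi
  } else {
    num <- sum(rt[!zero])
    den <- sqrt(sum(tt[!zero])) * sqrt(sum(rr[!zero]))
    out <- acos(min(max(num / den, -1), 1)) * 180 / pi
  }
  attr(out, "n_zero") <- sum(zero)
  out
}

ssim_constants <- function(L) {
  c(c1 = (0.01 * L)^2, c2 = (0.03 * L)^2)
}

#' Global structural similarity of two panchromatic images
#'
#' The single-statistic SSIM computed from whole-image means, standard
#' deviations and covariance:
#' \deqn{SSIM = \frac{(2\mu_G\mu_{\hat G} + c_1)(2\sigma_{G\hat G} + c_2)}
#'   {(\mu_G^2 + \mu_{\hat G}^2 + c_1)(\sigma_G^2 + \sigma_{\hat G}^2 + c_2)}}
#' with `c1 = (0.01 L)^2` and `c2 = (0.03 L)^2` for dynamic range `L`
#' (1e-4 and 9e-4 at L = 1).  This is deliberately the global form, not the
#' sliding-window index.
#'
#' @param g,ghat numeric matrices of equal shape.
#' @param L dynamic range of the values (default 1).
#' @return scalar in \[-1, 1\].
#' @export
ssim_global <- function(g, ghat, L = 1) {
  if (!identical(dim(g), dim(ghat))) stop("shape mismatch")
  stopifnot(L > 0)
  cc <- ssim_constants(L)
  n <- length(g)
  mu1 <- mean(g); mu2 <- mean(ghat)
  v1 <- sum((g - mu1)^2) / n
  v2 <- sum((ghat - mu2)^2) / n
  cv <- sum((g - mu1) * (ghat - mu2)) / n
  ((2 * mu1 * mu2 + cc["c1"]) * (2 * cv + cc["c2"])) /
    ((mu1^2 + mu2^2 + cc["c1"]) * (v1 + v2 + cc["c2"])) -> s
  unname(s)
}

#' Full reconstruction-quality report
#'
#' @param ref reference [hsi_cube] (original high-resolution cube).
#' @param gen generated [hsi_cube].
#' @param rgb_stacked optional stacked-RGB array; when given, the SSIM is
#'   computed between the panchromatic images of the stacked RGB and the
#'   generated cube (the recommended pairing when the generated cube's
#'   spatial content derives from the RGB guidance), otherwise between the
#'   panchromatic images of `ref` and `gen`.
#' @param peak PSNR peak value.
#' @param L SSIM dynamic range.
#' @return list of class `reconstruction_report`: `psnr_db`, `mae`,
#'   `mae_pct`, `sam_deg` (per-pixel mean), `sam_pooled_deg`, `ssim`, and
#'   per-band vectors.
#' @export
reconstruction_report <- function(ref, gen, rgb_stacked = NULL, peak = 1,
                                  L = 1) {
  ps <- psnr_hsi(ref, gen, peak)
  ma <- mae_hsi(ref, gen)
  gpan <- if (is.null(rgb_stacked)) panchromatic(ref)
          else panchromatic(rgb_stacked)
  s <- ssim_global(gpan, panchromatic(gen), L)
  structure(list(psnr_db = ps$mean, mae = ma$mean, mae_pct = ma$mean * 100,
                 sam_deg = as.numeric(sam(ref, gen)),
                 sam_pooled_deg = as.numeric(sam(ref, gen, "pooled")),
                 ssim = s,
                 psnr_per_band = ps$per_band, mae_per_band = ma$per_band),
            class = "reconstruction_report")
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf(
    "PSNR %.2f dB | MAE %.2f%% | SAM %.2f deg | SSIM %.3f\n",
    x$psnr_db, x$mae_pct, x$sam_deg, x$ssim))
  invisible(x)
}

#' Confusion-count classification metrics
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)` (fraction of
#' cancerous patches detected) and specificity `TN/(TN+FP)`.  A rate with a
#' zero denominator is returned as `NA` (undefined), never as 0.
#'
#' @param tp,tn,fp,fn nonnegative integer counts.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  tot <- tp + tn + fp + fn
  c(accuracy = if (tot > 0) (tp + tn) / tot else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Area under the ROC curve
#'
#' Threshold-free ranking performance of scores against binary labels;
#' computed as the trapezoidal area under the ROC curve, with ties handled
#' by rank averaging (equivalently, the normalized Mann-Whitney statistic).
#'
#' @param scores numeric vector of predicted probabilities/scores.
#' @param labels 0/1 vector (1 = positive class).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute an AUC")
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}
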