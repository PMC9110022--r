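# Feature-based affine registration: segment-test corner detection, oriented
# binary (BRIEF-style) descriptors matched by Hamming distance with a ratio
# test, and a RANSAC affine fit.  Coordinates are (x = col, y = row), 0-based.

# run `expr` under a private RNG stream so library internals (descriptor
# pattern) never perturb the caller's seed state
with_private_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

brief_pattern_cache <- new.env(parent = emptyenv())

# 256 point pairs ~ N(0, (patch/5)^2), clamped to the sampling window;
# fixed pattern, generated once under a private seed
brief_pattern <- function(n_bits = 256L, half = 12L) {
  key <- paste0(n_bits, "_", half)
  if (!is.null(brief_pattern_cache[[key]])) return(brief_pattern_cache[[key]])
  pat <- with_private_rng(761204, {
    sd <- (2 * half + 1) / 5
    clamp <- function(v) pmin(pmax(round(v), -half), half)
    list(x1 = clamp(rnorm(n_bits, 0, sd)), y1 = clamp(rnorm(n_bits, 0, sd)),
         x2 = clamp(rnorm(n_bits, 0, sd)), y2 = clamp(rnorm(n_bits, 0, sd)))
  })
  brief_pattern_cache[[key]] <- pat
  pat
}

fast_circle <- function() {
  # radius-3 Bresenham circle, 16 offsets (dy, dx), clockwise
  cbind(dy = c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3),
        dx = c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1))
}

shift_mat <- function(m, dy, dx, margin) {
  # m restricted to interior rows/cols, shifted by (dy, dx)
  H <- nrow(m); W <- ncol(m)
  m[(1 + margin + dy):(H - margin + dy),
    (1 + margin + dx):(W - margin + dx)]
}

#' Detect corner keypoints
#'
#' Segment-test detector: a pixel is a corner when at least `arc` contiguous
#' pixels on a radius-3 circle of 16 are all brighter than the centre by
#' `threshold`, or all darker.  Corner score (sum of absolute contrasts) is
#' 3 x 3 non-maximum suppressed and the strongest `n_max` corners are kept.
#' Each keypoint carries an intensity-centroid orientation.
#'
#' @param img numeric matrix (grayscale, any positive range).
#' @param threshold contrast threshold on the image's scale (default 0.04
#'   for images in \[0, 1\]).
#' @param n_max maximum number of keypoints (default 5000).
#' @param arc minimum contiguous arc length (default 9).
#' @param margin border margin in pixels within which keypoints are dropped
#'   (must cover the descriptor window).
#' @return data.frame with columns `x`, `y` (0-based), `score`, `angle`
#'   (radians).
#' @export
detect_corners <- function(img, threshold = 0.04, n_max = 5000L,
                           arc = 9L, margin = 17L) {
  stopifnot(is.matrix(img))
  H <- nrow(img); W <- ncol(img)
  if (H <= 2 * margin + 1 || W <= 2 * margin + 1)
    return(data.frame(x = numeric(0), y = numeric(0),
                      score = numeric(0), angle = numeric(0)))
  circ <- fast_circle()
  ctr <- shift_mat(img, 0L, 0L, margin)
  n <- length(ctr)
  bright <- matrix(FALSE, n, 16L); dark <- matrix(FALSE, n, 16L)
  contrast <- matrix(0, n, 16L)
  for (k in 1:16) {
    pk <- shift_mat(img, circ[k, 1L], circ[k, 2L], margin)
    bright[, k] <- pk > ctr + threshold
    dark[, k] <- pk < ctr - threshold
    contrast[, k] <- abs(pk - ctr)
  }
  run_ok <- function(b) {
    ok <- logical(n)
    for (s in 1:16) {
      idx <- ((s - 1L) + 0:(arc - 1L)) %% 16L + 1L
      cand <- b[, idx[1L]]
      for (j in idx[-1L]) cand <- cand & b[, j]
      ok <- ok | cand
    }
    ok
  }
  is_corner <- run_ok(bright) | run_ok(dark)
  if (!any(is_corner))
    return(data.frame(x = numeric(0), y = numeric(0),
                      score = numeric(0), angle = numeric(0)))
  score <- matrix(0, H - 2 * margin, W - 2 * margin)
  score[] <- rowSums(contrast) * is_corner
  # 3x3 non-maximum suppression
  mx <- score
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    sh <- matrix(0, nrow(score), ncol(score))
    ys <- max(1, 1 + dy):min(nrow(score), nrow(score) + dy)
    xs <- max(1, 1 + dx):min(ncol(score), ncol(score) + dx)
    sh[ys, xs] <- score[ys - dy, xs - dx]
    mx <- pmax(mx, sh)
  }
  keep <- which(score > 0 & score >= mx, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      score = numeric(0), angle = numeric(0)))
  sc <- score[keep]
  ord <- order(sc, decreasing = TRUE)
  if (length(ord) > n_max) ord <- ord[seq_len(n_max)]
  keep <- keep[ord, , drop = FALSE]
  row1 <- keep[, 1L] + margin   # 1-based full-image row
  col1 <- keep[, 2L] + margin
  ang <- centroid_angle(img, row1, col1, radius = 8L)
  data.frame(x = col1 - 1, y = row1 - 1, score = sc[ord], angle = ang)
}

centroid_angle <- function(img, row1, col1, radius = 8L) {
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  H <- nrow(img)
  m01 <- numeric(length(row1)); m10 <- numeric(length(row1))
  for (i in seq_len(nrow(offs))) {
    v <- img[cbind(row1 + offs$dy[i], col1 + offs$dx[i])]
    m01 <- m01 + offs$dy[i] * v
    m10 <- m10 + offs$dx[i] * v
  }
  atan2(m01, m10)
}

#' Binary descriptors at keypoints
#'
#' Oriented BRIEF-style descriptors: the image is Gaussian-smoothed, the
#' fixed 256-pair sampling pattern is rotated by each keypoint's orientation,
#' and each bit records whether the first sample is darker than the second.
#'
#' @param img numeric matrix.
#' @param kp data.frame from [detect_corners()].
#' @param blur_sigma Gaussian smoothing sd in pixels (default 2).
#' @return integer 0/1 matrix, `nrow(kp)` x 256.
#' @export
brief_descriptors <- function(img, kp, blur_sigma = 2) {
  if (nrow(kp) == 0L) return(matrix(integer(0), 0L, 256L))
  sm <- gauss_blur(img, blur_sigma)
  pat <- brief_pattern()
  H <- nrow(sm)
  n <- nrow(kp)
  desc <- matrix(0L, n, length(pat$x1))
  ca <- cos(kp$angle); sa <- sin(kp$angle)
  row1 <- kp$y + 1; col1 <- kp$x + 1
  for (b in seq_along(pat$x1)) {
    rx1 <- round(ca * pat$x1[b] - sa * pat$y1[b])
    ry1 <- round(sa * pat$x1[b] + ca * pat$y1[b])
    rx2 <- round(ca * pat$x2[b] - sa * pat$y2[b])
    ry2 <- round(sa * pat$x2[b] + ca * pat$y2[b])
    v1 <- sm[cbind(row1 + ry1, col1 + rx1)]
    v2 <- sm[cbind(row1 + ry2, col1 + rx2)]
    desc[, b] <- as.integer(v1 < v2)
  }
  desc
}

#' Match binary descriptors
#'
#' Hamming nearest neighbours with Lowe ratio test (best distance must be
#' below `ratio` times the second best).
#'
#' @param d1,d2 0/1 descriptor matrices.
#' @param ratio ratio-test threshold (default 0.75).
#' @return data.frame with `i1`, `i2`, `dist`.
#' @export
match_descriptors <- function(d1, d2, ratio = 0.75) {
  if (nrow(d1) == 0L || nrow(d2) < 2L)
    return(data.frame(i1 = integer(0), i2 = integer(0), dist = numeric(0)))
  # Hamming distance: a(1-b)' + (1-a)b'
  dist <- d1 %*% (1 - t(d2)) + (1 - d1) %*% t(d2)
  best <- max.col(-dist, ties.method = "first")
  bestd <- dist[cbind(seq_len(nrow(d1)), best)]
  dist[cbind(seq_len(nrow(d1)), best)] <- Inf
  secondd <- dist[cbind(seq_len(nrow(d1)), max.col(-dist, "first"))]
  keep <- bestd < ratio * secondd
  data.frame(i1 = which(keep), i2 = best[keep], dist = bestd[keep])
}

fit_affine_ls <- function(xy_from, xy_to) {
  # least-squares 2x3 affine mapping from -> to; xy_* are n x 2 (x, y)
  A <- cbind(xy_from, 1)
  cf <- qr.solve(A, xy_to)       # 3 x 2
  t(cf)                          # 2 x 3: rows (x', y')
}

apply_affine <- function(M, xy) {
  # M: 2 x 3; xy: n x 2 -> n x 2
  cbind(M[1, 1] * xy[, 1] + M[1, 2] * xy[, 2] + M[1, 3],
        M[2, 1] * xy[, 1] + M[2, 2] * xy[, 2] + M[2, 3])
}

invert_affine <- function(M) {
  A <- M[, 1:2]; b <- M[, 3]
  Ai <- solve(A)
  cbind(Ai, -Ai %*% b)
}

#' RANSAC affine estimation from point matches
#'
#' Repeatedly fits a 2 x 3 affine transform to random minimal samples of
#' three matches, scores by inlier count at `reproj_tol` pixels, and refits
#' on the best consensus set.
#'
#' @param xy_from,xy_to n x 2 matrices of matched (x, y) coordinates.
#' @param reproj_tol inlier reprojection tolerance in pixels (default 3).
#' @param n_iter RANSAC iterations (default 2000).
#' @param min_inliers minimum robust inlier count; fewer is a registration
#'   failure (error, never a silent identity).
#' @param seed RNG seed for the sampling.
#' @return list with `matrix` (2 x 3), `inliers` (indices), `residual`
#'   (mean inlier reprojection error, pixels).
#' @export
ransac_affine <- function(xy_from, xy_to, reproj_tol = 3, n_iter = 2000L,
                          min_inliers = 3L, seed = 1L) {
  n <- nrow(xy_from)
  if (n < 3L) stop("registration failure: fewer than 3 candidate matches")
  best_inl <- integer(0)
  with_private_rng(seed, {
    for (it in seq_len(n_iter)) {
      s <- sample.int(n, 3L)
      M <- tryCatch(fit_affine_ls(xy_from[s, , drop = FALSE],
                                  xy_to[s, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(M) || !all(is.finite(M))) next
      err <- sqrt(rowSums((apply_affine(M, xy_from) - xy_to)^2))
      inl <- which(err < reproj_tol)
      if (length(inl) > length(best_inl)) best_inl <- inl
    }
  })
  if (length(best_inl) < max(3L, min_inliers))
    stop("registration failure: only ", length(best_inl),
         " robust inlier matches")
  M <- fit_affine_ls(xy_from[best_inl, , drop = FALSE],
                     xy_to[best_inl, , drop = FALSE])
  err <- sqrt(rowSums((apply_affine(M, xy_from[best_inl, , drop = FALSE]) -
                         xy_to[best_inl, , drop = FALSE])^2))
  list(matrix = M, inliers = best_inl, residual = mean(err))
}

bilinear_sample <- function(img, x, y, fill = 1) {
  # img: matrix; x, y 0-based real coords (x = col); returns vector
  H <- nrow(img); W <- ncol(img)
  ok <- x >= 0 & y >= 0 & x <= W - 1 & y <= H - 1
  # clamp indices for the gather; invalid lanes overwritten by fill.
  # interior cell indices are capped at W-2/H-2 so the exact right/bottom
  # border interpolates with weight 1 on the border sample
  xc <- pmin(pmax(floor(x), 0), W - 2); yc <- pmin(pmax(floor(y), 0), H - 2)
  fx <- x - xc; fy <- y - yc
  i00 <- cbind(yc + 1, xc + 1); i01 <- cbind(yc + 1, xc + 2)
  i10 <- cbind(yc + 2, xc + 1); i11 <- cbind(yc + 2, xc + 2)
  v <- img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
  v[!ok] <- fill
  v
}

#' Warp an image with an affine transform
#'
#' Resamples `img` onto a target grid by inverse mapping with bilinear
#' interpolation.  `M` maps source (moving) pixel coordinates to target
#' (fixed) coordinates, (x = col, y = row), 0-based.
#'
#' @param img matrix or H x W x C array.
#' @param M 2 x 3 affine matrix.
#' @param dims length-2 (rows, cols) of the target grid.
#' @param fill value for samples falling outside the source (default 1,
#'   blank-slide white).
#' @return warped matrix / array of spatial size `dims`.
#' @export
warp_affine <- function(img, M, dims, fill = 1) {
  Mi <- invert_affine(M)
  g <- expand.grid(y = 0:(dims[1L] - 1L), x = 0:(dims[2L] - 1L))
  src <- apply_affine(Mi, cbind(g$x, g$y))
  if (is.matrix(img)) {
    return(matrix(bilinear_sample(img, src[, 1L], src[, 2L], fill),
                  dims[1L], dims[2L]))
  }
  C <- dim(img)[3L]
  out <- array(0, c(dims, C))
  for (ch in seq_len(C))
    out[, , ch] <- matrix(bilinear_sample(img[, , ch], src[, 1L], src[, 2L],
                                          fill), dims[1L], dims[2L])
  out
}

#' Register a high-resolution RGB image to a hyperspectral frame
#'
#' Detects corner keypoints on the moving image's luminance and on the fixed
#' panchromatic image, matches binary descriptors (Hamming, ratio test),
#' estimates an affine transform robustly, and resamples the RGB image onto
#' the fixed grid with bilinear interpolation.
#'
#' @param moving [rgb_image] (or H x W x 3 array), the RGB histology image.
#' @param fixed grayscale matrix (typically [panchromatic()] of the cube) or
#'   an [hsi_cube].
#' @param threshold,n_max,ratio,reproj_tol,n_iter,seed detector / matcher /
#'   RANSAC parameters; see [detect_corners()], [match_descriptors()],
#'   [ransac_affine()].
#' @return list with `warped` ([rgb_image] on the fixed grid) and
#'   `transform` (list: `matrix` 2 x 3 moving -> fixed, `inliers` count,
#'   `residual` mean inlier error in px, `params`).
#' @export
register_rgb_to_hsi <- function(moving, fixed, threshold = 0.04,
                                n_max = 5000L, ratio = 0.75,
                                reproj_tol = 3, n_iter = 2000L, seed = 1L) {
  if (is_hsi_cube(fixed)) fixed <- panchromatic(fixed)
  mv <- if (inherits(moving, "rgb_image")) moving$values else moving
  if (min(dim(fixed)) < 64L || min(dim(mv)[1:2]) < 64L)
    stop("images must be at least 64 x 64 for registration")
  mg <- luminance(mv)
  kp_m <- detect_corners(mg, threshold = threshold, n_max = n_max)
  kp_f <- detect_corners(fixed, threshold = threshold, n_max = n_max)
  if (nrow(kp_m) < 3L || nrow(kp_f) < 3L)
    stop("registration failure: too few keypoints (",
         nrow(kp_m), " moving, ", nrow(kp_f), " fixed)")
  d_m <- brief_descriptors(mg, kp_m)
  d_f <- brief_descriptors(fixed, kp_f)
  mt <- match_descriptors(d_m, d_f, ratio = ratio)
  fit <- ransac_affine(cbind(kp_m$x[mt$i1], kp_m$y[mt$i1]),
                       cbind(kp_f$x[mt$i2], kp_f$y[mt$i2]),
                       reproj_tol = reproj_tol, n_iter = n_iter, seed = seed)
  warped <- warp_affine(mv, fit$matrix, dim(fixed))
  warped <- pmin(pmax(warped, 0), 1)
  list(warped = rgb_image(warped,
                          meta = list(registered = TRUE)),
       transform = list(matrix = fit$matrix,
                        inliers = length(fit$inliers),
                        residual = fit$residual,
                        params = list(threshold = threshold, n_max = n_max,
                                      ratio = ratio,
                                      reproj_tol = reproj_tol)))
}
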