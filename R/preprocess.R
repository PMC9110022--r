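#' Panchromatic projection of a cube
#'
#' The band-mean image: `out[i, j] = mean_b values[i, j, b]`.  Used both for
#' registration (feature detection needs a single channel) and as the
#' grayscale operand of the spatial loss and the global SSIM.
#'
#' @param cube an [hsi_cube] or a bare H x W x B array.
#' @return H x W numeric matrix.
#' @export
panchromatic <- function(cube) {
  v <- if (is_hsi_cube(cube)) cube$values else cube
  stopifnot(length(dim(v)) == 3L)
  rowMeans(v, dims = 2L)
}

#' Rec. 709 luminance of an RGB image
#'
#' @param rgb an [rgb_image] or H x W x 3 array.
#' @return H x W numeric matrix.
#' @export
luminance <- function(rgb) {
  v <- if (inherits(rgb, "rgb_image")) rgb$values else rgb
  0.2126 * v[, , 1L] + 0.7152 * v[, , 2L] + 0.0722 * v[, , 3L]
}

#' Sliding-window patch grid
#'
#' Window origins along one axis are `0, s, 2s, ...` such that the window
#' fits entirely; the per-axis count is `floor((dim - w) / s) + 1`.
#'
#' @param dims length-2 integer (rows, cols) of the source frame.
#' @param w window size in pixels (default 200).
#' @param s step size in pixels (default 100).
#' @return data.frame with 0-based `row`, `col` origins (row-major order).
#' @examples
#' nrow(patch_origins(c(2000, 2000)))  # 361
#' @export
patch_origins <- function(dims, w = 200L, s = 100L) {
  stopifnot(length(dims) == 2L, s > 0L, s <= w)
  if (any(dims < w)) stop("frame smaller than the window: ",
                          paste(dims, collapse = "x"), " < ", w)
  rows <- seq(0L, dims[1L] - w, by = s)
  cols <- seq(0L, dims[2L] - w, by = s)
  data.frame(row = rep(rows, each = length(cols)),
             col = rep(cols, times = length(rows)))
}

#' Tissue fraction of a patch
#'
#' Fraction of pixels darker than `tau`.  Stained tissue absorbs light, so a
#' blank slide area has near-unity transmittance (or luminance); a pixel
#' counts as tissue when its panchromatic (hyperspectral input) or luminance
#' (RGB input) value falls below `tau`.
#'
#' @param patch [hsi_cube], [rgb_image], or a matrix already projected to a
#'   single channel.
#' @param tau tissue threshold in (0, 1); default 0.9.
#' @return fraction in \[0, 1\].
#' @export
tissue_fraction <- function(patch, tau = 0.9) {
  stopifnot(tau > 0, tau < 1)
  g <- if (is_hsi_cube(patch)) panchromatic(patch)
       else if (inherits(patch, "rgb_image")) luminance(patch)
       else patch
  mean(g < tau)
}

#' Extract aligned patches from a registered frame
#'
#' Crops a co-registered hyperspectral cube and RGB image into square patches
#' on a sliding-window grid, removes patches with too little tissue, and
#' produces [patch_pair] objects with box-downsampled low-resolution
#' hyperspectral members.
#'
#' @param cube [hsi_cube], the high-resolution hyperspectral frame.
#' @param rgb [rgb_image] registered to `cube` (same spatial dims), or
#'   `NULL` to derive patches from the cube alone via [rgb_from_cube()].
#' @param scale integer downsampling factor S for the LR member.
#' @param w,s window and step in pixels.
#' @param min_tissue_frac minimum tissue fraction to keep a patch (boundary
#'   kept: a patch at exactly the threshold is retained).
#' @param tau tissue threshold passed to [tissue_fraction()].
#' @param tissue_on `"hsi"` (default) or `"rgb"`: which member the tissue
#'   test is computed on.
#' @param label slide-level label attached to every patch.
#' @return list of [patch_pair].
#' @export
extract_patches <- function(cube, rgb = NULL, scale = 4L, w = 200L,
                            s = 100L, min_tissue_frac = 0.5, tau = 0.9,
                            tissue_on = c("hsi", "rgb"), label = 0L) {
  stopifnot(is_hsi_cube(cube))
  tissue_on <- match.arg(tissue_on)
  if (w %% scale != 0L) stop("window must be divisible by scale")
  d <- dim(cube$values)
  if (is.null(rgb)) rgb <- rgb_from_cube(cube)
  if (!identical(dim(rgb$values)[1:2], d[1:2]))
    stop("rgb and cube spatial dims differ; register first")
  org <- patch_origins(d[1:2], w, s)
  out <- list()
  for (i in seq_len(nrow(org))) {
    r0 <- org$row[i]; c0 <- org$col[i]
    ri <- (r0 + 1L):(r0 + w); ci <- (c0 + 1L):(c0 + w)
    hr <- hsi_cube(cube$values[ri, ci, , drop = FALSE], cube$wavelengths)
    hrgb <- rgb_image(rgb$values[ri, ci, , drop = FALSE])
    tf <- if (tissue_on == "hsi") tissue_fraction(hr, tau)
          else tissue_fraction(hrgb, tau)
    if (tf < min_tissue_frac) next
    lr <- box_downsample(hr, scale)
    out[[length(out) + 1L]] <-
      patch_pair(hr, hrgb, lr, label = label, origin = c(r0, c0))
  }
  out
}

#' Box (block-average) downsampling
#'
#' Each output pixel is the arithmetic mean of the corresponding S x S input
#' block, computed per band.  This operator is identical to stride-S average
#' pooling with an S x S kernel and is the degradation model used to
#' simulate low-resolution hyperspectral input.
#'
#' @param cube [hsi_cube], [rgb_image], H x W matrix or H x W x C array.
#' @param scale integer factor S >= 1; spatial dims must be divisible by S
#'   (no implicit padding).  Use [crop_to_multiple()] first if they are not.
#' @return object of the same kind with spatial dims divided by S.
#' @export
box_downsample <- function(cube, scale) {
  scale <- as.integer(scale)
  stopifnot(scale >= 1L)
  if (is_hsi_cube(cube)) {
    return(hsi_cube(box_downsample(cube$values, scale), cube$wavelengths,
                    meta = cube$meta))
  }
  if (inherits(cube, "rgb_image")) {
    return(rgb_image(box_downsample(cube$values, scale), meta = cube$meta))
  }
  v <- cube
  ismat <- is.matrix(v)
  if (ismat) v <- array(v, c(dim(v), 1L))
  d <- dim(v)
  if (d[1L] %% scale != 0L || d[2L] %% scale != 0L)
    stop("spatial dims (", d[1L], "x", d[2L],
         ") not divisible by scale ", scale)
  if (scale == 1L) return(if (ismat) v[, , 1L] else v)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  h <- H %/% scale; wd <- W %/% scale
  # average rows: (S, h, W*C) -> (h, W, C)
  t1 <- colMeans(array(v, c(scale, h, W * C)))
  a2 <- aperm(array(t1, c(h, W, C)), c(2L, 1L, 3L))  # (W, h, C)
  t2 <- colMeans(array(a2, c(scale, wd, h * C)))     # (wd, h*C)
  out <- aperm(array(t2, c(wd, h, C)), c(2L, 1L, 3L))
  if (ismat) out[, , 1L] else out
}

#' Crop to the nearest size divisible by a factor
#'
#' Explicit helper for inputs whose spatial dims are not multiples of the
#' downsampling scale; trims rows/cols at the bottom/right edge.
#'
#' @param x [hsi_cube], [rgb_image], matrix or 3-D array.
#' @param scale integer factor.
#' @return cropped object of the same kind.
#' @export
crop_to_multiple <- function(x, scale) {
  scale <- as.integer(scale)
  if (is_hsi_cube(x))
    return(hsi_cube(crop_to_multiple(x$values, scale), x$wavelengths, x$meta))
  if (inherits(x, "rgb_image"))
    return(rgb_image(crop_to_multiple(x$values, scale), x$meta))
  d <- dim(x)
  h <- (d[1L] %/% scale) * scale
  w <- (d[2L] %/% scale) * scale
  if (is.matrix(x)) x[seq_len(h), seq_len(w), drop = FALSE]
  else x[seq_len(h), seq_len(w), , drop = FALSE]
}

#' Stage-step overlap in pixels
#'
#' For a motorized-stage scan where the camera field of view spans
#' `fov_um` micrometres over `fov_px` pixels and the stage moves `step_um`
#' micrometres between frames, adjacent frames overlap by
#' `round(fov_px * (fov_um - step_um) / fov_um)` pixels.
#'
#' @param fov_um field-of-view width in micrometres (default 1113).
#' @param fov_px field-of-view width in pixels (default 2000).
#' @param step_um stage step in micrometres (default 1000).
#' @return integer overlap in pixels.
#' @examples
#' stage_overlap_px()  # 203
#' @export
stage_overlap_px <- function(fov_um = 1113, fov_px = 2000, step_um = 1000) {
  stopifnot(fov_um > 0, fov_px > 0, step_um <= fov_um)
  as.integer(round(fov_px * (fov_um - step_um) / fov_um))
}
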