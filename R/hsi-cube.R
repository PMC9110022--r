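#' Hyperspectral transmittance cube
#'
#' Container for an H x W x B hyperspectral image in transmittance units
#' (dimensionless, nominally within \[0, ~1.2\]) with an ascending wavelength
#' grid in nanometres.  The axis convention is (row, col, band) with the band
#' axis last.
#'
#' @param values numeric H x W x B array (a matrix is promoted to H x W x 1).
#' @param wavelengths numeric vector of band-centre wavelengths (nm), strictly
#'   increasing, of length B.  Defaults to a uniform grid over 470--720 nm.
#' @param meta named list of free-form provenance (slide id, magnification,
#'   scale tag, ...).
#' @return An object of class `hsi_cube` with elements `values`,
#'   `wavelengths`, `meta`.
#' @examples
#' cube <- hsi_cube(array(runif(4 * 4 * 5), c(4, 4, 5)))
#' dim(cube$values)
#' @export
hsi_cube <- function(values, wavelengths = NULL, meta = list()) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  storage.mode(values) <- "double"
  B <- dim(values)[3L]
  if (is.null(wavelengths)) wavelengths <- default_wavelengths(B)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != B)
    stop("length(wavelengths) must equal the number of bands (", B, ")")
  if (B > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!all(is.finite(values)))
    stop("cube values must all be finite")
  structure(list(values = values, wavelengths = wavelengths, meta = meta),
            class = "hsi_cube")
}

#' Default wavelength grid
#'
#' Uniform band-centre grid used when a cube carries no explicit wavelength
#' metadata.  The default spectral range matches a visible-range transmission
#' microscope (470--720 nm, 87 bands).
#'
#' @param n_bands number of bands.
#' @param range length-2 numeric, spectral range in nm.
#' @return numeric vector of length `n_bands`.
#' @export
default_wavelengths <- function(n_bands = 87L, range = c(470, 720)) {
  if (n_bands == 1L) return(mean(range))
  seq(range[1L], range[2L], length.out = n_bands)
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$values)

is_hsi_cube <- function(x) inherits(x, "hsi_cube")

#' RGB image
#'
#' An H x W x 3 colour image with values in \[0, 1\] and fixed channel order
#' (R, G, B).
#'
#' @param values numeric H x W x 3 array in \[0, 1\].
#' @param meta named list of provenance.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(values, meta = list()) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (dim(values)[3L] != 3L) stop("rgb_image requires exactly 3 channels")
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("rgb values must all be finite")
  if (min(values) < 0 || max(values) > 1)
    stop("rgb values must lie in [0, 1]")
  structure(list(values = values, meta = meta), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<rgb_image> %d x %d pixels\n", d[1L], d[2L]))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$values)

#' Aligned training/evaluation patch pair
#'
#' Bundles an aligned high-resolution hyperspectral patch, high-resolution
#' RGB patch and low-resolution hyperspectral patch together with a binary
#' label (1 = tumour, 0 = normal) and the patch origin in the source frame.
#'
#' @param hr_hsi `hsi_cube`, w x w x B.
#' @param hr_rgb `rgb_image`, w x w x 3.
#' @param lr_hsi `hsi_cube`, (w/S) x (w/S) x B.
#' @param label 0 or 1.
#' @param origin integer length-2 (row, col) of the patch's top-left corner in
#'   the source image, 0-based.
#' @return An object of class `patch_pair`.
#' @export
patch_pair <- function(hr_hsi, hr_rgb, lr_hsi, label = 0L,
                       origin = c(0L, 0L)) {
  stopifnot(is_hsi_cube(hr_hsi), inherits(hr_rgb, "rgb_image"),
            is_hsi_cube(lr_hsi))
  dh <- dim(hr_hsi$values); dl <- dim(lr_hsi$values)
  if (dh[1L] != dh[2L]) stop("patches must be square")
  if (!identical(dim(hr_rgb$values)[1:2], dh[1:2]))
    stop("hr_rgb spatial dims must match hr_hsi")
  if (dh[3L] != dl[3L]) stop("hr and lr band counts differ")
  if (dh[1L] %% dl[1L] != 0L)
    stop("hr size must be an integer multiple of lr size")
  if (!label %in% c(0, 1)) stop("label must be 0 or 1")
  structure(list(hr_hsi = hr_hsi, hr_rgb = hr_rgb, lr_hsi = lr_hsi,
                 label = as.integer(label),
                 origin = as.integer(origin)),
            class = "patch_pair")
}

#' Radiometric calibration to transmittance
#'
#' Converts a raw hyperspectral intensity cube to transmittance using a white
#' reference cube (blank slide area) and a dark-current cube (shutter
#' closed):
#' \deqn{T(\lambda) = \frac{I_{raw}(\lambda) - I_{dark}(\lambda)}
#'                         {I_{white}(\lambda) - I_{dark}(\lambda)}}
#' computed elementwise per band.  Pixels where the denominator falls below
#' `eps` carry no usable signal; they are set to 0 and counted in the
#' returned mask.  Output values are clamped to \[0, `clamp_max`\]; the
#' default ceiling 1.2 preserves slight super-unity shot noise while bounding
#' the domain.
#'
#' @param raw,white,dark `hsi_cube` objects (or bare arrays) of identical
#'   shape.
#' @param eps small positive denominator floor.
#' @param clamp_max upper clamp for transmittance.
#' @return An `hsi_cube` of transmittance.  `meta$calibration` records
#'   `eps`, `clamp_max` and `n_masked` (number of denominator-floored
#'   entries); `meta$masked` holds the logical H x W x B mask.
#' @examples
#' w <- array(100, c(2, 2, 3)); d <- array(10, c(2, 2, 3))
#' r <- d + 0.25 * (w - d)
#' calibrate_transmittance(hsi_cube(r), hsi_cube(w), hsi_cube(d))$values[1, 1, 1]
#' @export
calibrate_transmittance <- function(raw, white, dark, eps = 1e-6,
                                    clamp_max = 1.2) {
  va <- function(x) if (is_hsi_cube(x)) x$values else x
  wl <- if (is_hsi_cube(raw)) raw$wavelengths else NULL
  r <- va(raw); w <- va(white); d <- va(dark)
  if (!identical(dim(r), dim(w)) || !identical(dim(r), dim(d)))
    stop("raw, white and dark cubes must have identical shapes")
  stopifnot(eps > 0)
  den <- w - d
  bad <- den < eps
  den[bad] <- 1  # placeholder; masked below
  tr <- (r - d) / den
  tr[bad] <- 0
  tr[tr < 0] <- 0
  tr[tr > clamp_max] <- clamp_max
  meta <- if (is_hsi_cube(raw)) raw$meta else list()
  meta$calibration <- list(eps = eps, clamp_max = clamp_max,
                           n_masked = sum(bad))
  meta$masked <- bad
  hsi_cube(tr, wavelengths = wl, meta = meta)
}
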