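#' Specification of a stained-tissue phantom
#'
#' Phantoms emulate transmittance-domain histology patches through a
#' Beer-Lambert construction: each of K chromophores has a Gaussian
#' absorptivity curve over the wavelength grid, nuclei are random ellipses
#' rich in chromophore 1 (hematoxylin-like), cytoplasm is a smooth random
#' field of chromophore 2 (eosin-like), and a blank region carries no
#' chromophore at all (transmittance exactly 1).  The degraded view applies
#' defocus blur and heteroscedastic band noise, inflated at the spectral
#' extremes where real sensors lose sensitivity.  The RGB view is rendered
#' from the clean cube, reproducing the key asymmetry of the acquisition:
#' the colour camera carries high-frequency spatial detail the degraded
#' hyperspectral cube lacks.
#'
#' @param w patch size in pixels.
#' @param n_bands band count B.
#' @param wl_range spectral range in nm (default 470-720).
#' @param chromophores list of lists with `center` (nm), `width` (nm),
#'   `amplitude` (absorbance units at unit concentration).  Defaults are a
#'   hematoxylin-like (605 nm) and an eosin-like (525 nm) idealization.
#' @param nucleus_density expected nuclei per pixel^2 (default 0.008).
#' @param nucleus_radius length-2 range of ellipse semi-axes in pixels.
#' @param cyto_smoothness Gaussian sd (pixels) of the cytoplasm
#'   concentration field.
#' @param blank_frac approximate fraction of the patch left blank.
#' @param noise_sd mid-band Gaussian noise sd on transmittance.
#' @param noise_edge_factor multiplier on `noise_sd` at the first and last
#'   bands (default 4, tapering inwards).
#' @param blur_sd defocus blur sd in pixels for the degraded cube.
#' @param scale downsampling factor used for the low-resolution member.
#' @param class_contrast concentration shift delta distinguishing label 1
#'   (tumour-like: denser, larger, darker nuclei) from label 0.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(w = 32L, n_bands = 8L, wl_range = c(470, 720),
                         chromophores = list(
                           list(center = 605, width = 50, amplitude = 1.1),
                           list(center = 525, width = 35, amplitude = 0.65)),
                         nucleus_density = 0.008,
                         nucleus_radius = c(2, 5),
                         cyto_smoothness = 4,
                         blank_frac = 0.2,
                         noise_sd = 0.01,
                         noise_edge_factor = 4,
                         blur_sd = 1.0,
                         scale = 4L,
                         class_contrast = 0.5) {
  stopifnot(w %% as.integer(scale) == 0L, n_bands >= 2L,
            all(vapply(chromophores, function(ch) ch$amplitude >= 0, TRUE)),
            noise_sd >= 0, blur_sd >= 0, blank_frac >= 0, blank_frac < 1,
            class_contrast >= 0)
  structure(list(w = as.integer(w), n_bands = as.integer(n_bands),
                 wl_range = wl_range, chromophores = chromophores,
                 nucleus_density = nucleus_density,
                 nucleus_radius = nucleus_radius,
                 cyto_smoothness = cyto_smoothness,
                 blank_frac = blank_frac, noise_sd = noise_sd,
                 noise_edge_factor = noise_edge_factor, blur_sd = blur_sd,
                 scale = as.integer(scale),
                 class_contrast = class_contrast),
            class = "phantom_spec")
}

#' Chromophore absorptivity curves on the wavelength grid
#'
#' @param spec [phantom_spec].
#' @return B x K matrix of nonnegative absorptivities.
#' @export
absorptivity_matrix <- function(spec) {
  wl <- default_wavelengths(spec$n_bands, spec$wl_range)
  vapply(spec$chromophores,
         function(ch) ch$amplitude * exp(-(wl - ch$center)^2 /
                                           (2 * ch$width^2)),
         numeric(spec$n_bands))
}

#' Band-dependent noise profile
#'
#' Gaussian noise sd per band: `noise_sd` in the mid-range, rising to
#' `noise_edge_factor * noise_sd` at the first and last band with a
#' quadratic taper, emulating the low sensor sensitivity at the spectral
#' extremes.
#'
#' @param spec [phantom_spec].
#' @return length-B vector of sds.
#' @export
noise_profile <- function(spec) {
  B <- spec$n_bands
  x <- abs(seq(-1, 1, length.out = B))
  spec$noise_sd * (1 + (spec$noise_edge_factor - 1) * x^4)
}

#' Generate one phantom sample
#'
#' Draws concentration maps, renders the clean cube by Beer-Lambert
#' (`T = exp(-sum_k c_k eps_k(lambda))`), degrades it (Gaussian blur +
#' heteroscedastic band noise, clamped to nonnegative), renders RGB from the
#' clean cube via [rgb_from_cube()], and box-downsamples the degraded cube
#' into the low-resolution member.  Bit-reproducible given `seed`.
#'
#' @param spec [phantom_spec].
#' @param seed integer seed.
#' @param label 0 (normal-like) or 1 (tumour-like; concentrations shifted by
#'   `class_contrast`).
#' @return list of class `phantom_sample`: `clean` ([hsi_cube]),
#'   `degraded` ([hsi_cube]), `rgb` ([rgb_image]), `lr` ([hsi_cube]),
#'   `label`, `concentration` (w x w x K array), `blank_mask`.
#' @export
generate_phantom <- function(spec, seed = 1L, label = 0L) {
  stopifnot(inherits(spec, "phantom_spec"), label %in% c(0, 1))
  set.seed(seed)
  w <- spec$w
  K <- length(spec$chromophores)
  bump <- if (label == 1L) spec$class_contrast else 0
  # blank region: thresholded smooth field
  blank <- smooth_field(w, spec$cyto_smoothness * 2)
  blank_mask <- blank < stats::quantile(blank, spec$blank_frac)
  # cytoplasm: smooth nonnegative field of chromophore 2 (or last)
  cyto <- smooth_field(w, spec$cyto_smoothness)
  cyto <- (cyto - min(cyto)) / (max(cyto) - min(cyto) + 1e-12)
  cyto <- (0.25 + 0.75 * cyto) * (1 + 0.3 * bump)
  # nuclei: random ellipses of chromophore 1
  n_nuc <- stats::rpois(1, spec$nucleus_density * w^2 * (1 + bump))
  nuc <- matrix(0, w, w)
  if (n_nuc > 0) {
    cx <- stats::runif(n_nuc, 1, w); cy <- stats::runif(n_nuc, 1, w)
    ra <- stats::runif(n_nuc, spec$nucleus_radius[1L],
                       spec$nucleus_radius[2L]) * (1 + 0.3 * bump)
    rb <- stats::runif(n_nuc, spec$nucleus_radius[1L],
                       spec$nucleus_radius[2L]) * (1 + 0.3 * bump)
    th <- stats::runif(n_nuc, 0, pi)
    amp <- stats::runif(n_nuc, 0.8, 1.4) * (1 + bump)
    gx <- matrix(seq_len(w), w, w, byrow = TRUE)   # x = col
    gy <- matrix(seq_len(w), w, w)
    for (i in seq_len(n_nuc)) {
      dx <- gx - cx[i]; dy <- gy - cy[i]
      u <- (cos(th[i]) * dx + sin(th[i]) * dy) / ra[i]
      v <- (-sin(th[i]) * dx + cos(th[i]) * dy) / rb[i]
      nuc <- nuc + amp[i] * (u^2 + v^2 <= 1)
    }
  }
  conc <- array(0, c(w, w, K))
  conc[, , 1L] <- nuc
  if (K >= 2L) conc[, , 2L] <- cyto
  if (K > 2L) for (k in 3:K) conc[, , k] <- smooth_field(w, spec$cyto_smoothness)
  for (k in seq_len(K)) conc[, , k][blank_mask] <- 0
  conc[conc < 0] <- 0
  eps <- absorptivity_matrix(spec)               # B x K
  od <- matrix(conc, w * w, K) %*% t(eps)        # (w*w) x B optical density
  clean <- array(exp(-od), c(w, w, spec$n_bands))
  wl <- default_wavelengths(spec$n_bands, spec$wl_range)
  # degraded view: defocus blur then band-dependent sensor noise
  degr <- clean
  if (spec$blur_sd > 0) {
    for (b in seq_len(spec$n_bands))
      degr[, , b] <- gauss_blur(degr[, , b], spec$blur_sd)
  }
  nsd <- noise_profile(spec)
  for (b in seq_len(spec$n_bands))
    degr[, , b] <- degr[, , b] + stats::rnorm(w * w, 0, nsd[b])
  degr[degr < 0] <- 0
  rgb <- rgb_from_cube(hsi_cube(clean, wl))
  lr <- box_downsample(hsi_cube(degr, wl), spec$scale)
  structure(list(clean = hsi_cube(clean, wl),
                 degraded = hsi_cube(degr, wl),
                 rgb = rgb, lr = lr, label = as.integer(label),
                 concentration = conc, blank_mask = blank_mask),
            class = "phantom_sample")
}

# smooth nonneg-range random field: white noise blurred with a Gaussian
smooth_field <- function(w, sigma) {
  f <- matrix(stats::rnorm(w * w), w, w)
  if (sigma > 0) f <- gauss_blur(f, sigma)
  f
}

#' Render RGB from a hyperspectral cube
#'
#' Each colour channel is a response-weighted band average; default
#' responses are Gaussians centred at 610 (R), 540 (G) and 480 nm (B) with
#' 30 nm sd, renormalized to sum to 1 on the cube's wavelength grid.
#'
#' @param cube [hsi_cube].
#' @param responses optional B x 3 matrix of nonnegative channel weights,
#'   each column summing to 1.
#' @param clamp clamp the result into \[0, 1\] (default TRUE; transmittance
#'   can slightly exceed 1).
#' @return [rgb_image].
#' @export
rgb_from_cube <- function(cube, responses = NULL, clamp = TRUE) {
  stopifnot(is_hsi_cube(cube))
  wl <- cube$wavelengths
  B <- length(wl)
  if (is.null(responses)) {
    centers <- c(610, 540, 480)
    responses <- vapply(centers,
                        function(mu) exp(-(wl - mu)^2 / (2 * 30^2)),
                        numeric(B))
    responses <- sweep(responses, 2L, colSums(responses), "/")
  }
  responses <- as.matrix(responses)
  if (nrow(responses) != B || ncol(responses) != 3L)
    stop("responses must be B x 3")
  if (any(responses < 0)) stop("negative channel responses")
  if (any(abs(colSums(responses) - 1) > 1e-8))
    stop("each response column must sum to 1")
  d <- dim(cube$values)
  v <- matrix(cube$values, d[1L] * d[2L], B) %*% responses
  if (clamp) v <- pmin(pmax(v, 0), 1)
  rgb_image(array(v, c(d[1L], d[2L], 3L)),
            meta = list(rendered_from = "cube"))
}

#' Generate a partitioned phantom dataset
#'
#' Splits use disjoint seed ranges (akin to patient-level partitioning:
#' no sample is shared between groups) and alternate labels for class
#' balance.
#'
#' @param spec [phantom_spec].
#' @param n_train,n_val,n_test split sizes.
#' @param seed base seed; split i, sample j uses seed
#'   `seed + offset_i + j`.
#' @return list with `train`, `val`, `test` (lists of `phantom_sample`) and
#'   `manifest` (data.frame of split, index, seed, label).
#' @export
make_dataset <- function(spec, n_train, n_val, n_test, seed = 1L) {
  stopifnot(n_train > 0L, n_val > 0L, n_test > 0L)
  offs <- c(train = 0L, val = n_train, test = n_train + n_val)
  sizes <- c(train = n_train, val = n_val, test = n_test)
  out <- list()
  manifest <- NULL
  for (sp in names(sizes)) {
    ns <- sizes[[sp]]
    seeds <- seed + offs[[sp]] + seq_len(ns)
    labels <- rep_len(c(0L, 1L), ns)
    out[[sp]] <- lapply(seq_len(ns), function(i)
      generate_phantom(spec, seed = seeds[i], label = labels[i]))
    manifest <- rbind(manifest,
                      data.frame(split = sp, index = seq_len(ns),
                                 seed = seeds, label = labels))
  }
  out$manifest <- manifest
  out
}

#' Convert a phantom sample to a training patch pair
#'
#' The high-resolution hyperspectral member is the degraded cube (what a
#' real acquisition would provide); the clean cube remains available in the
#' sample for evaluation against ground truth.
#'
#' @param sample `phantom_sample`.
#' @param use_clean use the clean cube as the HR member instead.
#' @return [patch_pair].
#' @export
phantom_to_pair <- function(sample, use_clean = FALSE) {
  hr <- if (use_clean) sample$clean else sample$degraded
  patch_pair(hr_hsi = hr, hr_rgb = sample$rgb, lr_hsi = sample$lr,
             label = sample$label, origin = c(0L, 0L))
}
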