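# shared fixture builders (all generated in code; nothing on disk)

rand_cube <- function(h = 4L, w = 4L, b = 5L, seed = 1L, lo = 0, hi = 1) {
  set.seed(seed)
  hsi_cube(array(runif(h * w * b, lo, hi), c(h, w, b)))
}

rand_rgb <- function(h = 4L, w = 4L, seed = 1L) {
  set.seed(seed)
  rgb_image(array(runif(h * w * 3), c(h, w, 3)))
}

# tiny SRR configuration that trains in well under a second per epoch
toy_srr_config <- function(...) {
  srr_config(scale = 4L, w = 16L, n_bands = 6L, counts = c(2L, 2L, 2L),
             kappa = 0.05, ...)
}

toy_patch_set <- function(n = 4L, w = 16L, b = 6L, scale = 4L, seed = 1L) {
  spec <- phantom_spec(w = w, n_bands = b, scale = scale)
  lapply(seq_len(n), function(i)
    phantom_to_pair(generate_phantom(spec, seed = seed * 1000L + i,
                                     label = (i - 1L) %% 2L)))
}

# textured grayscale scene with reproducible corners for registration tests
textured_scene <- function(n = 160L, seed = 3L, n_blobs = 60L) {
  set.seed(seed)
  img <- matrix(1, n, n)
  cx <- runif(n_blobs, 10, n - 10); cy <- runif(n_blobs, 10, n - 10)
  r <- runif(n_blobs, 2, 6); v <- runif(n_blobs, 0.1, 0.7)
  gx <- matrix(seq_len(n), n, n, byrow = TRUE)
  gy <- matrix(seq_len(n), n, n)
  for (i in seq_len(n_blobs)) {
    m <- (gx - cx[i])^2 + (gy - cy[i])^2 <= r[i]^2
    img[m] <- pmin(img[m], v[i])
  }
  img
}

as_rgb_from_gray <- function(gray) {
  rgb_image(array(rep(pmin(pmax(gray, 0), 1), 3L), c(dim(gray), 3L)))
}

# integer-shift an image, padding with white (blank slide)
shift_image <- function(img, dy, dx, fill = 1) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}
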