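# Beer-Lambert phantom generator: construction identities, degradation
# model, reproducibility, dataset partitioning.

test_that("clean phantoms obey the Beer-Lambert construction exactly", {
  spec <- phantom_spec(w = 32L, n_bands = 8L)
  s <- generate_phantom(spec, seed = 21L, label = 0L)

  # blank pixels transmit exactly 1 at every band
  expect_true(any(s$blank_mask))
  blanks <- which(s$blank_mask)
  for (b in seq_len(8)) {
    band <- s$clean$values[, , b]
    expect_true(all(band[blanks] == 1))
  }

  # transmittance = exp(-concentration . absorptivity) at every pixel
  eps <- absorptivity_matrix(spec)
  od <- matrix(s$concentration, 32 * 32, 2) %*% t(eps)
  expect_equal(array(exp(-od), c(32, 32, 8)), s$clean$values)
  expect_true(all(s$clean$values > 0 & s$clean$values <= 1))

  # closed form: unit concentration against a single-chromophore spec
  one <- phantom_spec(w = 8L, n_bands = 5L,
                      chromophores = list(
                        list(center = 595, width = 1e5, amplitude = 0.693)))
  e1 <- absorptivity_matrix(one)
  expect_equal(exp(-1 * e1[3, 1]), 0.5, tolerance = 1e-3)
})

test_that("phantom generation is bit-reproducible and label-sensitive", {
  spec <- phantom_spec(w = 16L, n_bands = 6L)
  a <- generate_phantom(spec, seed = 4L, label = 1L)
  b <- generate_phantom(spec, seed = 4L, label = 1L)
  expect_identical(a$clean$values, b$clean$values)
  expect_identical(a$degraded$values, b$degraded$values)
  expect_identical(a$rgb$values, b$rgb$values)
  c_ <- generate_phantom(spec, seed = 5L, label = 1L)
  expect_false(identical(a$clean$values, c_$clean$values))
})

test_that("the low-resolution member is exactly the box-downsampled cube", {
  s <- generate_phantom(phantom_spec(w = 24L, n_bands = 5L, scale = 4L),
                        seed = 8L)
  expect_identical(s$lr$values, box_downsample(s$degraded, 4L)$values)
})

test_that("optical-density spectra of proportionally concentrated pixels
           are collinear", {
  spec <- phantom_spec(w = 8L, n_bands = 6L)
  eps <- absorptivity_matrix(spec)
  c1 <- c(0.4, 0.9); c2 <- 2.5 * c1
  od1 <- as.numeric(eps %*% c1); od2 <- as.numeric(eps %*% c2)
  a1 <- array(od1, c(1, 1, 6)); a2 <- array(od2, c(1, 1, 6))
  expect_equal(as.numeric(sam(a1, a2)), 0, tolerance = 1e-8)
})

test_that("blank-region noise estimate recovers the band noise profile", {
  spec <- phantom_spec(w = 128L, n_bands = 8L, blank_frac = 0.4)
  s <- generate_phantom(spec, seed = 30L)
  # stay clear of the blank boundary so defocus blur does not leak tissue in
  interior <- gauss_blur(1 - s$blank_mask * 1, spec$blur_sd * 3) < 1e-3
  expect_gt(sum(interior), 200L)
  est <- vapply(seq_len(8), function(b) {
    resid <- s$degraded$values[, , b][interior] - 1
    sqrt(mean(resid^2))
  }, 0)
  expect_true(all(abs(est - noise_profile(spec)) / noise_profile(spec) < 0.2))
  # spectral extremes are noisier than the mid-range by construction
  np <- noise_profile(spec)
  expect_gt(np[1], 3 * min(np))
})

test_that("RGB rendering is a response-weighted band average", {
  const <- hsi_cube(array(0.4, c(3, 3, 6)))
  expect_equal(rgb_from_cube(const)$values, array(0.4, c(3, 3, 3)))

  cube <- rand_cube(4, 4, 6, seed = 44)
  delta <- matrix(0, 6, 3); delta[2, 1] <- 1; delta[4, 2] <- 1; delta[6, 3] <- 1
  out <- rgb_from_cube(cube, responses = delta, clamp = FALSE)
  expect_equal(out$values[, , 1], cube$values[, , 2])
  expect_equal(out$values[, , 3], cube$values[, , 6])

  set.seed(45)
  resp <- matrix(runif(18), 6, 3)
  resp <- sweep(resp, 2, colSums(resp), "/")
  out2 <- rgb_from_cube(cube, responses = resp, clamp = FALSE)
  oracle <- array(0, c(4, 4, 3))
  for (i in 1:4) for (j in 1:4) for (ch in 1:3)
    oracle[i, j, ch] <- sum(cube$values[i, j, ] * resp[, ch])
  expect_equal(out2$values, oracle, tolerance = 1e-12)

  expect_error(rgb_from_cube(cube, responses = -delta), "sum to 1|negative")
})

test_that("datasets partition into disjoint, balanced, manifested splits", {
  spec <- phantom_spec(w = 16L, n_bands = 5L)
  ds <- make_dataset(spec, 8, 2, 2, seed = 60L)
  expect_length(ds$train, 8L)
  expect_length(ds$val, 2L)
  expect_length(ds$test, 2L)
  expect_equal(nrow(ds$manifest), 12L)
  expect_equal(anyDuplicated(ds$manifest$seed), 0L)
  expect_equal(sum(ds$manifest$label), 6L)   # alternating labels

  # class contrast moves the mean nucleus load; delta = 0 removes the shift
  spec0 <- phantom_spec(w = 32L, n_bands = 5L, class_contrast = 0)
  spec1 <- phantom_spec(w = 32L, n_bands = 5L, class_contrast = 1.5)
  load_of <- function(spec, label, seeds)
    vapply(seeds, function(sd)
      mean(generate_phantom(spec, sd, label)$concentration[, , 1]), 0)
  s0 <- mean(load_of(spec1, 0L, 1:12)); s1 <- mean(load_of(spec1, 1L, 13:24))
  expect_gt(s1, s0 * 1.5)
  z0 <- mean(load_of(spec0, 0L, 1:12)); z1 <- mean(load_of(spec0, 1L, 13:24))
  expect_lt(abs(z1 - z0) / z0, 0.5)
})
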