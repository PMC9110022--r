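# Reconstruction-quality and classification metrics, each checked against an
# independent brute-force oracle.

oracle_psnr <- function(a, b, peak) {
  B <- dim(a)[3L]
  per <- numeric(B)
  for (k in seq_len(B)) {
    s <- 0; n <- 0
    for (i in seq_len(dim(a)[1L])) for (j in seq_len(dim(a)[2L])) {
      s <- s + (a[i, j, k] - b[i, j, k])^2; n <- n + 1
    }
    per[k] <- 10 * log10(peak^2 / (s / n))
  }
  per
}

oracle_mae <- function(a, b) {
  B <- dim(a)[3L]
  per <- numeric(B)
  for (k in seq_len(B)) {
    s <- 0; n <- 0
    for (i in seq_len(dim(a)[1L])) for (j in seq_len(dim(a)[2L])) {
      s <- s + abs(a[i, j, k] - b[i, j, k]); n <- n + 1
    }
    per[k] <- s / n
  }
  per
}

oracle_sam_mean <- function(r, t) {
  tot <- 0; n <- 0
  for (i in seq_len(dim(r)[1L])) for (j in seq_len(dim(r)[2L])) {
    rs <- r[i, j, ]; ts <- t[i, j, ]
    cosang <- sum(rs * ts) / (sqrt(sum(rs^2)) * sqrt(sum(ts^2)))
    tot <- tot + acos(min(max(cosang, -1), 1)); n <- n + 1
  }
  tot / n * 180 / pi
}

oracle_ssim <- function(g, h, L) {
  n <- length(g)
  mg <- sum(g) / n; mh <- sum(h) / n
  vg <- sum((g - mg)^2) / n; vh <- sum((h - mh)^2) / n
  cv <- sum((g - mg) * (h - mh)) / n
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  (2 * mg * mh + c1) * (2 * cv + c2) /
    ((mg^2 + mh^2 + c1) * (vg + vh + c2))
}

test_that("PSNR matches its definition and flags zero-MSE bands", {
  ones <- array(1, c(4, 4, 1)); zeros <- array(0, c(4, 4, 1))
  expect_equal(psnr_hsi(ones, zeros, peak = 1)$mean, 0)   # MSE 1 -> 0 dB

  cube <- rand_cube(4, 4, 3, seed = 21)$values
  gen <- rand_cube(4, 4, 3, seed = 22)$values
  expect_equal(psnr_hsi(cube, gen, 1)$per_band, oracle_psnr(cube, gen, 1),
               tolerance = 1e-9)

  expect_warning(res <- psnr_hsi(cube, cube, 1), "zero MSE")
  expect_true(all(is.infinite(res$per_band)))
  expect_error(psnr_hsi(cube, gen[, , 1:2]), "mismatch")
})

test_that("MAE matches its definition, with a percent scale", {
  cube <- rand_cube(4, 4, 3, seed = 23)$values
  expect_equal(mae_hsi(cube, cube)$mean, 0)
  expect_equal(mae_hsi(cube, cube + 0.05)$mean, 0.05)
  expect_equal(mae_hsi(cube, cube + 0.05, percent = TRUE)$mean, 5)
  gen <- rand_cube(4, 4, 3, seed = 24)$values
  expect_equal(mae_hsi(cube, gen)$per_band, oracle_mae(cube, gen),
               tolerance = 1e-9)
})

test_that("spectral angle is zero for collinear spectra and 90 deg for
           orthogonal ones", {
  cube <- rand_cube(3, 3, 5, seed = 25)
  expect_equal(as.numeric(sam(cube, cube)), 0)
  scaled <- hsi_cube(cube$values * 2.7)
  expect_equal(as.numeric(sam(cube, scaled)), 0, tolerance = 1e-6)
  expect_equal(as.numeric(sam(cube, scaled, mode = "pooled")), 0,
               tolerance = 1e-6)

  r <- array(c(1, 0), c(1, 1, 2)); t_ <- array(c(0, 1), c(1, 1, 2))
  expect_equal(as.numeric(sam(r, t_)), 90)

  # invariance to positive per-pixel rescaling of either argument
  set.seed(26)
  ref <- rand_cube(4, 4, 6, seed = 26)$values
  gen <- rand_cube(4, 4, 6, seed = 27)$values
  gains <- array(rep(runif(16, 0.2, 5), 6), c(4, 4, 6))
  expect_equal(as.numeric(sam(ref, gen)),
               as.numeric(sam(ref * gains, gen)), tolerance = 1e-8)
  expect_equal(as.numeric(sam(ref, gen)), oracle_sam_mean(ref, gen),
               tolerance = 1e-9)

  # all-zero spectra are excluded with a count
  z <- ref; z[1, 1, ] <- 0
  res <- sam(z, gen)
  expect_equal(attr(res, "n_zero"), 1L)
})

test_that("global SSIM matches the closed-form statistic", {
  g <- matrix(runif(64), 8, 8)
  expect_equal(ssim_global(g, g), 1, tolerance = 1e-12)
  h <- matrix(runif(64), 8, 8)
  expect_equal(ssim_global(g, h, L = 1), oracle_ssim(g, h, 1),
               tolerance = 1e-12)
  expect_equal(ssim_global(g, h), ssim_global(h, g))   # symmetry
  expect_lte(ssim_global(g, h), 1)
  cc <- hsifuse:::ssim_constants(1)
  expect_equal(unname(cc), c(1e-4, 9e-4))
})

test_that("every metric matches its oracle across many random instances", {
  set.seed(77)
  for (k in 1:50) {
    a <- array(runif(8 * 8 * 5), c(8, 8, 5))
    b <- array(runif(8 * 8 * 5), c(8, 8, 5))
    expect_equal(psnr_hsi(a, b, 1)$per_band, oracle_psnr(a, b, 1),
                 tolerance = 1e-9)
    expect_equal(mae_hsi(a, b)$per_band, oracle_mae(a, b), tolerance = 1e-9)
    expect_equal(as.numeric(sam(a, b)), oracle_sam_mean(a, b),
                 tolerance = 1e-9)
    expect_equal(ssim_global(a[, , 1], b[, , 1]),
                 oracle_ssim(a[, , 1], b[, , 1], 1), tolerance = 1e-9)
  }
})

test_that("PSNR decreases monotonically with added noise variance", {
  set.seed(5)
  ref <- rand_cube(16, 16, 4, seed = 50)$values
  psnrs <- vapply(c(0.01, 0.02, 0.04, 0.08, 0.16), function(s) {
    psnr_hsi(ref, ref + array(rnorm(length(ref), 0, s), dim(ref)), 1)$mean
  }, 0)
  expect_true(all(diff(psnrs) < 0))
})

test_that("confusion-count rates follow their definitions", {
  expect_equal(unname(classification_metrics(1, 1, 0, 0)), c(1, 1, 1))
  expect_equal(classification_metrics(85, 0, 0, 15)[["sensitivity"]], 0.85)
  expect_true(is.na(classification_metrics(0, 5, 3, 0)[["sensitivity"]]))

  # accuracy is the prevalence-weighted mix of sensitivity and specificity
  set.seed(9)
  for (k in 1:20) {
    cnt <- sample(1:50, 4)
    m <- classification_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    npos <- cnt[1] + cnt[4]; nneg <- cnt[2] + cnt[3]
    expect_equal(m[["accuracy"]],
                 (npos * m[["sensitivity"]] + nneg * m[["specificity"]]) /
                   (npos + nneg))
  }
})

test_that("AUC equals the brute-force concordant-pair statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)

  pair_count_auc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(13)
  for (k in 1:10) {
    sc <- round(runif(40), 1)            # coarse grid forces ties
    lb <- rbinom(40, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), pair_count_auc(sc, lb), tolerance = 1e-12)
  }

  set.seed(14)
  sc <- runif(4000); lb <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_auc(sc, lb) - 0.5), 0.05)    # null AUC
  expect_error(roc_auc(runif(5), c(1, 1, 1, 1, 1)), "both classes")
})

test_that("reconstruction report aggregates the suite", {
  ref <- rand_cube(8, 8, 4, seed = 31)
  gen <- hsi_cube(ref$values + array(rnorm(256, 0, 0.02), c(8, 8, 4)))
  rep <- reconstruction_report(ref, gen)
  expect_true(rep$psnr_db > 20)
  expect_equal(rep$mae_pct, rep$mae * 100)
  expect_length(rep$psnr_per_band, 4L)
  expect_true(rep$sam_deg >= 0 && rep$sam_deg <= 180)
})
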