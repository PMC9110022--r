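# The unsupervised fusion network: stacking, architecture contracts, losses,
# training behaviour.

test_that("RGB stacking duplicates channels in wavelength-ascending blocks", {
  px <- rgb_image(array(rep(c(0.2, 0.5, 0.8), each = 4), c(2, 2, 3)))
  st <- stack_rgb(px, counts = c(35L, 35L, 17L))
  expect_equal(dim(st)[3L], 87L)
  vals <- st[1, 1, ]
  expect_equal(as.numeric(table(vals)[c("0.2", "0.5", "0.8")]),
               c(35, 35, 17))                       # R, G, B multiplicities
  expect_equal(vals[1:17], rep(0.8, 17))            # blue block first
  expect_equal(vals[18:52], rep(0.5, 35))           # then green
  expect_equal(vals[53:87], rep(0.2, 35))           # then red

  st3 <- stack_rgb(px, counts = c(1L, 1L, 1L))
  expect_equal(st3[, , c(3, 2, 1)], px$values)      # b,g,r order
  expect_error(srr_config(n_bands = 87L, counts = c(35L, 35L, 18L)),
               "sum")
})

test_that("configuration invariants are enforced", {
  expect_error(srr_config(scale = 3L, w = 200L), "divisible by scale")
  expect_error(srr_config(scale = 2L, w = 18L), "divisible by 4")
  expect_error(srr_config(loss_weights = c(0.7, 0.5)), "sum to 1")
  cfg <- srr_config(n_bands = 8L)
  expect_equal(sum(cfg$counts), 8L)
})

test_that("the network realizes the reference shapes at full width", {
  # traced shapes only; no weight allocation at reference scale
  m4 <- build_srr(srr_config(scale = 4L, w = 200L, n_bands = 87L),
                  init_weights = FALSE)
  g <- m4$graph
  expect_equal(hsifuse:::nn_shape(g, m4$hr_id), c(200, 200, 87))
  expect_equal(hsifuse:::nn_shape(g, m4$lr_id), c(50, 50, 87))
  expect_equal(hsifuse:::nn_shape(g, m4$in_lr), c(50, 50, 87))
  # encoder/decoder widths follow the printed table
  widths <- vapply(g$nodes, function(n)
    if (n$op %in% c("conv", "conv_t")) n$out_shape[3L] else NA_integer_,
    0)
  expect_equal(widths[!is.na(widths)],
               c(87, 196, 256, 384, 512, 640, 768, 768, 640, 512, 256,
                 256, 194, 160, 128, 96, 87))

  m5 <- build_srr(srr_config(scale = 5L, w = 200L, n_bands = 87L),
                  init_weights = FALSE)
  expect_equal(hsifuse:::nn_shape(m5$graph, m5$lr_id), c(40, 40, 87))

  # toy scale: actual forward pass obeys the shape contract
  cfg <- srr_config(scale = 2L, w = 16L, n_bands = 6L,
                    counts = c(2L, 2L, 2L), kappa = 0.05, seed = 1L)
  m <- build_srr(cfg)
  out <- srr_forward(m, array(runif(8 * 8 * 6), c(8, 8, 6)),
                     array(runif(16 * 16 * 3), c(16, 16, 3)))
  expect_equal(dim(out$hr), c(16, 16, 6))
  expect_equal(dim(out$lr), c(8, 8, 6))
})

test_that("loss components follow their closed forms", {
  a <- array(runif(2 * 2 * 3), c(2, 2, 3))
  expect_equal(spatial_loss(a, a), 0)
  expect_equal(spatial_loss(array(1, c(2, 2, 3)), array(0, c(2, 2, 3))), 1)
  b <- array(runif(2 * 2 * 3), c(2, 2, 3))
  G <- apply(a, 1:2, mean); Gh <- apply(b, 1:2, mean)
  hand <- sum((G - Gh)^2) / 4
  expect_equal(spatial_loss(a, b), hand)

  expect_equal(spectral_loss(a, a), 0)
  expect_equal(spectral_loss(a, a + 0.1), 0.01)
  hand3 <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:3)
    hand3 <- hand3 + (a[i, j, k] - b[i, j, k])^2
  expect_equal(spectral_loss(a, b), hand3 / 12)

  expect_equal(total_loss(0.2, 0.4), 0.3)
  expect_equal(total_loss(1, 0), 0.5)
  expect_equal(total_loss(0.37, 0.37, c(0.3, 0.7)), 0.37)
})

test_that("the average-pool head equals box downsampling of the output", {
  cfg <- toy_srr_config(seed = 3L)
  m <- build_srr(cfg)
  set.seed(99)
  for (k in 1:20) {
    lr <- array(runif(4 * 4 * 6), c(4, 4, 6))
    rgb <- array(runif(16 * 16 * 3), c(16, 16, 3))
    out <- srr_forward(m, lr, rgb)
    expect_equal(out$lr, box_downsample(out$hr, 4L), tolerance = 1e-12)
  }
})

test_that("loss operators agree with the preprocessing degradation", {
  hr <- rand_cube(16, 16, 6, seed = 41)
  lr <- box_downsample(hr, 4L)
  # if the generated cube equals the truth, the spectral loss of its pooled
  # version against a box-downsampled input is exactly zero
  expect_equal(spectral_loss(box_downsample(hr$values, 4L), lr$values), 0)
})

test_that("evaluation loss is invariant to patch order and gradients are
           finite", {
  patches <- toy_patch_set(n = 4L, seed = 5L)
  cfg <- toy_srr_config(seed = 2L)
  m <- build_srr(cfg)
  l1 <- hsifuse:::srr_eval_loss(m, patches)
  l2 <- hsifuse:::srr_eval_loss(m, rev(patches))
  expect_equal(l1, l2)

  p <- patches[[1L]]
  st <- stack_rgb(p$hr_rgb$values, cfg$counts)
  ins <- list()
  ins[[as.character(m$in_lr)]] <- p$lr_hsi$values
  ins[[as.character(m$in_rgb)]] <- st
  a <- hsifuse:::nn_forward(m$graph, ins, train = TRUE)
  seeds <- list()
  seeds[[as.character(m$hr_id)]] <- array(1e-3, c(16, 16, 6))
  seeds[[as.character(m$lr_id)]] <- array(1e-3, c(4, 4, 6))
  bw <- hsifuse:::nn_backward(m$graph, a, seeds)
  fg <- hsifuse:::nn_flat_grads(m$graph, bw$params)
  expect_true(all(vapply(fg, function(x) all(is.finite(x)), TRUE)))
})

test_that("training is reproducible, improves the objective, and stops
           early", {
  patches <- toy_patch_set(n = 6L, seed = 9L)
  val <- toy_patch_set(n = 2L, seed = 77L)
  cfg <- toy_srr_config(seed = 4L, max_epochs = 4L, patience = 2L)

  f1 <- train_srr(patches, cfg, val)
  f2 <- train_srr(patches, cfg, val)
  expect_identical(f1$history, f2$history)
  expect_lt(min(f1$history$val_loss), f1$history$val_loss[1L])

  # early stopping: training never runs more than patience epochs past the
  # best validation epoch, within the epoch budget
  expect_lte(nrow(f1$history),
             min(cfg$max_epochs, f1$best_epoch + cfg$patience))
  expect_equal(f1$best_epoch, which.min(f1$history$val_loss))

  expect_error(train_srr(list(), cfg, val), "empty")
  bad <- toy_patch_set(n = 1L, w = 32L, b = 6L)
  expect_error(train_srr(bad, cfg, val), "inconsistent")
})

test_that("reconstruction honours shapes, clamping and checkpoints", {
  cfg <- toy_srr_config(seed = 6L)
  m <- build_srr(cfg)
  p <- toy_patch_set(n = 1L, seed = 13L)[[1L]]
  rec <- reconstruct(p$lr_hsi, p$hr_rgb, m)
  expect_equal(dim(rec$values), c(16L, 16L, 6L))
  expect_true(all(rec$values >= 0 & rec$values <= cfg$clamp_max))
  expect_error(reconstruct(rand_cube(3, 3, 6), p$hr_rgb, m), "inconsistent")

  # untrained model with a fixed seed is deterministic
  m2 <- build_srr(cfg)
  expect_identical(reconstruct(p$lr_hsi, p$hr_rgb, m2)$values, rec$values)

  f <- tempfile(fileext = ".rds")
  save_srr(m, f)
  m3 <- load_srr(f)
  expect_identical(reconstruct(p$lr_hsi, p$hr_rgb, m3)$values, rec$values)
})
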