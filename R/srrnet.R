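#' Configuration of the super-resolution reconstruction network
#'
#' The reference architecture reconstructs 200 x 200 x 87 hyperspectral
#' patches from a low-resolution hyperspectral input (scale S in
#' 2, 4, 5, 8, 10) under high-resolution RGB guidance.  The three RGB
#' channels are duplicated `counts` times (default 35, 35, 17 for R, G, B;
#' blue least because the spectral range starts at 470 nm) and stacked into a
#' B-band image.  `kappa` scales every internal channel width to
#' `ceiling(kappa * width)` so the same architecture runs at desk scale;
#' `kappa = 1` reproduces the reference widths exactly.
#'
#' @param scale spatial enhancement factor S.
#' @param w patch size in pixels (must be divisible by `scale` and by 4,
#'   for the two stride-2 encoder stages).
#' @param n_bands band count B.
#' @param counts length-3 integer (R, G, B duplication counts), summing to
#'   `n_bands`.
#' @param kappa width multiplier in (0, 1].
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size minibatch size (default 2).
#' @param loss_weights length-2 (spatial, spectral) loss weights, summing
#'   to 1 (default 0.5, 0.5).
#' @param max_epochs training epoch budget (default 13).
#' @param patience early-stopping patience on validation total loss
#'   (default 2).
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @param clamp_max transmittance ceiling applied at inference.
#' @param output_bias_init initial bias of the final 1 x 1 convolution
#'   (default 0.7, a typical stained-tissue transmittance); weights remain
#'   Glorot-uniform.
#' @return object of class `srr_config`.
#' @export
srr_config <- function(scale = 4L, w = 200L, n_bands = 87L,
                       counts = NULL, kappa = 1,
                       lr = 1e-4, batch_size = 2L,
                       loss_weights = c(0.5, 0.5),
                       max_epochs = 13L, patience = 2L, seed = 1L,
                       clamp_max = 1.2, output_bias_init = 0.7) {
  scale <- as.integer(scale); w <- as.integer(w)
  n_bands <- as.integer(n_bands)
  if (is.null(counts)) {
    counts <- if (n_bands == 87L) c(35L, 35L, 17L)
              else default_stack_counts(n_bands)
  }
  counts <- as.integer(counts)
  stopifnot(length(counts) == 3L, all(counts > 0L))
  if (sum(counts) != n_bands)
    stop("duplication counts must sum to the band count (",
         sum(counts), " != ", n_bands, ")")
  if (w %% scale != 0L) stop("patch size must be divisible by scale")
  if (w %% 4L != 0L)
    stop("patch size must be divisible by 4 (two stride-2 stages)")
  stopifnot(kappa > 0, kappa <= 1, length(loss_weights) == 2L,
            all(loss_weights >= 0))
  if (abs(sum(loss_weights) - 1) > 1e-9)
    stop("loss weights must sum to 1")
  structure(list(scale = scale, w = w, n_bands = n_bands, counts = counts,
                 kappa = kappa, lr = lr, batch_size = as.integer(batch_size),
                 loss_weights = loss_weights,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 clamp_max = clamp_max,
                 output_bias_init = output_bias_init),
            class = "srr_config")
}

# R/G/B duplication counts for non-default band counts, keeping the
# reference 35/35/17 proportions (blue smallest) and summing to B
default_stack_counts <- function(n_bands) {
  raw <- n_bands * c(35, 35, 17) / 87
  cnt <- floor(raw)
  rem <- n_bands - sum(cnt)
  ord <- order(raw - cnt, decreasing = TRUE)
  cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
  as.integer(cnt)
}

#' Stack an RGB image into a pseudo-hyperspectral band stack
#'
#' Each colour channel is duplicated `counts` times and the blocks are laid
#' out contiguously in wavelength-ascending order (blue block first, then
#' green, then red, matching a 470 -> 720 nm grid).
#'
#' @param rgb [rgb_image] or H x W x 3 array.
#' @param counts length-3 integer duplication counts for (R, G, B).
#' @param order channel block order, default `c("b", "g", "r")`
#'   (wavelength-ascending).
#' @return H x W x sum(counts) array.
#' @export
stack_rgb <- function(rgb, counts = c(35L, 35L, 17L),
                      order = c("b", "g", "r")) {
  v <- if (inherits(rgb, "rgb_image")) rgb$values else rgb
  stopifnot(length(dim(v)) == 3L, dim(v)[3L] == 3L, length(counts) == 3L,
            all(counts > 0L))
  names(counts) <- c("r", "g", "b")
  chan <- c(r = 1L, g = 2L, b = 3L)
  idx <- unlist(lapply(order, function(ch) rep(chan[[ch]], counts[[ch]])),
                use.names = FALSE)
  v[, , idx, drop = FALSE]
}

srr_widths <- function(kappa) {
  k <- function(w) as.integer(ceiling(kappa * w))
  list(enc = c(k(196), k(256), k(384), k(512), k(640), k(768)),
       dec_t1 = k(768), dec1 = c(k(640), k(512)),
       dec_t2 = k(256), dec2 = c(k(256), k(194), k(160), k(128), k(96)))
}

#' Build the super-resolution reconstruction network
#'
#' Realizes the reference layer table: a transposed convolution
#' ((S+1) x (S+1), stride S, 'same') upsamples the low-resolution
#' hyperspectral input to the patch grid; it is concatenated with the
#' stacked RGB along the spectral axis; a U-Net-style encoder-decoder
#' (widths 196, 256, 384/s2, 512, 640/s2, 768; transposed-conv upsampling
#' with skip concatenations; widths 640, 512, 256, 194, 160, 128, 96)
#' produces the generated high-resolution cube through a linear 1 x 1
#' convolution; an S x S average pool (stride S, 'valid') forms the
#' generated low-resolution output.  All hidden convolutions are ReLU,
#' Glorot-uniform initialized under `config$seed`.
#'
#' @param config an [srr_config].
#' @param init_weights set `FALSE` to build the graph for shape tracing
#'   only (no parameter allocation).
#' @return object of class `srr_model`: list with the computation graph and
#'   node bookkeeping.
#' @export
build_srr <- function(config, init_weights = TRUE) {
  stopifnot(inherits(config, "srr_config"))
  S <- config$scale; w <- config$w; B <- config$n_bands
  wd <- srr_widths(config$kappa)
  set.seed(config$seed)
  g <- nn_graph(init = "glorot_uniform", init_weights = init_weights)
  in_lr <- nn_input(g, c(w %/% S, w %/% S, B))
  in_rgb <- nn_input(g, c(w, w, B))     # stacked RGB
  up <- nn_conv_transpose(g, in_lr, B, kernel = c(S + 1L, S + 1L),
                          stride = S, activation = "relu")
  cat0 <- nn_concat(g, c(up, in_rgb))
  e1 <- nn_conv(g, cat0, wd$enc[1L])
  e2 <- nn_conv(g, e1, wd$enc[2L])                 # skip -> d2
  e3 <- nn_conv(g, e2, wd$enc[3L], stride = 2L)
  e4 <- nn_conv(g, e3, wd$enc[4L])                 # skip -> d1
  e5 <- nn_conv(g, e4, wd$enc[5L], stride = 2L)
  e6 <- nn_conv(g, e5, wd$enc[6L])
  t1 <- nn_conv_transpose(g, e6, wd$dec_t1, stride = 2L)
  c1 <- nn_concat(g, c(t1, e4))
  d1 <- nn_conv(g, c1, wd$dec1[1L])
  d2 <- nn_conv(g, d1, wd$dec1[2L])
  t2 <- nn_conv_transpose(g, d2, wd$dec_t2, stride = 2L)
  c2 <- nn_concat(g, c(t2, e2))
  d3 <- nn_conv(g, c2, wd$dec2[1L])
  d4 <- nn_conv(g, d3, wd$dec2[2L])
  d5 <- nn_conv(g, d4, wd$dec2[3L])
  d6 <- nn_conv(g, d5, wd$dec2[4L])
  d7 <- nn_conv(g, d6, wd$dec2[5L])
  hr <- nn_conv(g, d7, B, kernel = c(1L, 1L), activation = "linear")
  lr_out <- nn_avgpool(g, hr, S)
  if (init_weights) {
    # regression-head bias starts at the typical tissue transmittance so
    # the optimizer spends its steps on structure rather than on reaching
    # the output scale from zero
    g$nodes[[hr]]$params$b[] <- config$output_bias_init
  }
  structure(list(graph = g, config = config,
                 in_lr = in_lr, in_rgb = in_rgb,
                 hr_id = hr, lr_id = lr_out),
            class = "srr_model")
}

#' @export
print.srr_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<srr_model> scale %dx, patch %d px, %d bands, kappa %.3g, %d parameters\n",
    cfg$scale, cfg$w, cfg$n_bands, cfg$kappa,
    if (x$graph$init_weights) nn_n_params(x$graph) else NA_integer_))
  invisible(x)
}

#' Forward pass of the SRR network
#'
#' @param model [build_srr()] output.
#' @param lr (w/S) x (w/S) x B array or [hsi_cube].
#' @param rgb w x w x 3 array or [rgb_image] (stacked internally), or an
#'   already-stacked w x w x B array.
#' @param acts return the full activation list instead of outputs.
#' @return list with `hr` (w x w x B) and `lr` ((w/S) x (w/S) x B) arrays.
#' @export
srr_forward <- function(model, lr, rgb, acts = FALSE) {
  lrv <- if (is_hsi_cube(lr)) lr$values else lr
  rv <- if (inherits(rgb, "rgb_image")) rgb$values else rgb
  if (dim(rv)[3L] == 3L)
    rv <- stack_rgb(rv, model$config$counts)
  ins <- list()
  ins[[as.character(model$in_lr)]] <- lrv
  ins[[as.character(model$in_rgb)]] <- rv
  a <- nn_forward(model$graph, ins, train = FALSE)
  if (acts) return(a)
  list(hr = a[[model$hr_id]], lr = a[[model$lr_id]])
}

#' Spatial loss
#'
#' Both the stacked RGB input and the generated high-resolution cube are
#' averaged along the spectral dimension into panchromatic images G and
#' G-hat; the loss is their mean squared difference
#' `1/(M N) * sum (G - Ghat)^2`.
#'
#' @param stacked_rgb w x w x B array (stacked RGB).
#' @param generated_hr w x w x B array.
#' @return scalar.
#' @export
spatial_loss <- function(stacked_rgb, generated_hr) {
  if (!identical(dim(stacked_rgb)[1:2], dim(generated_hr)[1:2]))
    stop("spatial shapes differ")
  G <- panchromatic(stacked_rgb)
  Gh <- panchromatic(generated_hr)
  mean((G - Gh)^2)
}

#' Spectral loss
#'
#' Mean squared error between the generated and input low-resolution
#' hyperspectral cubes, averaged over all `m * n * b` voxels.
#'
#' @param generated_lr,input_lr (m x n x b) arrays or [hsi_cube]s.
#' @return scalar.
#' @export
spectral_loss <- function(generated_lr, input_lr) {
  a <- if (is_hsi_cube(generated_lr)) generated_lr$values else generated_lr
  b <- if (is_hsi_cube(input_lr)) input_lr$values else input_lr
  if (!identical(dim(a), dim(b))) stop("shapes differ")
  mean((a - b)^2)
}

#' Weighted total loss
#'
#' @param spatial,spectral scalar loss components.
#' @param weights length-2 nonnegative weights (spatial, spectral).
#' @return scalar `weights[1]*spatial + weights[2]*spectral`.
#' @export
total_loss <- function(spatial, spectral, weights = c(0.5, 0.5)) {
  stopifnot(all(weights >= 0))
  weights[1L] * spatial + weights[2L] * spectral
}

srr_eval_loss <- function(model, patches) {
  cfg <- model$config
  tot <- 0
  for (p in patches) {
    st <- stack_rgb(p$hr_rgb$values, cfg$counts)
    out <- srr_forward(model, p$lr_hsi$values, st)
    tot <- tot + total_loss(spatial_loss(st, out$hr),
                            spectral_loss(out$lr, p$lr_hsi$values),
                            cfg$loss_weights)
  }
  tot / length(patches)
}

#' Train the unsupervised SRR network
#'
#' Minimizes the weighted sum of the spatial loss (panchromatic agreement
#' with the stacked RGB) and the spectral loss (agreement of the
#' average-pooled output with the low-resolution input) with Adam.  No
#' high-resolution hyperspectral reference enters the objective.  Training
#' stops early when the validation total loss has not improved for
#' `config$patience` epochs; the best-validation parameters are restored.
#' Fully deterministic given `config$seed`.
#'
#' @param patches list of [patch_pair] training units (the `hr_hsi` member
#'   is unused by the objective).
#' @param config [srr_config].
#' @param val_patches validation patch list for early stopping.
#' @param verbose print per-epoch losses.
#' @return list with `model` ([srr_model], best-validation weights) and
#'   `history` (data.frame: epoch, train_loss, val_loss).
#' @export
train_srr <- function(patches, config, val_patches, verbose = FALSE) {
  stopifnot(inherits(config, "srr_config"))
  if (length(patches) == 0L) stop("empty training set")
  cfg <- config
  for (p in c(patches, val_patches)) {
    d <- dim(p$hr_hsi$values)
    if (d[1L] != cfg$w || d[3L] != cfg$n_bands ||
        dim(p$lr_hsi$values)[1L] != cfg$w %/% cfg$scale)
      stop("patch dimensions inconsistent with config")
  }
  model <- build_srr(cfg)          # seeds RNG with cfg$seed, inits weights
  g <- model$graph
  opt <- optimizer_adam(lr = cfg$lr)
  stacked <- lapply(patches, function(p) stack_rgb(p$hr_rgb$values,
                                                   cfg$counts))
  n <- length(patches)
  hist_tr <- numeric(0); hist_val <- numeric(0)
  best_val <- Inf; best_params <- nn_params(g); best_epoch <- 0L
  wait <- 0L
  npix_hr <- cfg$w^2
  nvox_lr <- (cfg$w %/% cfg$scale)^2 * cfg$n_bands
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    i <- 1L
    while (i <= n) {
      bidx <- ord[i:min(i + cfg$batch_size - 1L, n)]
      gsum <- NULL
      for (j in bidx) {
        p <- patches[[j]]
        st <- stacked[[j]]
        ins <- list()
        ins[[as.character(model$in_lr)]] <- p$lr_hsi$values
        ins[[as.character(model$in_rgb)]] <- st
        a <- nn_forward(g, ins, train = TRUE)
        hr <- a[[model$hr_id]]; lrg <- a[[model$lr_id]]
        Ls <- spatial_loss(st, hr)
        Lp <- spectral_loss(lrg, p$lr_hsi$values)
        L <- total_loss(Ls, Lp, cfg$loss_weights)
        if (!is.finite(L))
          stop("non-finite loss at epoch ", epoch, " (spatial = ", Ls,
               ", spectral = ", Lp, ")")
        ep_loss <- ep_loss + L
        # seed gradients: spatial term through the HR head (band-mean),
        # spectral term through the average-pool LR head
        G <- panchromatic(st); Gh <- panchromatic(hr)
        dG <- cfg$loss_weights[1L] * 2 * (Gh - G) / npix_hr
        dhr <- array(dG / cfg$n_bands,
                     c(dim(dG), cfg$n_bands))
        dlr <- cfg$loss_weights[2L] * 2 * (lrg - p$lr_hsi$values) / nvox_lr
        seeds <- list()
        seeds[[as.character(model$hr_id)]] <- dhr
        seeds[[as.character(model$lr_id)]] <- dlr
        bw <- nn_backward(g, a, seeds)
        fg <- nn_flat_grads(g, bw$params)
        gsum <- if (is.null(gsum)) fg
                else mapply(`+`, gsum, fg, SIMPLIFY = FALSE)
      }
      gavg <- lapply(gsum, `/`, length(bidx))
      nn_set_params(g, opt$step(nn_params(g), gavg))
      i <- i + cfg$batch_size
    }
    tr <- ep_loss / n
    val <- srr_eval_loss(model, val_patches)
    hist_tr <- c(hist_tr, tr); hist_val <- c(hist_val, val)
    if (verbose)
      message(sprintf("epoch %d: train %.6f  val %.6f", epoch, tr, val))
    if (val < best_val - 1e-12) {
      best_val <- val; best_params <- nn_params(g); best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  nn_set_params(g, best_params)
  list(model = model,
       history = data.frame(epoch = seq_along(hist_tr),
                            train_loss = hist_tr, val_loss = hist_val),
       best_epoch = best_epoch)
}

#' Reconstruct a high-resolution cube
#'
#' Runs the trained network on a low-resolution hyperspectral cube and its
#' registered RGB guidance; the low-resolution head is discarded and the
#' generated cube is clamped to \[0, clamp_max\].
#'
#' @param lr [hsi_cube] (or array), (w/S) x (w/S) x B.
#' @param rgb [rgb_image] (or array), w x w x 3.
#' @param model trained [srr_model].
#' @return [hsi_cube] of size w x w x B.
#' @export
reconstruct <- function(lr, rgb, model) {
  cfg <- model$config
  lrv <- if (is_hsi_cube(lr)) lr$values else lr
  d <- dim(lrv)
  if (d[1L] != cfg$w %/% cfg$scale || d[3L] != cfg$n_bands)
    stop("lr cube shape inconsistent with model config")
  t0 <- proc.time()[["elapsed"]]
  out <- srr_forward(model, lrv, rgb)
  hr <- pmin(pmax(out$hr, 0), cfg$clamp_max)
  wl <- if (is_hsi_cube(lr)) lr$wavelengths else default_wavelengths(cfg$n_bands)
  hsi_cube(hr, wavelengths = wl,
           meta = list(reconstructed = TRUE, scale = cfg$scale,
                       runtime_s = proc.time()[["elapsed"]] - t0))
}

#' Save / load an SRR model checkpoint
#'
#' Checkpoints carry the configuration and the flat parameter list; loading
#' rebuilds the graph and restores the parameters.
#'
#' @param model [srr_model].
#' @param path destination `.rds` path.
#' @return `path` / the restored [srr_model].
#' @export
save_srr <- function(model, path) {
  saveRDS(list(config = model$config, params = nn_params(model$graph)),
          path)
  invisible(path)
}

#' @rdname save_srr
#' @export
load_srr <- function(path) {
  ck <- readRDS(path)
  model <- build_srr(ck$config)
  nn_set_params(model$graph, ck$params)
  model
}
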