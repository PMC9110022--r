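#' Configuration of the patch classifier
#'
#' An Inception-v4-style convolutional classifier adapted to square
#' histology patches: a three-convolution stem (stride-2 'same' stages
#' taking 200 -> 100 -> 50 -> 25 px at reference scale), 4 Inception-A
#' blocks, Reduction-A, 7 Inception-B blocks, Reduction-B, 3 Inception-C
#' blocks, global average pooling and a 2-neuron sigmoid head.  Every
#' convolution is he_normal-initialized, ReLU-activated and followed by
#' dropout.  `kappa` scales all block widths for desk-scale runs.
#'
#' @param input_shape length-3 (w, w, C); C is 3 for RGB input or the band
#'   count for hyperspectral input.  w must be divisible by 8 (three
#'   stride-2 stem stages).
#' @param dropout dropout rate after each convolution (default 0.2).
#' @param lr,rho Adadelta learning rate and decay (defaults 1.0, 0.95).
#' @param batch_size minibatch size (default 16).
#' @param epochs training epochs (default 10).
#' @param kappa width multiplier in (0, 1].
#' @param seed RNG seed.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(input_shape = c(200L, 200L, 87L),
                              dropout = 0.2, lr = 1.0, rho = 0.95,
                              batch_size = 16L, epochs = 10L,
                              kappa = 1, seed = 1L) {
  stopifnot(length(input_shape) == 3L, input_shape[1L] == input_shape[2L],
            dropout >= 0, dropout < 1, kappa > 0, kappa <= 1)
  if (input_shape[1L] %% 8L != 0L)
    stop("input spatial size must be divisible by 8 ",
         "(three stride-2 stem stages)")
  structure(list(input_shape = as.integer(input_shape), dropout = dropout,
                 lr = lr, rho = rho, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), kappa = kappa,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# conv + ReLU + dropout unit used throughout the classifier
cls_conv <- function(g, input, filters, kernel = c(3L, 3L), stride = 1L,
                     padding = "same", rate = 0.2) {
  cv <- nn_conv(g, input, filters, kernel = kernel, stride = stride,
                padding = padding, activation = "relu")
  nn_dropout(g, cv, rate)
}

inception_a <- function(g, x, k, rate) {
  b1 <- cls_conv(g, nn_avgpool3_same(g, x), k(96), c(1L, 1L), rate = rate)
  b2 <- cls_conv(g, x, k(96), c(1L, 1L), rate = rate)
  b3 <- cls_conv(g, cls_conv(g, x, k(64), c(1L, 1L), rate = rate),
                 k(96), rate = rate)
  b4 <- cls_conv(g, cls_conv(g, cls_conv(g, x, k(64), c(1L, 1L),
                                         rate = rate),
                             k(96), rate = rate),
                 k(96), rate = rate)
  nn_concat(g, c(b1, b2, b3, b4))
}

reduction_a <- function(g, x, k, rate) {
  x <- nn_crop_even(g, x)
  b1 <- nn_maxpool(g, x)
  b2 <- cls_conv(g, x, k(384), stride = 2L, padding = "valid", rate = rate)
  b3 <- cls_conv(g, cls_conv(g, cls_conv(g, x, k(192), c(1L, 1L),
                                         rate = rate),
                             k(224), rate = rate),
                 k(256), stride = 2L, padding = "valid", rate = rate)
  nn_concat(g, c(b1, b2, b3))
}

inception_b <- function(g, x, k, rate) {
  b1 <- cls_conv(g, nn_avgpool3_same(g, x), k(128), c(1L, 1L), rate = rate)
  b2 <- cls_conv(g, x, k(384), c(1L, 1L), rate = rate)
  b3 <- cls_conv(g, cls_conv(g, cls_conv(g, x, k(192), c(1L, 1L),
                                         rate = rate),
                             k(224), c(1L, 7L), rate = rate),
                 k(256), c(7L, 1L), rate = rate)
  b4 <- x
  for (spec in list(list(k(192), c(1L, 1L)), list(k(192), c(1L, 7L)),
                    list(k(224), c(7L, 1L)), list(k(224), c(1L, 7L)),
                    list(k(256), c(7L, 1L))))
    b4 <- cls_conv(g, b4, spec[[1L]], spec[[2L]], rate = rate)
  nn_concat(g, c(b1, b2, b3, b4))
}

reduction_b <- function(g, x, k, rate) {
  b1 <- nn_maxpool(g, x)
  b2 <- cls_conv(g, cls_conv(g, x, k(192), c(1L, 1L), rate = rate),
                 k(192), stride = 2L, padding = "valid", rate = rate)
  b3 <- x
  for (spec in list(list(k(256), c(1L, 1L)), list(k(256), c(1L, 7L)),
                    list(k(320), c(7L, 1L))))
    b3 <- cls_conv(g, b3, spec[[1L]], spec[[2L]], rate = rate)
  b3 <- cls_conv(g, b3, k(320), stride = 2L, padding = "valid", rate = rate)
  nn_concat(g, c(b1, b2, b3))
}

inception_c <- function(g, x, k, rate) {
  b1 <- cls_conv(g, nn_avgpool3_same(g, x), k(256), c(1L, 1L), rate = rate)
  b2 <- cls_conv(g, x, k(256), c(1L, 1L), rate = rate)
  s3 <- cls_conv(g, x, k(384), c(1L, 1L), rate = rate)
  b3a <- cls_conv(g, s3, k(256), c(1L, 3L), rate = rate)
  b3b <- cls_conv(g, s3, k(256), c(3L, 1L), rate = rate)
  s4 <- cls_conv(g, cls_conv(g, cls_conv(g, x, k(384), c(1L, 1L),
                                         rate = rate),
                             k(448), c(1L, 3L), rate = rate),
                 k(512), c(3L, 1L), rate = rate)
  b4a <- cls_conv(g, s4, k(256), c(3L, 1L), rate = rate)
  b4b <- cls_conv(g, s4, k(256), c(1L, 3L), rate = rate)
  nn_concat(g, c(b1, b2, b3a, b3b, b4a, b4b))
}

#' Build the Inception-style patch classifier
#'
#' @param config [classifier_config].
#' @param init_weights `FALSE` builds the graph for shape tracing only.
#' @return object of class `patch_classifier` (graph + node bookkeeping).
#'   `$trace` gives the output shape of every block for inspection.
#' @export
build_classifier <- function(config, init_weights = TRUE) {
  stopifnot(inherits(config, "classifier_config"))
  set.seed(config$seed)
  k <- function(wd) as.integer(ceiling(config$kappa * wd))
  rate <- config$dropout
  g <- nn_graph(init = "he_normal", init_weights = init_weights)
  inp <- nn_input(g, config$input_shape)
  trace <- list(input = config$input_shape)
  x <- cls_conv(g, inp, k(90), stride = 2L, rate = rate)
  x <- cls_conv(g, x, k(94), stride = 2L, rate = rate)
  x <- cls_conv(g, x, k(96), stride = 2L, rate = rate)
  trace$stem <- nn_shape(g, x)
  for (i in 1:4) x <- inception_a(g, x, k, rate)
  trace$inception_a <- nn_shape(g, x)
  x <- reduction_a(g, x, k, rate)
  trace$reduction_a <- nn_shape(g, x)
  for (i in 1:7) x <- inception_b(g, x, k, rate)
  trace$inception_b <- nn_shape(g, x)
  x <- reduction_b(g, x, k, rate)
  trace$reduction_b <- nn_shape(g, x)
  for (i in 1:3) x <- inception_c(g, x, k, rate)
  trace$inception_c <- nn_shape(g, x)
  sp <- nn_shape(g, x)
  if (sp[1L] < 1L) stop("input spatial size incompatible with the network")
  x <- nn_avgpool(g, x, sp[1L])          # global average pool
  trace$avgpool <- nn_shape(g, x)
  fl <- nn_flatten(g, x)
  out <- nn_dense(g, fl, 2L, activation = "sigmoid")
  structure(list(graph = g, config = config, in_id = inp, out_id = out,
                 trace = trace),
            class = "patch_classifier")
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat(sprintf("<patch_classifier> input %s, kappa %.3g\n",
              paste(x$config$input_shape, collapse = "x"),
              x$config$kappa))
  invisible(x)
}

cls_input_array <- function(x) {
  if (is_hsi_cube(x)) x$values
  else if (inherits(x, "rgb_image")) x$values
  else x
}

#' Predict class probabilities
#'
#' The two sigmoid neurons estimate P(normal) and P(tumour) independently
#' (they need not sum to 1); class calls take the larger neuron, ROC
#' analysis uses the tumour neuron.
#'
#' @param model [build_classifier()] output (trained).
#' @param x list of patches ([hsi_cube] / [rgb_image] / arrays).
#' @return n x 2 matrix of probabilities (columns: normal, tumour).
#' @export
predict_classifier <- function(model, x) {
  if (!is.list(x)) x <- list(x)
  out <- matrix(0, length(x), 2L,
                dimnames = list(NULL, c("normal", "tumour")))
  for (i in seq_along(x)) {
    ins <- list()
    ins[[as.character(model$in_id)]] <- cls_input_array(x[[i]])
    a <- nn_forward(model$graph, ins, train = FALSE)
    out[i, ] <- a[[model$out_id]]
  }
  out
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the patch classifier
#'
#' Binary cross-entropy on one-hot targets over the two sigmoid neurons,
#' Adadelta optimizer, seeded and reproducible.  When patient identifiers
#' are supplied for both splits, any overlap raises an error (patch-level
#' splits from the same patient leak appearance and stain characteristics
#' between groups).
#'
#' @param x list of training patches; `labels` 0/1 vector.
#' @param config [classifier_config].
#' @param val_x,val_labels validation split (optional; used to pick the
#'   best checkpoint).
#' @param patients,val_patients optional patient identifiers parallel to
#'   `x` / `val_x`.
#' @param verbose print per-epoch metrics.
#' @return list with `model` (best-validation weights when a validation
#'   split is given, else final weights) and `history` (data.frame: epoch,
#'   train_loss, train_acc, val_loss, val_acc).
#' @export
train_classifier <- function(x, labels, config, val_x = NULL,
                             val_labels = NULL, patients = NULL,
                             val_patients = NULL, verbose = FALSE) {
  stopifnot(length(x) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the training data")
  if (!is.null(patients) && !is.null(val_patients)) {
    ov <- intersect(unique(patients), unique(val_patients))
    if (length(ov))
      stop("patient-level partition violated: patient(s) ",
           paste(ov, collapse = ", "), " appear in both splits")
  }
  cfg <- config
  model <- build_classifier(cfg)     # seeds RNG, he_normal init
  g <- model$graph
  opt <- optimizer_adadelta(lr = cfg$lr, rho = cfg$rho)
  xs <- lapply(x, cls_input_array)
  onehot <- cbind(normal = as.numeric(labels == 0),
                  tumour = as.numeric(labels == 1))
  n <- length(xs)
  hist <- NULL
  best_val <- Inf; best_params <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_hit <- 0
    i <- 1L
    while (i <= n) {
      bidx <- ord[i:min(i + cfg$batch_size - 1L, n)]
      gsum <- NULL
      for (j in bidx) {
        ins <- list()
        ins[[as.character(model$in_id)]] <- xs[[j]]
        a <- nn_forward(g, ins, train = TRUE)
        p <- a[[model$out_id]]
        y <- onehot[j, ]
        ep_loss <- ep_loss + bce_loss(p, y)
        ep_hit <- ep_hit + (which.max(p) == which.max(y))
        pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
        dp <- (-y / pc + (1 - y) / (1 - pc)) / 2
        seeds <- list()
        seeds[[as.character(model$out_id)]] <- dp
        bw <- nn_backward(g, a, seeds)
        fg <- nn_flat_grads(g, bw$params)
        gsum <- if (is.null(gsum)) fg
                else mapply(`+`, gsum, fg, SIMPLIFY = FALSE)
      }
      gavg <- lapply(gsum, `/`, length(bidx))
      nn_set_params(g, opt$step(nn_params(g), gavg))
      i <- i + cfg$batch_size
    }
    row <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                      train_acc = ep_hit / n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val_x)) {
      pv <- predict_classifier(model, val_x)
      vy <- cbind(as.numeric(val_labels == 0), as.numeric(val_labels == 1))
      row$val_loss <- mean(vapply(seq_len(nrow(pv)),
                                  function(i) bce_loss(pv[i, ], vy[i, ]), 0))
      row$val_acc <- mean(max.col(pv) - 1L == val_labels)
      if (row$val_loss < best_val) {
        best_val <- row$val_loss
        best_params <- nn_params(g)
      }
    }
    hist <- rbind(hist, row)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f acc %.3f val %.4f/%.3f",
                      epoch, row$train_loss, row$train_acc,
                      row$val_loss, row$val_acc))
  }
  if (!is.null(best_params)) nn_set_params(g, best_params)
  list(model = model, history = hist)
}

#' Stitch patch probabilities into a whole-slide map
#'
#' Every slide pixel receives the mean probability of all patches whose
#' window covers it (a 200-px window at 100-px step covers interior pixels
#' up to 4 times); pixels under no patch are `NA`.
#'
#' @param probs numeric vector of patch probabilities in \[0, 1\].
#' @param origins data.frame / matrix with 0-based `row`, `col` patch
#'   origins.
#' @param slide_dims length-2 (rows, cols) of the slide frame.
#' @param w patch window size in pixels.
#' @return list of class `probability_map`: `values` (matrix, `NA` where
#'   uncovered), `coverage` (integer matrix).
#' @export
stitch_probability_map <- function(probs, origins, slide_dims, w = 200L) {
  origins <- as.data.frame(origins)
  stopifnot(length(probs) == nrow(origins),
            all(probs >= 0), all(probs <= 1),
            all(origins$row >= 0), all(origins$col >= 0),
            all(origins$row + w <= slide_dims[1L]),
            all(origins$col + w <= slide_dims[2L]))
  acc <- matrix(0, slide_dims[1L], slide_dims[2L])
  cov <- matrix(0L, slide_dims[1L], slide_dims[2L])
  for (i in seq_along(probs)) {
    ri <- (origins$row[i] + 1L):(origins$row[i] + w)
    ci <- (origins$col[i] + 1L):(origins$col[i] + w)
    acc[ri, ci] <- acc[ri, ci] + probs[i]
    cov[ri, ci] <- cov[ri, ci] + 1L
  }
  vals <- acc / ifelse(cov > 0L, cov, NA_integer_)
  structure(list(values = vals, coverage = cov), class = "probability_map")
}

#' Export a probability map
#'
#' Writes the map as a grayscale float TIFF (uncovered pixels as 0) plus a
#' JSON sidecar `<path>.json` with the coverage matrix and the uncovered
#' mask, so the zeros are recoverable as missing.
#'
#' @param map a `probability_map` from [stitch_probability_map()].
#' @param path destination TIFF path.
#' @return `path`, invisibly.
#' @export
write_probability_map <- function(map, path) {
  stopifnot(inherits(map, "probability_map"))
  v <- map$values
  v[is.na(v)] <- 0
  suppressWarnings(tiff::writeTIFF(v, path, bits.per.sample = 32L))
  jsonlite::write_json(list(coverage = map$coverage,
                            uncovered = which(map$coverage == 0L)),
                       paste0(path, ".json"))
  invisible(path)
}
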