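# Minimal static-shape computation-graph engine for the convolutional models
# in this package.  Tensors are single-sample H x W x C arrays (column-major,
# row fastest); batching is an outer loop with gradient averaging.  Layers:
# conv2d (stride 1/2, 'same'/'valid'), transposed conv2d ('same', output
# stride*H, realized as the adjoint of a strided conv), average pooling
# (block and 3x3/stride-1), max pooling, channel concatenation, dropout,
# flatten, dense.  'same' padding follows the ceil(H/stride) convention with
# the extra pad row/col at the bottom/right.

nn_graph <- function(init = c("glorot_uniform", "he_normal"),
                     init_weights = TRUE) {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$init <- match.arg(init)
  g$init_weights <- init_weights
  class(g) <- "nn_graph"
  g
}

nn_add_node <- function(g, op, inputs, opts, params, out_shape) {
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- list(id = id, op = op, inputs = inputs, opts = opts,
                        params = params, out_shape = out_shape,
                        cache = new.env(parent = emptyenv()))
  id
}

nn_shape <- function(g, id) {
  force(id)   # id may be a call that appends nodes to g; evaluate it first
  g$nodes[[id]]$out_shape
}

init_conv_weights <- function(g, kh, kw, cin, cout, fan_in, fan_out) {
  if (!g$init_weights) return(NULL)
  n <- kh * kw * cin * cout
  w <- if (g$init == "glorot_uniform") {
    lim <- sqrt(6 / (fan_in + fan_out))
    runif(n, -lim, lim)
  } else {
    rnorm(n, 0, sqrt(2 / fan_in))
  }
  array(w, c(kh, kw, cin, cout))
}

nn_input <- function(g, shape) {
  nn_add_node(g, "input", integer(0), list(), NULL, shape)
}

# gather-index table for a (possibly padded) strided convolution window;
# entry 0 denotes a padded position
conv_spatial_index <- function(Hin, Win, kh, kw, stride, padding) {
  if (padding == "same") {
    Hout <- ceiling(Hin / stride); Wout <- ceiling(Win / stride)
    ph <- max((Hout - 1L) * stride + kh - Hin, 0L)
    pw <- max((Wout - 1L) * stride + kw - Win, 0L)
    pt <- ph %/% 2L; pl <- pw %/% 2L
  } else {
    Hout <- (Hin - kh) %/% stride + 1L; Wout <- (Win - kw) %/% stride + 1L
    pt <- 0L; pl <- 0L
  }
  npos <- Hout * Wout
  rows0 <- rep.int(seq.int(0L, by = stride, length.out = Hout), Wout)
  cols0 <- rep(seq.int(0L, by = stride, length.out = Wout), each = Hout)
  Isp <- matrix(0L, npos, kh * kw)
  t <- 0L
  for (dw in seq_len(kw)) for (dh in seq_len(kh)) {
    t <- t + 1L
    r <- rows0 + dh - pt; cc <- cols0 + dw - pl
    ok <- r >= 1L & r <= Hin & cc >= 1L & cc <= Win
    Isp[, t] <- ifelse(ok, r + (cc - 1L) * Hin, 0L)
  }
  # column order within a tap block: dh fastest, then dw -- matches the
  # flatten order of a [kh, kw, ...] weight array
  list(Isp = Isp, Hout = Hout, Wout = Wout)
}

conv_full_index <- function(Isp, Cin, HW) {
  khkw <- ncol(Isp); npos <- nrow(Isp)
  Ifull <- matrix(0L, npos, khkw * Cin)
  nz <- Isp > 0L
  for (ci in seq_len(Cin)) {
    blk <- Isp
    blk[nz] <- blk[nz] + (ci - 1L) * HW
    Ifull[, (ci - 1L) * khkw + seq_len(khkw)] <- blk
  }
  Ifull
}

node_conv_index <- function(node, Hin, Win, Cin, kh, kw, stride, padding) {
  # built once; shapes are static per graph
  if (is.null(node$cache$Ifull)) {
    sp <- conv_spatial_index(Hin, Win, kh, kw, stride, padding)
    node$cache$Isp <- sp$Isp
    node$cache$Ifull <- conv_full_index(sp$Isp, Cin, Hin * Win)
    node$cache$Ifull1 <- node$cache$Ifull + 1L
    node$cache$Hout <- sp$Hout; node$cache$Wout <- sp$Wout
  }
  node$cache
}

nn_conv <- function(g, input, filters, kernel = c(3L, 3L), stride = 1L,
                    padding = "same", activation = "relu") {
  ish <- nn_shape(g, input)
  kh <- kernel[1L]; kw <- kernel[2L]
  sp <- conv_spatial_index(ish[1L], ish[2L], kh, kw, stride, padding)
  W <- init_conv_weights(g, kh, kw, ish[3L], filters,
                         fan_in = kh * kw * ish[3L],
                         fan_out = kh * kw * filters)
  b <- if (g$init_weights) numeric(filters) else NULL
  nn_add_node(g, "conv", input,
              list(kernel = c(kh, kw), stride = stride, padding = padding,
                   activation = activation),
              list(W = W, b = b),
              c(sp$Hout, sp$Wout, filters))
}

nn_conv_transpose <- function(g, input, filters, kernel = c(3L, 3L),
                              stride = 2L, activation = "relu") {
  ish <- nn_shape(g, input)
  kh <- kernel[1L]; kw <- kernel[2L]
  Hout <- ish[1L] * stride; Wout <- ish[2L] * stride
  # weights in [kh, kw, Cout, Cin] layout (adjoint-of-conv view)
  W <- init_conv_weights(g, kh, kw, filters, ish[3L],
                         fan_in = kh * kw * ish[3L],
                         fan_out = kh * kw * filters)
  b <- if (g$init_weights) numeric(filters) else NULL
  nn_add_node(g, "conv_t", input,
              list(kernel = c(kh, kw), stride = stride,
                   activation = activation),
              list(W = W, b = b),
              c(Hout, Wout, filters))
}

nn_concat <- function(g, inputs) {
  shs <- lapply(inputs, function(i) nn_shape(g, i))
  sp <- shs[[1L]][1:2]
  for (s in shs) if (!identical(s[1:2], sp))
    stop("concat inputs must share spatial dims")
  nn_add_node(g, "concat", inputs, list(),
              NULL, c(sp, sum(vapply(shs, `[`, 0, 3L))))
}

# block average pool, kernel = stride, 'valid' (the box-downsample operator)
nn_avgpool <- function(g, input, stride) {
  ish <- nn_shape(g, input)
  if (ish[1L] %% stride != 0L || ish[2L] %% stride != 0L)
    stop("avgpool input not divisible by stride")
  nn_add_node(g, "avgpool", input, list(stride = stride), NULL,
              c(ish[1L] %/% stride, ish[2L] %/% stride, ish[3L]))
}

# 3x3, stride-1, 'same' average pool, padding excluded from the divisor
nn_avgpool3_same <- function(g, input) {
  ish <- nn_shape(g, input)
  nn_add_node(g, "avgpool3s", input, list(), NULL, ish)
}

nn_maxpool <- function(g, input, kernel = 3L, stride = 2L,
                       padding = "valid") {
  ish <- nn_shape(g, input)
  sp <- conv_spatial_index(ish[1L], ish[2L], kernel, kernel, stride, padding)
  nn_add_node(g, "maxpool", input,
              list(kernel = kernel, stride = stride, padding = padding),
              NULL, c(sp$Hout, sp$Wout, ish[3L]))
}

# drop the last row/col when the spatial size is odd (used ahead of strided
# 'valid' reduction stages so the traced sizes match the printed architecture)
nn_crop_even <- function(g, input) {
  ish <- nn_shape(g, input)
  h <- ish[1L] - ish[1L] %% 2L; w <- ish[2L] - ish[2L] %% 2L
  if (h == ish[1L] && w == ish[2L]) return(input)
  nn_add_node(g, "crop", input, list(h = h, w = w), NULL, c(h, w, ish[3L]))
}

nn_dropout <- function(g, input, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(input)
  nn_add_node(g, "dropout", input, list(rate = rate), NULL,
              nn_shape(g, input))
}

nn_flatten <- function(g, input) {
  nn_add_node(g, "flatten", input, list(), NULL, prod(nn_shape(g, input)))
}

nn_dense <- function(g, input, units, activation = "linear") {
  nin <- nn_shape(g, input)
  stopifnot(length(nin) == 1L)
  W <- NULL; b <- NULL
  if (g$init_weights) {
    if (g$init == "glorot_uniform") {
      lim <- sqrt(6 / (nin + units))
      W <- matrix(runif(nin * units, -lim, lim), nin, units)
    } else {
      W <- matrix(rnorm(nin * units, 0, sqrt(2 / nin)), nin, units)
    }
    b <- numeric(units)
  }
  nn_add_node(g, "dense", input, list(activation = activation),
              list(W = W, b = b), units)
}

apply_activation <- function(x, act) {
  switch(act,
         linear = x,
         relu = pmax(x, 0),
         sigmoid = 1 / (1 + exp(-x)))
}

activation_bwd <- function(dy, y, act) {
  switch(act,
         linear = dy,
         relu = dy * (y > 0),
         sigmoid = dy * y * (1 - y))
}

#' @keywords internal
nn_forward <- function(g, inputs, train = FALSE) {
  acts <- vector("list", length(g$nodes))
  for (node in g$nodes) {
    id <- node$id
    acts[[id]] <- switch(
      node$op,
      input = inputs[[as.character(id)]],
      conv = {
        x <- acts[[node$inputs]]
        ish <- nn_shape(g, node$inputs)
        k <- node$opts$kernel
        cc <- node_conv_index(node, ish[1L], ish[2L], ish[3L],
                              k[1L], k[2L], node$opts$stride,
                              node$opts$padding)
        x0 <- c(0, x)
        col <- x0[cc$Ifull1]
        dim(col) <- dim(cc$Ifull1)
        node$cache$col <- col
        Wm <- matrix(node$params$W, ncol(cc$Ifull), node$out_shape[3L])
        out <- col %*% Wm
        out <- out + rep(node$params$b, each = nrow(col))
        array(apply_activation(out, node$opts$activation), node$out_shape)
      },
      conv_t = {
        x <- acts[[node$inputs]]
        ish <- nn_shape(g, node$inputs)
        k <- node$opts$kernel
        # virtual conv: out grid (Hout, Wout, Cout) -> (Hin, Win)
        cc <- node_conv_index(node, node$out_shape[1L], node$out_shape[2L],
                              node$out_shape[3L], k[1L], k[2L],
                              node$opts$stride, "same")
        xm <- matrix(x, ish[1L] * ish[2L], ish[3L])
        node$cache$xm <- xm
        Wm <- matrix(node$params$W, ncol(cc$Ifull), ish[3L])
        dcol <- xm %*% t(Wm)
        yv <- scatter_apply(node_scatter(node, prod(node$out_shape)), dcol)
        yv <- yv + rep(node$params$b,
                       each = node$out_shape[1L] * node$out_shape[2L])
        array(apply_activation(yv, node$opts$activation), node$out_shape)
      },
      concat = {
        xs <- lapply(node$inputs, function(i) acts[[i]])
        array(unlist(xs, use.names = FALSE), node$out_shape)
      },
      avgpool = box_downsample(acts[[node$inputs]], node$opts$stride),
      avgpool3s = {
        x <- acts[[node$inputs]]
        ish <- nn_shape(g, node$inputs)
        cc <- node_conv_index(node, ish[1L], ish[2L], ish[3L], 3L, 3L,
                              1L, "same")
        if (is.null(node$cache$cnt))
          node$cache$cnt <- rowSums(node$cache$Isp > 0L)
        x0 <- c(0, x)
        npos <- nrow(cc$Isp)
        colarr <- array(x0[cc$Ifull1], c(npos, 9L, ish[3L]))
        s <- matrix(colarr[, 1L, ], npos, ish[3L])
        for (t in 2:9) s <- s + matrix(colarr[, t, ], npos, ish[3L])
        array(s / node$cache$cnt, node$out_shape)
      },
      maxpool = {
        x <- acts[[node$inputs]]
        ish <- nn_shape(g, node$inputs)
        cc <- node_conv_index(node, ish[1L], ish[2L], ish[3L],
                              node$opts$kernel, node$opts$kernel,
                              node$opts$stride, node$opts$padding)
        x0 <- c(-Inf, x)   # padded positions never win the max
        kk <- ncol(cc$Isp)
        npos <- nrow(cc$Isp)
        colarr <- array(x0[cc$Ifull1], c(npos, kk, ish[3L]))
        m <- matrix(colarr[, 1L, ], npos, ish[3L])
        am <- matrix(1L, npos, ish[3L])
        for (t in 2:kk) {
          v <- matrix(colarr[, t, ], npos, ish[3L])
          upd <- v > m
          m[upd] <- v[upd]
          am[upd] <- t
        }
        node$cache$argmax <- am
        array(m, node$out_shape)
      },
      crop = {
        acts[[node$inputs]][seq_len(node$opts$h), seq_len(node$opts$w), ,
                            drop = FALSE]
      },
      dropout = {
        x <- acts[[node$inputs]]
        if (train) {
          mask <- (runif(length(x)) >= node$opts$rate) /
            (1 - node$opts$rate)
          node$cache$mask <- mask
          array(x * mask, dim(x))
        } else x
      },
      flatten = as.vector(acts[[node$inputs]]),
      dense = {
        x <- acts[[node$inputs]]
        out <- as.vector(x %*% node$params$W) + node$params$b
        apply_activation(out, node$opts$activation)
      },
      stop("unknown op ", node$op))
  }
  acts
}

scatter_sum <- function(vals, idx, n_out) {
  v <- as.vector(vals); ix <- as.vector(idx)
  rs <- rowsum(v, ix)
  gn <- as.integer(rownames(rs))
  out <- numeric(n_out)
  pos <- gn > 0L
  out[gn[pos]] <- rs[pos, 1L]
  out
}

# precomputed segment structure for summing values into a fixed index
# pattern (index 0 = dropped); scatter becomes a gather + cumsum
make_scatter <- function(ix, n_out) {
  ord <- order(ix)
  ixs <- ix[ord]
  nz <- ixs > 0L
  ord <- ord[nz]; ixs <- ixs[nz]
  if (length(ixs) == 0L)
    return(list(ord = integer(0), ends = integer(0),
                targets = integer(0), n_out = n_out))
  ends <- which(c(ixs[-1L] != ixs[-length(ixs)], TRUE))
  list(ord = ord, ends = ends, targets = ixs[ends], n_out = n_out)
}

scatter_apply <- function(sc, vals) {
  out <- numeric(sc$n_out)
  if (length(sc$ord) == 0L) return(out)
  s <- cumsum(vals[sc$ord])
  se <- s[sc$ends]
  out[sc$targets] <- se - c(0, se[-length(se)])
  out
}

# cached scatter over a node's gather index
node_scatter <- function(node, n_out) {
  if (is.null(node$cache$scat))
    node$cache$scat <- make_scatter(as.vector(node$cache$Ifull), n_out)
  node$cache$scat
}

# Backward pass.  `seed_grads` is a list mapping node id (character) to the
# gradient of the loss w.r.t. that node's output.  Returns param gradients
# (list per node: W, b) plus gradients at the input nodes.
#' @keywords internal
nn_backward <- function(g, acts, seed_grads, train = TRUE) {
  n <- length(g$nodes)
  dacts <- vector("list", n)
  for (nm in names(seed_grads)) {
    id <- as.integer(nm)
    dacts[[id]] <- seed_grads[[nm]]
  }
  pgrads <- vector("list", n)
  addg <- function(cur, add) if (is.null(cur)) add else cur + add
  for (id in rev(seq_len(n))) {
    node <- g$nodes[[id]]
    dy <- dacts[[id]]
    if (is.null(dy)) next
    switch(
      node$op,
      input = NULL,
      conv = {
        y <- acts[[id]]
        dz <- activation_bwd(dy, y, node$opts$activation)
        cc <- node$cache
        npos <- nrow(cc$Ifull)
        dzm <- matrix(dz, npos, node$out_shape[3L])
        Wm <- matrix(node$params$W, ncol(cc$Ifull), node$out_shape[3L])
        pgrads[[id]] <- list(
          W = array(crossprod(cc$col, dzm), dim(node$params$W)),
          b = colSums(dzm))
        ish <- nn_shape(g, node$inputs)
        dcol <- dzm %*% t(Wm)
        dx <- array(scatter_apply(node_scatter(node, prod(ish)), dcol), ish)
        dacts[[node$inputs]] <- addg(dacts[[node$inputs]], dx)
      },
      conv_t = {
        y <- acts[[id]]
        dz <- activation_bwd(dy, y, node$opts$activation)
        cc <- node$cache
        ish <- nn_shape(g, node$inputs)
        dz0 <- c(0, dz)
        col <- dz0[cc$Ifull1]
        dim(col) <- dim(cc$Ifull1)
        Wm <- matrix(node$params$W, ncol(cc$Ifull), ish[3L])
        pgrads[[id]] <- list(
          W = array(crossprod(col, cc$xm), dim(node$params$W)),
          b = colSums(matrix(dz, node$out_shape[1L] * node$out_shape[2L],
                             node$out_shape[3L])))
        dx <- array(col %*% Wm, ish)
        dacts[[node$inputs]] <- addg(dacts[[node$inputs]], dx)
      },
      concat = {
        off <- 0L
        sp <- node$out_shape[1L] * node$out_shape[2L]
        for (i in node$inputs) {
          ci <- nn_shape(g, i)[3L]
          blk <- dy[, , off + seq_len(ci), drop = FALSE]
          dacts[[i]] <- addg(dacts[[i]], blk)
          off <- off + ci
        }
      },
      avgpool = {
        s <- node$opts$stride
        ish <- nn_shape(g, node$inputs)
        dx <- dy[rep(seq_len(node$out_shape[1L]), each = s),
                 rep(seq_len(node$out_shape[2L]), each = s), ,
                 drop = FALSE] / s^2
        dacts[[node$inputs]] <- addg(dacts[[node$inputs]], dx)
      },
      avgpool3s = {
        cc <- node$cache
        ish <- nn_shape(g, node$inputs)
        npos <- nrow(cc$Isp)
        dym <- matrix(dy, npos, ish[3L]) / cc$cnt
        dcol <- dym[, rep(seq_len(ish[3L]), each = 9L)]
        dx <- array(scatter_apply(node_scatter(node, prod(ish)), dcol), ish)
        dacts[[node$inputs]] <- addg(dacts[[node$inputs]], dx)
      },
      maxpool = {
        cc <- node$cache
        ish <- nn_shape(g, node$inputs)
        npos <- nrow(cc$Isp)
        C <- ish[3L]
        pos <- rep(seq_len(npos), C)
        ch <- rep(seq_len(C), each = npos)
        tap <- as.vector(cc$argmax)
        lin <- cc$Ifull[cbind(pos, (ch - 1L) * ncol(cc$Isp) + tap)]
        dx <- array(scatter_sum(as.vector(dy), lin, prod(ish)), ish)
        dacts[[node$inputs]] <- addg(dacts[[node$inputs]], dx)
      },
      crop = {
        ish <- nn_shape(g, node$inputs)
        dx <- array(0, ish)
        dx[seq_len(node$opts$h), seq_len(node$opts$w), ] <- dy
        dacts[[node$inputs]] <- addg(dacts[[node$inputs]], dx)
      },
      dropout = {
        dx <- if (train && !is.null(node$cache$mask))
          array(dy * node$cache$mask, dim(dy)) else dy
        dacts[[node$inputs]] <- addg(dacts[[node$inputs]], dx)
      },
      flatten = {
        dacts[[node$inputs]] <- addg(dacts[[node$inputs]],
                                     array(dy, nn_shape(g, node$inputs)))
      },
      dense = {
        y <- acts[[id]]
        dz <- activation_bwd(dy, y, node$opts$activation)
        x <- acts[[node$inputs]]
        pgrads[[id]] <- list(W = outer(as.vector(x), dz),
                             b = dz)
        dacts[[node$inputs]] <- addg(dacts[[node$inputs]],
                                     as.vector(node$params$W %*% dz))
      })
  }
  list(params = pgrads, inputs = dacts)
}

# flat named list of all trainable parameters
nn_params <- function(g) {
  out <- list()
  for (node in g$nodes) {
    if (is.null(node$params)) next
    for (p in names(node$params))
      out[[paste0(node$id, ".", p)]] <- node$params[[p]]
  }
  out
}

nn_set_params <- function(g, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    id <- as.integer(parts[1L])
    g$nodes[[id]]$params[[parts[2L]]] <- flat[[nm]]
  }
  invisible(g)
}

nn_flat_grads <- function(g, pgrads) {
  out <- list()
  for (id in seq_along(pgrads)) {
    pg <- pgrads[[id]]
    if (is.null(pg)) next
    for (p in names(pg)) out[[paste0(id, ".", p)]] <- pg[[p]]
  }
  out
}

nn_n_params <- function(g) {
  sum(vapply(nn_params(g), length, 0L))
}
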