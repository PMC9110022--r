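# Stochastic optimizers over the flat parameter lists of nn_graph models.

optimizer_adam <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L; st$m <- NULL; st$v <- NULL
  list(
    step = function(params, grads) {
      st$t <- st$t + 1L
      if (is.null(st$m)) {
        st$m <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
        st$v <- st$m
      }
      for (nm in names(params)) {
        gr <- grads[[nm]]
        if (is.null(gr)) next
        st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gr
        st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gr^2
        mhat <- st$m[[nm]] / (1 - beta1^st$t)
        vhat <- st$v[[nm]] / (1 - beta2^st$t)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      params
    })
}

optimizer_adadelta <- function(lr = 1.0, rho = 0.95, eps = 1e-6) {
  st <- new.env(parent = emptyenv())
  st$eg <- NULL; st$ex <- NULL
  list(
    step = function(params, grads) {
      if (is.null(st$eg)) {
        st$eg <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
        st$ex <- st$eg
      }
      for (nm in names(params)) {
        gr <- grads[[nm]]
        if (is.null(gr)) next
        st$eg[[nm]] <- rho * st$eg[[nm]] + (1 - rho) * gr^2
        upd <- sqrt(st$ex[[nm]] + eps) / sqrt(st$eg[[nm]] + eps) * gr
        st$ex[[nm]] <- rho * st$ex[[nm]] + (1 - rho) * upd^2
        params[[nm]] <- params[[nm]] - lr * upd
      }
      params
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
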