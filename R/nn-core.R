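# Minimal layer machinery: parameters are mutable environments holding a
# value and an accumulated gradient; layers are environments exposing
# fwd(x)/bwd(dy) with the forward cache kept in the layer (batch-of-one
# training, single use per step).  All initialization draws from R's global
# RNG so a single set.seed() makes a whole network deterministic.

new_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- array(0, dim = dim(value) %||% length(value))
  class(e) <- "nn_param"
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

param_zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

# Recursively collect nn_param objects from a nested list / layer tree.
collect_params <- function(x, acc = list()) {
  if (inherits(x, "nn_param")) return(c(acc, list(x)))
  if (is.environment(x) && !is.null(x$params))
    return(collect_params(x$params, acc))
  if (is.list(x)) for (el in x) acc <- collect_params(el, acc)
  acc
}

# He/Glorot-style fan-in scaled init for conv and linear weights.
init_weight <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' Adam optimizer state over a list of parameters
#'
#' Standard Adam with bias-corrected first and second moment estimates.
#'
#' @param params list of internal parameter objects.
#' @param lr learning rate.
#' @param beta1,beta2 exponential decay rates of the moment estimates.
#' @param eps numerical stabilizer.
#' @return an optimizer environment with a `step()` method.
#' @keywords internal
adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(params, function(p) array(0, dim = dim(p$grad) %||%
                                              length(p$grad)))
  opt$v <- lapply(params, function(p) array(0, dim = dim(p$grad) %||%
                                              length(p$grad)))
  opt$step <- function() {
    opt$t <- opt$t + 1L
    bc1 <- 1 - opt$beta1^opt$t
    bc2 <- 1 - opt$beta2^opt$t
    for (i in seq_along(opt$params)) {
      p <- opt$params[[i]]
      opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * p$grad
      opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * p$grad^2
      p$value <- p$value - opt$lr * (opt$m[[i]] / bc1) /
        (sqrt(opt$v[[i]] / bc2) + opt$eps)
    }
    invisible(NULL)
  }
  opt
}

# Adam update for a single bare array (used by the instance optimizer where
# the "parameter" is the displacement field itself).
adam_array_new <- function(shape, lr, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- array(0, dim = shape); st$v <- array(0, dim = shape)
  st$t <- 0L
  st$update <- function(x, g) {
    st$t <- st$t + 1L
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    x - lr * (st$m / (1 - beta1^st$t)) /
      (sqrt(st$v / (1 - beta2^st$t)) + eps)
  }
  st
}
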