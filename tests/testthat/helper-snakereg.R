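# Shared fixtures and oracles, built in code at test time.

ns <- asNamespace("snakereg")

# brute-force 8-corner trilinear oracle with border clamping
oracle_trilinear <- function(vol, p) {
  d <- dim(vol)
  s <- 0
  base <- floor(p)
  for (a in 0:1) for (b in 0:1) for (e in 0:1) {
    corner <- base + c(a, b, e)
    w <- prod(pmax(0, 1 - abs(p - corner)))
    cc <- pmin(pmax(corner, 0), d - 1) + 1
    s <- s + w * vol[cc[1], cc[2], cc[3]]
  }
  s
}

rand_vol <- function(shape, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(prod(shape)), dim = shape)
}

# smooth textured volume with non-degenerate local variance everywhere
textured_vol <- function(shape, seed = 1) {
  set.seed(seed)
  x <- array(rnorm(prod(shape)), dim = shape)
  k <- ns$gauss_kernel(1)
  sm <- ns$gsmooth0(x, k) / ns$gsmooth0(array(1, dim = shape), k)
  volume3d(0.5 + 0.4 * sm / max(abs(sm)) + 0.02 * array(rnorm(prod(shape)),
                                                        dim = shape))
}

# finite-difference gradient check on a layer's parameters; the layer must
# expose fwd/bwd and carry params reachable via collect_params.
fd_grad_check <- function(layer, x, seed = 1, n_checks = 6, eps = 1e-5,
                          fwd = function(l, x) l$fwd(x)) {
  set.seed(seed)
  tgt <- array(rnorm(length(fwd(layer, x))), dim = dim(fwd(layer, x)))
  loss <- function() sum(fwd(layer, x) * tgt)
  params <- ns$collect_params(layer)
  ns$param_zero_grads(params)
  fwd(layer, x)
  layer$bwd(tgt)
  errs <- c()
  for (p in params) {
    for (i in sample(length(p$value), min(n_checks, length(p$value)))) {
      old <- p$value[i]
      p$value[i] <- old + eps; lp <- loss()
      p$value[i] <- old - eps; lm <- loss()
      p$value[i] <- old
      gn <- (lp - lm) / (2 * eps)
      errs <- c(errs, abs(p$grad[i] - gn) / max(1, abs(gn), abs(p$grad[i])))
    }
  }
  errs
}

tiny_case <- function(shape = c(16L, 16L, 16L), seed = 1,
                      amplitude = 1.5) {
  make_pair(phantom_spec(shape = shape), field_spec(amplitude = amplitude),
            seed = seed)
}
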