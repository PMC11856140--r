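#' Optimization-stage configuration
#'
#' Controls the per-case Adam refinement of a displacement field against
#' the registration energy (1 - local NCC + smoothness, optional SSIM).
#'
#' @param iterations Adam steps per refinement (default 10).
#' @param lr Adam learning rate (default 0.1).
#' @param beta1,beta2 Adam moment decay rates (defaults 0.9, 0.999).
#' @param gtol convergence tolerance: iteration stops early once the
#'   largest gradient component falls below this (an already-aligned pair
#'   is a fixed point and must not be dithered away from by Adam's
#'   scale-free updates on float-noise gradients).
#' @param loss a [loss_config()] defining the energy terms.
#' @return object of class `opt_stage_config`.
#' @export
opt_stage_config <- function(iterations = 10L, lr = 0.1, beta1 = 0.9,
                             beta2 = 0.999, gtol = 1e-9,
                             loss = loss_config()) {
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("iterations must be >= 0")
  if (lr <= 0) stop("lr must be positive")
  structure(list(iterations = iterations, lr = lr, beta1 = beta1,
                 beta2 = beta2, gtol = gtol, loss = loss),
            class = "opt_stage_config")
}

#' Instance optimization of a displacement field
#'
#' Refines an initial field by Adam descent on the registration energy of
#' the (moving, fixed) pair, treating the field's per-voxel vectors as the
#' free parameters.  A pure function of its inputs: nothing is mutated and
#' no randomness is involved, so the result is deterministic.
#'
#' @param moving,fixed [volume3d()] objects.
#' @param init_field initial [dispfield()] (e.g. a network prediction).
#' @param cfg an [opt_stage_config()].
#' @return the refined [dispfield()], with attributes `energy_init` and
#'   `energy_final` recording the energy before and after refinement.
#' @export
instance_optimize <- function(moving, fixed, init_field,
                              cfg = opt_stage_config()) {
  stopifnot(inherits(init_field, "dispfield"))
  if (!identical(vol_shape(moving), vol_shape(init_field)))
    stop("instance_optimize: field shape does not match images")
  u <- init_field$vectors
  st <- adam_array_new(dim(u), lr = cfg$lr, beta1 = cfg$beta1,
                       beta2 = cfg$beta2)
  e0 <- NULL
  for (it in seq_len(cfg$iterations)) {
    eg <- energy_grad(fixed, moving, dispfield(u), cfg$loss)
    if (!is.finite(eg$value))
      stop(sprintf("instance_optimize: non-finite energy at iteration %d",
                   it))
    if (is.null(e0)) e0 <- eg$value
    if (max(abs(eg$grad)) < cfg$gtol) break
    u <- st$update(u, eg$grad)
  }
  ef <- energy(fixed, moving, dispfield(u), cfg$loss)
  if (is.null(e0)) e0 <- ef
  out <- dispfield(u)
  attr(out, "energy_init") <- e0
  attr(out, "energy_final") <- ef
  out
}
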