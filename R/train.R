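#' Training configuration
#'
#' @param epochs training epochs (full-scale reference: 300).
#' @param lr network Adam learning rate (default 1e-4).
#' @param seed RNG seed recorded in every artifact.
#' @param augment apply random label-safe flips and axis permutations.
#' @param oss weakly supervised mode: refine each predicted field into a
#'   pseudo-ground truth and supervise with the field MSE + smoothness
#'   loss; with `oss = FALSE` training minimizes the unsupervised
#'   `(1 - NCC) + lambda * grad_l2` energy directly.
#' @param gate_threshold pseudo-label gate: a refined field is used only if
#'   it improves the energy by at least this fraction of the initial
#'   energy (default 0 = any non-worsening refinement passes; the
#'   predicted field itself is the fallback target).
#' @param checkpoint_every epochs between checkpoint snapshots (0 = only
#'   track the best).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 300L, lr = 1e-4, seed = 1L,
                         augment = TRUE, oss = TRUE, gate_threshold = 0,
                         checkpoint_every = 0L) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(epochs = epochs, batch_size = 1L, lr = lr,
                 seed = as.integer(seed), augment = isTRUE(augment),
                 oss = isTRUE(oss), gate_threshold = gate_threshold,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

# label-safe geometric augmentation: permute grid axes and flip axes,
# transforming displacement components consistently (permuted and negated
# along flipped axes).
transform_case <- function(case, perm = 1:3, flips = c(FALSE, FALSE, FALSE)) {
  tx_grid <- function(a) {
    a <- aperm(a, perm)
    idx <- lapply(1:3, function(i)
      if (flips[i]) rev(seq_len(dim(a)[i])) else seq_len(dim(a)[i]))
    a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  tx_field <- function(f) {
    u <- f$vectors
    u <- aperm(u, c(perm, 4L))[, , , perm, drop = FALSE]
    idx <- lapply(1:3, function(i)
      if (flips[i]) rev(seq_len(dim(u)[i])) else seq_len(dim(u)[i]))
    u <- u[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
    for (i in 1:3) if (flips[i]) u[, , , i] <- -u[, , , i]
    dispfield(u)
  }
  registration_case(
    moving = volume3d(tx_grid(case$moving$data), case$moving$spacing),
    fixed = volume3d(tx_grid(case$fixed$data), case$fixed$spacing),
    moving_labels = if (!is.null(case$moving_labels))
      labelmap3d(tx_grid(case$moving_labels$labels)),
    fixed_labels = if (!is.null(case$fixed_labels))
      labelmap3d(tx_grid(case$fixed_labels$labels)),
    gt_field = if (!is.null(case$gt_field)) tx_field(case$gt_field),
    seed = case$seed)
}

random_augment <- function(case) {
  if (!all(diff(vol_shape(case$moving)) == 0))
    return(case)  # permutations need a cubic grid
  perm <- sample(1:3)
  flips <- runif(3) < 0.5
  transform_case(case, perm, flips)
}

#' One weakly supervised training step
#'
#' Forward pass, per-case refinement of the (detached) predicted field into
#' a pseudo-ground truth, gating, one Adam update of the network on the
#' supervised field loss; or, with `oss = FALSE` in `tcfg`, one update on
#' the unsupervised registration energy.
#'
#' @param case a `regcase`.
#' @param net a [stunet()] model.
#' @param opt network Adam optimizer (from an ongoing [train_oss()] run).
#' @param tcfg a [train_config()]; @param ocfg an [opt_stage_config()].
#' @return named list of scalar diagnostics for the step.
#' @export
train_step <- function(case, net, opt, tcfg = train_config(),
                       ocfg = opt_stage_config()) {
  mov <- vol_data(case$moving); fix <- vol_data(case$fixed)
  field <- stunet_forward(net, mov, fix)
  lcfg <- ocfg$loss
  rec <- list()
  if (tcfg$oss) {
    pseudo <- instance_optimize(case$moving, case$fixed, dispfield(field),
                                ocfg)
    e0 <- attr(pseudo, "energy_init")
    e1 <- attr(pseudo, "energy_final")
    gate_ok <- (e0 - e1) >= tcfg$gate_threshold * abs(e0)
    target <- if (gate_ok) pseudo$vectors else field
    sg <- supervised_loss_grad(field, target, lcfg)
    if (lcfg$ssim_weight > 0) {
      st <- ssim_field_term(case$fixed, case$moving, field, lcfg)
      sg$value <- sg$value + st$value
      sg$grad <- sg$grad + st$grad
    }
    rec <- list(loss = sg$value,
                mse = mean((field - target)^2),
                reg = grad_l2(dispfield(field)),
                energy_init = e0, energy_opt = e1, gated = !gate_ok)
    dfield <- sg$grad
  } else {
    eg <- energy_grad(case$fixed, case$moving, dispfield(field), lcfg)
    rec <- list(loss = eg$value, mse = NA_real_,
                reg = grad_l2(dispfield(field)),
                energy_init = eg$value, energy_opt = NA_real_,
                gated = FALSE)
    dfield <- eg$grad
  }
  if (!is.finite(rec$loss)) {
    warning(sprintf("non-finite loss; step skipped (case seed %s)",
                    as.character(case$seed)))
    rec$skipped <- TRUE
    return(rec)
  }
  param_zero_grads(net$params)
  stunet_backward(net, dfield)
  opt$step()
  rec$skipped <- FALSE
  rec
}

#' Train a registration network
#'
#' Epoch loop over the cases with optional augmentation, weakly supervised
#' (or unsupervised) updates, periodic validation (mean Dice of
#' nearest-warped labels and the folding fraction on held-out cases) and
#' best-validation checkpoint retention.
#'
#' @param cases list of `regcase` training cases.
#' @param net a [stunet()] model (modified in place).
#' @param tcfg a [train_config()]; @param ocfg an [opt_stage_config()].
#' @param val_cases optional held-out cases with labels.
#' @param checkpoint_dir directory for periodic checkpoints (written every
#'   `tcfg$checkpoint_every` epochs when both are set).
#' @return object of class `train_history`: per-step records, per-epoch
#'   validation, and the best parameter state.
#' @export
train_oss <- function(cases, net, tcfg = train_config(),
                      ocfg = opt_stage_config(), val_cases = NULL,
                      checkpoint_dir = NULL) {
  if (length(cases) == 0L) stop("train_oss: empty dataset")
  set.seed(tcfg$seed)
  opt <- adam_new(net$params, lr = tcfg$lr)
  steps <- list()
  val <- list()
  best <- list(dice = -Inf, state = net_state(net), epoch = 0L)
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample(seq_along(cases))
    for (ci in ord) {
      case <- cases[[ci]]
      if (tcfg$augment) case <- random_augment(case)
      rec <- train_step(case, net, opt, tcfg, ocfg)
      steps[[length(steps) + 1L]] <-
        c(list(epoch = ep, case = ci), rec)
    }
    if (!is.null(val_cases)) {
      rep_ <- evaluate_registration(net, val_cases, ocfg$loss)
      val[[length(val) + 1L]] <- list(epoch = ep,
                                      dice = rep_$aggregate$dice_mean,
                                      pct_folding =
                                        rep_$aggregate$pct_folding_mean)
      if (rep_$aggregate$dice_mean > best$dice)
        best <- list(dice = rep_$aggregate$dice_mean,
                     state = net_state(net), epoch = ep)
    } else if (ep == tcfg$epochs) {
      best <- list(dice = NA_real_, state = net_state(net), epoch = ep)
    }
    if (!is.null(checkpoint_dir) && tcfg$checkpoint_every > 0L &&
        ep %% tcfg$checkpoint_every == 0L) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      stunet_save(net, file.path(checkpoint_dir,
                                 sprintf("epoch_%04d.rds", ep)))
    }
  }
  structure(list(steps = steps, validation = val, best = best,
                 seed = tcfg$seed, epochs = tcfg$epochs),
            class = "train_history")
}

#' @export
print.train_history <- function(x, ...) {
  losses <- vapply(x$steps, function(s) s$loss, numeric(1))
  cat(sprintf("<train_history: %d epochs, %d steps, loss %.4g -> %.4g%s>\n",
              x$epochs, length(x$steps), losses[1],
              losses[length(losses)],
              if (length(x$validation))
                sprintf(", best val Dice %.4f (epoch %d)", x$best$dice,
                        x$best$epoch) else ""))
  invisible(x)
}

#' Evaluate registration quality on labelled cases
#'
#' For each case, obtains a displacement field (predicted by a network, or
#' supplied directly), warps the moving labels in nearest mode, and scores
#' mean Dice against the fixed labels plus the folding fraction of the
#' field.  Cases without labels are excluded with a warning.
#'
#' @param object a [stunet()] model, a single [dispfield()], or a list of
#'   fields (one per case).
#' @param cases list of `regcase` objects carrying label maps.
#' @param lcfg a [loss_config()] (for the reported energy).
#' @return object of class `metrics_report` with `per_case` and
#'   `aggregate` summaries.
#' @export
evaluate_registration <- function(object, cases, lcfg = loss_config()) {
  if (inherits(cases, "regcase")) cases <- list(cases)
  per <- list()
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    if (is.null(case$moving_labels) || is.null(case$fixed_labels)) {
      warning(sprintf("case %d has no labels; excluded", i))
      next
    }
    field <- if (inherits(object, "stunet"))
      dispfield(stunet_forward(object, vol_data(case$moving),
                               vol_data(case$fixed)))
    else if (inherits(object, "dispfield")) object
    else object[[i]]
    warped_lab <- warp_volume(case$moving_labels, field, "nearest")
    ds <- dice_score(warped_lab, case$fixed_labels)
    per[[length(per) + 1L]] <- list(
      case = i, dice = ds$mean,
      pct_folding = pct_nondiffeomorphic(field),
      max_disp = max(abs(field$vectors)))
  }
  if (length(per) == 0L) stop("evaluate_registration: no usable cases")
  dice <- vapply(per, function(p) p$dice, numeric(1))
  fold <- vapply(per, function(p) p$pct_folding, numeric(1))
  structure(list(
    per_case = per,
    aggregate = list(dice_mean = mean(dice),
                     dice_sd = if (length(dice) > 1) sd(dice) else 0,
                     pct_folding_mean = mean(fold),
                     pct_folding_sd = if (length(fold) > 1) sd(fold)
                                      else 0,
                     n_cases = length(per),
                     runtime_s = proc.time()[["elapsed"]] - t0)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "<metrics_report: %d cases, Dice %.4f +/- %.4f, %%det<=0 %.4g +/- %.4g, %.2fs>\n",
    a$n_cases, a$dice_mean, a$dice_sd, 100 * a$pct_folding_mean,
    100 * a$pct_folding_sd, a$runtime_s))
  invisible(x)
}
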