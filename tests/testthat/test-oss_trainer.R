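test_that("instance optimization is a pure, convergent refinement", {
  v <- volume3d(rand_vol(c(16, 16, 16), seed = 70))
  z <- zero_field(c(16, 16, 16))
  # an aligned pair is a fixed point: the field stays (essentially) zero
  ref <- instance_optimize(v, v, z, opt_stage_config())
  expect_lt(max(abs(ref$vectors)), 1e-3)
  # inputs are not mutated
  case <- tiny_case(c(16L, 16L, 16L), seed = 71)
  mov_before <- case$moving$data
  init <- zero_field(c(16, 16, 16))
  init_before <- init$vectors
  out <- instance_optimize(case$moving, case$fixed, init,
                           opt_stage_config())
  expect_identical(case$moving$data, mov_before)
  expect_identical(init$vectors, init_before)
  # energy never increases over the configured 10 steps (seeded cases)
  for (s in 72:77) {
    cs <- tiny_case(c(16L, 16L, 16L), seed = s)
    r <- instance_optimize(cs$moving, cs$fixed, zero_field(c(16, 16, 16)),
                           opt_stage_config())
    expect_lte(attr(r, "energy_final"), attr(r, "energy_init"))
  }
  # zero iterations return the initial field unchanged
  r0 <- instance_optimize(case$moving, case$fixed, init,
                          opt_stage_config(iterations = 0))
  expect_identical(r0$vectors, init$vectors)
  # determinism
  r1 <- instance_optimize(case$moving, case$fixed, init,
                          opt_stage_config())
  r2 <- instance_optimize(case$moving, case$fixed, init,
                          opt_stage_config())
  expect_identical(r1$vectors, r2$vectors)
})

test_that("a degenerate aligned case yields zero loss via pseudo-label gating", {
  set.seed(78)
  net <- stunet(network_config_desk(c(16L, 16L, 16L)))
  v <- make_phantom(phantom_spec(shape = c(16, 16, 16)), seed = 79)
  case <- registration_case(moving = v$volume, fixed = v$volume,
                            moving_labels = v$labels,
                            fixed_labels = v$labels)
  opt <- ns$adam_new(net$params, lr = 1e-4)
  rec <- train_step(case, net, opt, train_config(epochs = 1),
                    opt_stage_config())
  expect_equal(rec$loss, 0)
  expect_equal(rec$mse, 0)
})

test_that("training runs, records history, and is seed-reproducible", {
  shape <- c(16L, 16L, 16L)
  cases <- lapply(80:81, function(s) tiny_case(shape, seed = s))
  run <- function() {
    set.seed(42)
    net <- stunet(network_config_desk(shape))
    hist <- train_oss(cases, net, train_config(epochs = 1, seed = 42),
                      opt_stage_config(), val_cases = cases[1])
    hist
  }
  h1 <- run()
  expect_length(h1$steps, 2L)
  expect_true(all(c("epoch", "case", "loss", "mse", "reg", "energy_init",
                    "energy_opt") %in% names(h1$steps[[1]])))
  expect_length(h1$validation, 1L)
  h2 <- run()
  expect_identical(vapply(h1$steps, function(s) s$loss, 0),
                   vapply(h2$steps, function(s) s$loss, 0))
  expect_identical(h1$best$dice, h2$best$dice)
})

test_that("a small-step update does not increase the supervised loss", {
  shape <- c(16L, 16L, 16L)
  set.seed(83)
  net <- stunet(network_config_desk(shape))
  opt <- ns$adam_new(net$params, lr = 1e-5)
  ocfg <- opt_stage_config()
  improved <- 0; total <- 0
  for (s in 84:88) {
    case <- tiny_case(shape, seed = s)
    mov <- case$moving$data; fix <- case$fixed$data
    field <- ns$stunet_forward(net, mov, fix)
    pseudo <- instance_optimize(case$moving, case$fixed, dispfield(field),
                                ocfg)
    before <- supervised_loss(field, pseudo$vectors, ocfg$loss)
    sg <- ns$supervised_loss_grad(field, pseudo$vectors, ocfg$loss)
    ns$param_zero_grads(net$params)
    ns$stunet_backward(net, sg$grad)
    opt$step()
    after <- supervised_loss(ns$stunet_forward(net, mov, fix),
                             pseudo$vectors, ocfg$loss)
    improved <- improved + (after <= before + 1e-12)
    total <- total + 1
  }
  expect_gte(improved / total, 0.8)
})

test_that("evaluation scores identity cases perfectly and aggregates correctly", {
  shape <- c(16L, 16L, 16L)
  ph <- make_phantom(phantom_spec(shape = shape), seed = 90)
  ident <- registration_case(moving = ph$volume, fixed = ph$volume,
                             moving_labels = ph$labels,
                             fixed_labels = ph$labels)
  rep_ <- evaluate_registration(list(zero_field(shape)), list(ident))
  expect_equal(rep_$aggregate$dice_mean, 1)
  expect_equal(rep_$aggregate$pct_folding_mean, 0)
  # aggregates recompute from the per-case records
  cases <- lapply(91:93, function(s) tiny_case(shape, seed = s))
  fields <- lapply(cases, function(cs) cs$gt_field)
  r2 <- evaluate_registration(fields, cases)
  dice <- vapply(r2$per_case, function(p) p$dice, 0)
  expect_equal(r2$aggregate$dice_mean, mean(dice))
  expect_equal(r2$aggregate$dice_sd, sd(dice))
  # a case without labels is excluded with a warning
  nolab <- registration_case(moving = ph$volume, fixed = ph$volume)
  expect_warning(
    r3 <- evaluate_registration(list(zero_field(shape), zero_field(shape)),
                                list(ident, nolab)),
    "no labels")
  expect_equal(r3$aggregate$n_cases, 1L)
})

test_that("evaluating a stored field equals evaluating the net that made it", {
  shape <- c(16L, 16L, 16L)
  set.seed(94)
  net <- stunet(network_config_desk(shape))
  net$final$params$w$value[] <- rnorm(length(net$final$params$w$value),
                                      sd = 0.02)
  case <- tiny_case(shape, seed = 95)
  field <- predict(net, case$moving, case$fixed)$field
  ra <- evaluate_registration(net, list(case))
  rb <- evaluate_registration(list(field), list(case))
  expect_identical(ra$aggregate$dice_mean, rb$aggregate$dice_mean)
  expect_identical(ra$aggregate$pct_folding_mean,
                   rb$aggregate$pct_folding_mean)
})

test_that("augmentation transforms cases consistently with their truth", {
  case <- tiny_case(c(16L, 16L, 16L), seed = 96)
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    for (flips in list(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, TRUE))) {
      tc <- ns$transform_case(case, perm, flips)
      # the transformed ground truth still aligns the transformed labels
      warped <- warp_volume(tc$moving_labels, tc$gt_field, "nearest")
      expect_equal(dice_score(warped, tc$fixed_labels)$mean, 1)
      # and the transformed intensities
      wv <- warp_volume(tc$moving, tc$gt_field, "trilinear")
      expect_lt(max(abs(wv$data - tc$fixed$data)), 1e-10)
    }
  }
})

test_that("the smoothness term suppresses folding during refinement", {
  folds <- sapply(120:123, function(s) {
    case <- make_pair(phantom_spec(shape = c(16, 16, 16)),
                      field_spec(amplitude = 3), seed = s)
    with_reg <- instance_optimize(case$moving, case$fixed,
                                  zero_field(c(16, 16, 16)),
                                  opt_stage_config(iterations = 50))
    no_reg <- instance_optimize(case$moving, case$fixed,
                                zero_field(c(16, 16, 16)),
                                opt_stage_config(iterations = 50,
                                  loss = loss_config(lambda_reg = 0)))
    c(pct_nondiffeomorphic(with_reg), pct_nondiffeomorphic(no_reg))
  })
  expect_lte(mean(folds[1, ]), mean(folds[2, ]))
})
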