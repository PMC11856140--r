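#' Network configuration of the registration model
#'
#' Assembles the architecture hyperparameters: the shifted-window backbone,
#' the snake-convolution head, the convolutional stem that feeds full- and
#' half-resolution skip features into the final upsampling path, and the
#' dense-skip wiring.
#'
#' @param shape input volume shape `(D, H, W)`; each dim divisible by 4.
#' @param swin a [swin_config()]; `embed_dim` must be divisible by 4.
#' @param snake a [snake_kernel_spec()] for the head's snake convolution.
#' @param stem_channels full-resolution stem features (default 16).
#' @param head_channels channels of the two head convolution blocks.
#' @param dense_skips include the VGG-style multi-fusion branches that pull
#'   shallower encoder features into each decoder scale.
#' @param norm `"group"` (default, stable at batch size 1) or `"batch"`.
#' @return object of class `network_config`.
#' @export
network_config <- function(shape = c(32L, 32L, 32L), swin = swin_config(),
                           snake = snake_kernel_spec(),
                           stem_channels = 16L, head_channels = 16L,
                           dense_skips = TRUE, norm = c("group", "batch")) {
  shape <- as.integer(rep_len(shape, 3L))
  norm <- match.arg(norm)
  if (any(shape %% 4L != 0L) || any(shape < 16L))
    stop("shape must be divisible by 4 and at least 16 per axis")
  if (swin$embed_dim %% 4L != 0L)
    stop("embed_dim must be divisible by 4 (half- and quarter-width skips)")
  structure(list(shape = shape, swin = swin, snake = snake,
                 stem_channels = as.integer(stem_channels),
                 head_channels = as.integer(head_channels),
                 dense_skips = isTRUE(dense_skips), norm = norm),
            class = "network_config")
}

#' Desk-scale network preset
#'
#' A small configuration (8 embedding channels, single-block stages,
#' 2-voxel windows) for CPU-scale experiments and tests on volumes of
#' 16--48 voxels per side.
#'
#' @param shape input shape, each dim divisible by 4.
#' @param snake snake kernel spec for the head.
#' @return a [network_config()].
#' @export
network_config_desk <- function(shape = c(24L, 24L, 24L),
                                snake = snake_kernel_spec()) {
  network_config(shape = shape,
                 swin = swin_config(embed_dim = 8L, window = c(2L, 2L, 2L),
                                    depths = c(1L, 1L, 1L, 1L),
                                    heads = c(2L, 2L, 2L, 2L),
                                    mlp_ratio = 2),
                 snake = snake,
                 stem_channels = 8L, head_channels = 8L)
}

bind4 <- function(...) {
  xs <- list(...)
  dims <- dim(xs[[1]])[1:3]
  array(unlist(lapply(xs, as.vector), use.names = FALSE),
        dim = c(dims, sum(vapply(xs, function(x) dim(x)[4], 1L))))
}

# zero-pad a token grid to even spatial dims (backward: crop)
layer_pad_even <- function() {
  ly <- new.env(parent = emptyenv())
  ly$params <- list()
  ly$fwd <- function(x) {
    dims <- dim(x)
    pd <- dims[1:3] + dims[1:3] %% 2L
    ly$cache <- dims
    if (all(pd == dims[1:3])) return(x)
    y <- array(0, dim = c(pd, dims[4]))
    y[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), ] <- x
    y
  }
  ly$bwd <- function(dy) {
    dims <- ly$cache
    dy[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), ,
       drop = FALSE]
  }
  ly
}

# patch merging with automatic odd-dim padding
layer_merge_padded <- function(C) {
  ly <- new.env(parent = emptyenv())
  ly$pad <- layer_pad_even()
  ly$merge <- layer_patch_merge(C)
  ly$params <- list(ly$merge)
  ly$fwd <- function(x) ly$merge$fwd(ly$pad$fwd(x))
  ly$bwd <- function(dy) ly$pad$bwd(ly$merge$bwd(dy))
  ly
}

# VGG-style downsampling branch of the dense skips: two conv blocks then a
# 2x max pool (with odd-dim padding).
layer_vgg_down <- function(cin, norm) {
  ly <- new.env(parent = emptyenv())
  ly$c1 <- layer_conv_block(cin, cin, norm = norm)
  ly$c2 <- layer_conv_block(cin, cin, norm = norm)
  ly$pad <- layer_pad_even()
  ly$pool <- layer_maxpool2()
  ly$params <- list(ly$c1, ly$c2)
  ly$fwd <- function(x) ly$pool$fwd(ly$pad$fwd(ly$c2$fwd(ly$c1$fwd(x))))
  ly$bwd <- function(dy)
    ly$c1$bwd(ly$c2$bwd(ly$pad$bwd(ly$pool$bwd(dy))))
  ly
}

# Multi-fusion dense skip block: concatenates the upsampled decoder
# feature, the same-scale encoder feature and (optionally) a shallower
# encoder feature brought down by a VGG branch, then fuses with two conv
# blocks.  Degenerates to the two conv blocks when only `cur` is given.
layer_dense_skip <- function(c_cur, c_enc = 0L, c_shallow = 0L, norm) {
  ly <- new.env(parent = emptyenv())
  if (c_shallow > 0L) ly$vgg <- layer_vgg_down(c_shallow, norm)
  cin <- c_cur + c_enc + c_shallow
  ly$f1 <- layer_conv_block(cin, c_cur, norm = norm)
  ly$f2 <- layer_conv_block(c_cur, c_cur, norm = norm)
  ly$params <- c(list(ly$f1, ly$f2),
                 if (c_shallow > 0L) list(ly$vgg))
  ly$c_cur <- c_cur; ly$c_enc <- c_enc; ly$c_shallow <- c_shallow
  ly$fwd <- function(cur, enc = NULL, shallow = NULL) {
    parts <- list(cur)
    if (!is.null(enc)) parts <- c(parts, list(enc))
    if (!is.null(shallow)) {
      v <- ly$vgg$fwd(shallow)
      if (!all(dim(v)[1:3] == dim(cur)[1:3]))
        stop("dense_skip: scale mismatch after resampling")
      parts <- c(parts, list(v))
    }
    x <- do.call(bind4, parts)
    ly$fwd_used <- c(!is.null(enc), !is.null(shallow))
    ly$f2$fwd(ly$f1$fwd(x))
  }
  ly$bwd <- function(dy) {
    dx <- ly$f1$bwd(ly$f2$bwd(dy))
    dcur <- dx[, , , seq_len(ly$c_cur), drop = FALSE]
    off <- ly$c_cur
    denc <- NULL; dshallow <- NULL
    if (ly$fwd_used[1]) {
      denc <- dx[, , , off + seq_len(ly$c_enc), drop = FALSE]
      off <- off + ly$c_enc
    }
    if (ly$fwd_used[2]) {
      dv <- dx[, , , off + seq_len(ly$c_shallow), drop = FALSE]
      dshallow <- ly$vgg$bwd(dv)
    }
    list(cur = dcur, enc = denc, shallow = dshallow)
  }
  ly
}

run_stage_fwd <- function(blocks, x) {
  for (b in blocks) x <- b$fwd(x)
  x
}
run_stage_bwd <- function(blocks, dy) {
  for (b in rev(blocks)) dy <- b$bwd(dy)
  dy
}

#' Construct the registration network
#'
#' Builds the full model: a convolutional stem on the stacked (moving,
#' fixed) pair, a 4-stage shifted-window encoder over embedded patches, a
#' mirrored 4-stage decoder whose skip connections fuse same-scale and
#' VGG-downsampled shallower encoder features, two final upsampling steps
#' that consume the half- and full-resolution stem skips, and a head of a
#' standard convolution block plus a dynamic-snake convolution block (each
#' gated by concurrent spatial/channel squeeze-and-excitation) ending in a
#' zero-initialized 3-channel convolution, so an untrained network predicts
#' the identity transform.  Parameter initialization draws from R's RNG;
#' call `set.seed()` first for reproducible weights.
#'
#' @param config a [network_config()].
#' @return object of class `stunet`.
#' @export
stunet <- function(config = network_config()) {
  cfg <- config
  C <- cfg$swin$embed_dim
  sw <- cfg$swin
  nrm <- cfg$norm
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  g1 <- cfg$shape %/% 4L
  g2 <- (g1 + g1 %% 2L) %/% 2L
  g3 <- (g2 + g2 %% 2L) %/% 2L
  g4 <- (g3 + g3 %% 2L) %/% 2L
  net$grids <- list(g1, g2, g3, g4)
  mkstage <- function(Cs, hs, grid, depth) {
    lapply(seq_len(depth), function(i)
      layer_swin_block(Cs, hs, grid, sw$window, shifted = (i %% 2L == 0L),
                       mlp_ratio = sw$mlp_ratio, use_bias = sw$use_bias))
  }
  net$stem_a <- layer_conv_block(2L, cfg$stem_channels, norm = nrm)
  net$stem_b <- layer_conv_block(cfg$stem_channels, C %/% 2L, stride = 2L,
                                 norm = nrm)
  net$embed <- layer_patch_embed(C)
  net$enc1 <- mkstage(C, sw$heads[1], g1, sw$depths[1])
  net$merge1 <- layer_merge_padded(C)
  net$enc2 <- mkstage(2L * C, sw$heads[2], g2, sw$depths[2])
  net$merge2 <- layer_merge_padded(2L * C)
  net$enc3 <- mkstage(4L * C, sw$heads[3], g3, sw$depths[3])
  net$merge3 <- layer_merge_padded(4L * C)
  net$enc4 <- mkstage(8L * C, sw$heads[4], g4, sw$depths[4])
  net$dec4 <- mkstage(8L * C, sw$heads[4], g4, sw$depths[4])
  net$exp3 <- layer_patch_expand(8L * C)
  net$skip3 <- layer_dense_skip(4L * C, 4L * C,
                                if (cfg$dense_skips) 2L * C else 0L, nrm)
  net$dec3 <- mkstage(4L * C, sw$heads[3], g3, sw$depths[3])
  net$exp2 <- layer_patch_expand(4L * C)
  net$skip2 <- layer_dense_skip(2L * C, 2L * C,
                                if (cfg$dense_skips) C else 0L, nrm)
  net$dec2 <- mkstage(2L * C, sw$heads[2], g2, sw$depths[2])
  net$exp1 <- layer_patch_expand(2L * C)
  net$skip1 <- layer_dense_skip(C, C, 0L, nrm)
  net$dec1 <- mkstage(C, sw$heads[1], g1, sw$depths[1])
  net$exp_h <- layer_patch_expand(C)
  net$fuse_h <- layer_conv_block(C, C %/% 2L, norm = nrm)
  net$exp_f <- layer_patch_expand(C %/% 2L)
  net$head1 <- layer_conv_block(C %/% 4L + cfg$stem_channels,
                                cfg$head_channels, norm = nrm)
  net$scse1 <- layer_scse(cfg$head_channels)
  net$snake <- layer_dsconv3d(cfg$head_channels, cfg$head_channels,
                              cfg$snake)
  net$snake_norm <- layer_groupnorm(cfg$head_channels,
                                    groups = if (nrm == "batch")
                                      cfg$head_channels else NULL)
  net$snake_act <- layer_relu()
  net$scse2 <- layer_scse(cfg$head_channels)
  net$final <- layer_conv3d(cfg$head_channels, 3L, zero_init = TRUE)
  net$modules <- list(net$stem_a, net$stem_b, net$embed, net$enc1,
                      net$merge1, net$enc2, net$merge2, net$enc3,
                      net$merge3, net$enc4, net$dec4, net$exp3, net$skip3,
                      net$dec3, net$exp2, net$skip2, net$dec2, net$exp1,
                      net$skip1, net$dec1, net$exp_h, net$fuse_h,
                      net$exp_f, net$head1, net$scse1, net$snake,
                      net$snake_norm, net$scse2, net$final)
  net$params <- collect_params(net$modules)
  class(net) <- "stunet"
  net
}

# forward pass on bare arrays; ablate names elements of
# c("enc_skip1","enc_skip2","enc_skip3","stem_full","stem_half",
#   "dense_branch2","dense_branch1") to zero for sensitivity checks.
stunet_forward <- function(net, mov, fix, ablate = character(0)) {
  cfg <- net$cfg
  if (!identical(dim(mov), dim(fix)))
    stop("stunet: moving and fixed shapes differ")
  if (!identical(as.integer(dim(mov)), cfg$shape))
    stop(sprintf("stunet: input shape (%s) does not match config (%s)",
                 paste(dim(mov), collapse = "x"),
                 paste(cfg$shape, collapse = "x")))
  g <- net$grids
  zero_if <- function(x, name) if (name %in% ablate) x * 0 else x
  x <- bind4(array(mov, c(dim(mov), 1L)), array(fix, c(dim(fix), 1L)))
  sa <- net$stem_a$fwd(x)
  sb <- net$stem_b$fwd(sa)
  t1 <- net$embed$fwd(x)
  e1 <- run_stage_fwd(net$enc1, t1)
  e2 <- run_stage_fwd(net$enc2, net$merge1$fwd(e1))
  e3 <- run_stage_fwd(net$enc3, net$merge2$fwd(e2))
  e4 <- run_stage_fwd(net$enc4, net$merge3$fwd(e3))
  d4 <- run_stage_fwd(net$dec4, e4)
  x3 <- net$exp3$fwd(d4, g[[3]])
  s3 <- net$skip3$fwd(x3, zero_if(e3, "enc_skip3"),
                      if (cfg$dense_skips)
                        zero_if(e2, "dense_branch2") else NULL)
  d3 <- run_stage_fwd(net$dec3, s3)
  x2 <- net$exp2$fwd(d3, g[[2]])
  s2 <- net$skip2$fwd(x2, zero_if(e2, "enc_skip2"),
                      if (cfg$dense_skips)
                        zero_if(e1, "dense_branch1") else NULL)
  d2 <- run_stage_fwd(net$dec2, s2)
  x1 <- net$exp1$fwd(d2, g[[1]])
  s1 <- net$skip1$fwd(x1, zero_if(e1, "enc_skip1"))
  d1 <- run_stage_fwd(net$dec1, s1)
  xh <- net$exp_h$fwd(d1)
  fh <- net$fuse_h$fwd(bind4(xh, zero_if(sb, "stem_half")))
  xf <- net$exp_f$fwd(fh)
  h1 <- net$scse1$fwd(net$head1$fwd(bind4(xf, zero_if(sa, "stem_full"))))
  h2 <- net$scse2$fwd(net$snake_act$fwd(net$snake_norm$fwd(
    net$snake$fwd(h1))))
  net$final$fwd(h2)
}

stunet_backward <- function(net, dfield) {
  cfg <- net$cfg
  C <- cfg$swin$embed_dim
  dh2 <- net$final$bwd(dfield)
  dh1 <- net$scse1$bwd(net$snake$bwd(net$snake_norm$bwd(
    net$snake_act$bwd(net$scse2$bwd(dh2)))))
  dcat <- net$head1$bwd(dh1)
  C4 <- C %/% 4L
  dxf <- dcat[, , , seq_len(C4), drop = FALSE]
  dsa <- dcat[, , , C4 + seq_len(cfg$stem_channels), drop = FALSE]
  dfh <- net$exp_f$bwd(dxf)
  dch <- net$fuse_h$bwd(dfh)
  C2 <- C %/% 2L
  dxh <- dch[, , , seq_len(C2), drop = FALSE]
  dsb <- dch[, , , C2 + seq_len(C2), drop = FALSE]
  dd1 <- net$exp_h$bwd(dxh)
  ds1 <- run_stage_bwd(net$dec1, dd1)
  sk1 <- net$skip1$bwd(ds1)
  de1 <- sk1$enc
  dd2 <- net$exp1$bwd(sk1$cur)
  ds2 <- run_stage_bwd(net$dec2, dd2)
  sk2 <- net$skip2$bwd(ds2)
  de2 <- sk2$enc
  if (!is.null(sk2$shallow)) de1 <- de1 + sk2$shallow
  dd3 <- net$exp2$bwd(sk2$cur)
  ds3 <- run_stage_bwd(net$dec3, dd3)
  sk3 <- net$skip3$bwd(ds3)
  de3 <- sk3$enc
  if (!is.null(sk3$shallow)) de2 <- de2 + sk3$shallow
  dd4 <- net$exp3$bwd(sk3$cur)
  de4 <- run_stage_bwd(net$dec4, dd4)
  de3 <- de3 + net$merge3$bwd(run_stage_bwd(net$enc4, de4))
  de2 <- de2 + net$merge2$bwd(run_stage_bwd(net$enc3, de3))
  de1 <- de1 + net$merge1$bwd(run_stage_bwd(net$enc2, de2))
  dt1 <- run_stage_bwd(net$enc1, de1)
  dx <- net$embed$bwd(dt1)
  dsa <- dsa + net$stem_b$bwd(dsb)
  dx <- dx + net$stem_a$bwd(dsa)
  invisible(dx)
}

#' Register a pair of volumes with a network
#'
#' Runs the model forward on a (moving, fixed) pair and warps the moving
#' image by the predicted displacement field.
#'
#' @param object a [stunet()] model.
#' @param moving,fixed [volume3d()] objects matching the configured shape.
#' @param ... unused.
#' @return a `registration_output`: list with `field` (a [dispfield()])
#'   and `warped` (a [volume3d()]).
#' @export
predict.stunet <- function(object, moving, fixed, ...) {
  field <- stunet_forward(object, vol_data(moving), vol_data(fixed))
  fld <- dispfield(field)
  structure(list(field = fld,
                 warped = warp_volume(moving, fld, "trilinear")),
            class = "registration_output")
}

#' @export
print.registration_output <- function(x, ...) {
  cat("<registration_output>\n  ")
  print(x$field)
  cat(sprintf("  %% det<=0: %.4g\n",
              100 * pct_nondiffeomorphic(x$field)))
  invisible(x)
}

#' @export
print.stunet <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), 1))
  cat(sprintf(
    "<stunet: input %s, embed %d, stem %d, head %d, %s params>\n",
    paste(x$cfg$shape, collapse = "x"), x$cfg$swin$embed_dim,
    x$cfg$stem_channels, x$cfg$head_channels, format(np, big.mark = ",")))
  invisible(x)
}

#' @export
summary.stunet <- function(object, ...) {
  print(object)
  cat(sprintf("  swin depths: %s, heads: %s, window: %s\n",
              paste(object$cfg$swin$depths, collapse = ","),
              paste(object$cfg$swin$heads, collapse = ","),
              paste(object$cfg$swin$window, collapse = "x")))
  cat(sprintf("  token grids: %s\n",
              paste(vapply(object$grids, function(g)
                paste(g, collapse = "x"), ""), collapse = " | ")))
  cat(sprintf("  dense skips: %s, norm: %s, snake taps: %d\n",
              object$cfg$dense_skips, object$cfg$norm,
              object$cfg$snake$points_per_kernel))
  invisible(object)
}

# flat parameter state for checkpoints
net_state <- function(net) lapply(net$params, function(p) p$value)

net_load_state <- function(net, state) {
  stopifnot(length(state) == length(net$params))
  for (i in seq_along(state)) {
    stopifnot(length(net$params[[i]]$value) == length(state[[i]]))
    net$params[[i]]$value <- state[[i]]
  }
  invisible(net)
}

#' Save / load a network checkpoint
#'
#' Checkpoints embed the full [network_config()] so a saved model can be
#' reconstructed without external context.
#'
#' @param net a [stunet()] model.
#' @param path file path (`.rds`).
#' @export
stunet_save <- function(net, path) {
  saveRDS(list(config = net$cfg, state = net_state(net),
               package_version = as.character(
                 utils::packageVersion("snakereg"))), path)
  invisible(path)
}

#' @rdname stunet_save
#' @export
stunet_load <- function(path) {
  ck <- readRDS(path)
  net <- stunet(ck$config)
  net_load_state(net, ck$state)
  net
}
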