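#' Hyperparameters of the pit-and-fissure generation network
#'
#' Defaults follow the established training configuration: Adam with learning
#' rate 2e-4 and momenta (0.5, 0.999), batch size 1, 200 epochs, L1 weight
#' `lambda_l1 = 100`, perceptual weights `lambda_pg = 50` (generator side) and
#' `lambda_pd = 20` (discriminator side) with hinge margin `margin = 0.35`,
#' and per-layer perceptual weights 1, 2, 2 on discriminator stages 2-4.
#'
#' Ablation groups select the loss terms: group 1 trains with the adversarial
#' objective under the jaw-space (opposing tooth) conditioning only, group 2
#' adds the L1 term, group 3 adds the perceptual-feature terms.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam momentum parameters.
#' @param batch_size samples per update (the method uses 1).
#' @param epochs passes over the training set.
#' @param lambda_l1 weight of the L1 reconstruction term.
#' @param lambda_pg,lambda_pd generator/discriminator perceptual weights.
#' @param margin hinge boundary m of the discriminator feature loss.
#' @param layer_weights perceptual weights of discriminator stages 2, 3, 4.
#' @param group ablation group, 1, 2 or 3.
#' @param base_width channels of the first conv stage.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param noise_mode `"dropout"` (generator dropout acts as the noise source
#'   during training) or `"off"` for fully deterministic training.
#' @param eps probability clamp inside logs.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                       batch_size = 1, epochs = 200, lambda_l1 = 100,
                       lambda_pg = 50, lambda_pd = 20, margin = 0.35,
                       layer_weights = c(1, 2, 2), group = 3, base_width = 64,
                       seed = 1L, noise_mode = c("dropout", "off"),
                       eps = 1e-7) {
  if (!group %in% 1:3) stop("ablation group must be 1, 2 or 3")
  if (any(c(lambda_l1, lambda_pg, lambda_pd, layer_weights) < 0)) {
    stop("loss weights must be >= 0")
  }
  if (margin < 0) stop("margin must be >= 0")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lambda_l1 = lambda_l1, lambda_pg = lambda_pg,
                 lambda_pd = lambda_pd, margin = margin,
                 layer_weights = layer_weights, group = as.integer(group),
                 base_width = as.integer(base_width), seed = as.integer(seed),
                 noise_mode = match.arg(noise_mode), eps = eps),
            class = "gan_config")
}

#' U-Net generator architecture
#'
#' Symmetric encoder/decoder with stride-2 4x4 convolutions; encoder stage i
#' is skip-connected to decoder stage `depth - i` by channel concatenation,
#' so the input and output spatial sizes are equal. Channel widths double up
#' to `8 * base_width` and the innermost stage reduces the image to 1x1.
#'
#' @param resolution input image side (power of two, >= 16).
#' @param in_channels conditioning channels (mask + opposing = 2).
#' @param out_channels generated channels (1).
#' @param base_width first-stage channel count.
#' @param enc_channels,dec_channels optional explicit channel plans; the
#'   decoder plan must mirror the encoder (length `depth - 1`).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(resolution = 256, in_channels = 2, out_channels = 1,
                           base_width = 64, enc_channels = NULL,
                           dec_channels = NULL) {
  depth <- log2(resolution)
  if (resolution < 16 || depth != round(depth)) {
    stop("resolution must be a power of two >= 16")
  }
  depth <- as.integer(depth)
  if (is.null(enc_channels)) {
    enc_channels <- base_width * pmin(2^(seq_len(depth) - 1), 8)
  }
  if (is.null(dec_channels)) {
    dec_channels <- rev(enc_channels)[-1]
  }
  if (length(enc_channels) != depth || length(dec_channels) != depth - 1) {
    stop("asymmetric generator spec: need ", depth, " encoder and ",
         depth - 1, " decoder stages for resolution ", resolution)
  }
  structure(list(resolution = as.integer(resolution),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = depth, enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels)),
            class = "generator_spec")
}

#' Patch-based discriminator architecture
#'
#' Four 4x4 conv stages (strides 2, 2, 2, 1) with channel widths
#' `base_width * (1, 2, 4, 8)` followed by a stride-1 projection to a single
#' channel and a sigmoid, yielding an `N x N` matrix of per-patch real/fake
#' probabilities (30x30 at 256x256 input). Hidden stages named in
#' `exposed_layers` are returned by the forward pass for the perceptual loss.
#'
#' @param resolution input image side.
#' @param in_channels input channels (mask + opposing + candidate = 3).
#' @param base_width first-stage channel count.
#' @param exposed_layers indices of conv stages exposed for the perceptual
#'   feature deviation (default 2:4).
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(resolution = 256, in_channels = 3,
                               base_width = 64, exposed_layers = 2:4) {
  channels <- base_width * c(1, 2, 4, 8)
  strides <- c(2, 2, 2, 1)
  s <- resolution
  for (st in c(strides, 1)) s <- (s + 2 - 4) %/% st + 1
  if (s < 1) stop("resolution too small for the patch stack (need >= 32)")
  structure(list(resolution = as.integer(resolution),
                 in_channels = as.integer(in_channels),
                 channels = as.integer(channels), strides = as.integer(strides),
                 kernel = 4L, patch_size = as.integer(s),
                 exposed_layers = as.integer(exposed_layers)),
            class = "discriminator_spec")
}

#' Build (initialize) the U-Net generator
#'
#' Conv weights are drawn from N(0, 0.02) and batch-normalization gains from
#' N(1, 0.02) using the current RNG state; seed the RNG for reproducible
#' initialization. Normalization is omitted on the first encoder stage and on
#' the innermost stage (1x1 spatial size).
#'
#' @param spec a [generator_spec].
#' @return An object of class `gan_generator` holding all parameters.
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  L <- spec$depth
  enc <- vector("list", L)
  c_prev <- spec$in_channels
  for (i in seq_len(L)) {
    enc[[i]] <- list(conv = nn_init_conv(c_prev, spec$enc_channels[i]))
    if (i > 1 && i < L) enc[[i]]$bn <- nn_init_bn(spec$enc_channels[i])
    c_prev <- spec$enc_channels[i]
  }
  dec <- vector("list", L)
  for (j in seq_len(L)) {
    c_in <- if (j == 1) spec$enc_channels[L] else
      spec$dec_channels[j - 1] + spec$enc_channels[L - j + 1]
    c_out <- if (j == L) spec$out_channels else spec$dec_channels[j]
    dec[[j]] <- list(tconv = nn_init_tconv(c_in, c_out))
    if (j < L) dec[[j]]$bn <- nn_init_bn(c_out)
  }
  structure(list(spec = spec, enc = enc, dec = dec), class = "gan_generator")
}

#' Build (initialize) the patch discriminator
#'
#' @param spec a [discriminator_spec].
#' @return An object of class `gan_discriminator`.
#' @export
build_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  stages <- vector("list", 5)
  c_prev <- spec$in_channels
  for (i in 1:4) {
    stages[[i]] <- list(conv = nn_init_conv(c_prev, spec$channels[i]))
    if (i > 1) stages[[i]]$bn <- nn_init_bn(spec$channels[i])
    c_prev <- spec$channels[i]
  }
  stages[[5]] <- list(conv = nn_init_conv(c_prev, 1L))
  structure(list(spec = spec, stages = stages), class = "gan_discriminator")
}

# stack H x W matrices into a (C, H, W) array
stack_chw <- function(...) {
  mats <- list(...)
  H <- nrow(mats[[1]])
  W <- ncol(mats[[1]])
  out <- array(0, c(length(mats), H, W))
  for (i in seq_along(mats)) out[i, , ] <- mats[[i]]
  out
}

# pixel [0,255] <-> network [-1,1]
img_to_net <- function(px) as.matrix(px) / 127.5 - 1
net_to_img <- function(v) pmin(pmax(round_half_up((v + 1) * 127.5), 0), 255)

generator_forward <- function(g, x, op, train = FALSE, dropout = FALSE) {
  L <- g$spec$depth
  inp <- stack_chw(x, op)
  acts <- vector("list", L)
  ctxs <- list(enc = vector("list", L), dec = vector("list", L))
  h <- inp
  for (i in seq_len(L)) {
    st <- g$enc[[i]]
    cv <- conv_fwd(st$conv, h, 4, 2, 1)
    ctxs$enc[[i]]$conv <- cv$ctx
    h <- cv$out
    if (!is.null(st$bn)) {
      bn <- bn_fwd(st$bn, h)
      ctxs$enc[[i]]$bn <- bn$ctx
      h <- bn$out
    }
    ac <- lrelu_fwd(h)
    ctxs$enc[[i]]$act <- ac$ctx
    h <- ac$out
    acts[[i]] <- h
  }
  for (j in seq_len(L)) {
    st <- g$dec[[j]]
    if (j > 1) {
      skip <- acts[[L - j + 1]]
      ctxs$dec[[j]]$split <- dim(h)[1]      # channels of the decoder part
      h <- abind_chw(h, skip)
    }
    tc <- tconv_fwd(st$tconv, h)
    ctxs$dec[[j]]$tconv <- tc$ctx
    h <- tc$out
    if (j < L) {
      bn <- bn_fwd(st$bn, h)
      ctxs$dec[[j]]$bn <- bn$ctx
      h <- bn$out
      if (j <= 3 && dropout) {
        dr <- dropout_fwd(h, 0.5, active = TRUE)
        ctxs$dec[[j]]$drop <- dr$ctx
        h <- dr$out
      }
      ac <- relu_fwd(h)
      ctxs$dec[[j]]$act <- ac$ctx
      h <- ac$out
    } else {
      ac <- tanh_fwd(h)
      ctxs$dec[[j]]$act <- ac$ctx
      h <- ac$out
    }
  }
  list(out = matrix(h[1, , ], dim(h)[2]), ctxs = if (train) ctxs else NULL)
}

abind_chw <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1] + dim(b)[1], d[2], d[3]))
  out[seq_len(d[1]), , ] <- a
  out[d[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

generator_backward <- function(g, dout, ctxs) {
  L <- g$spec$depth
  grads <- list(enc = vector("list", L), dec = vector("list", L))
  dskip <- vector("list", L)     # gradients flowing into encoder activations
  h <- array(dout, c(1, nrow(dout), ncol(dout)))
  for (j in rev(seq_len(L))) {
    st <- g$dec[[j]]
    cx <- ctxs$dec[[j]]
    if (j < L) {
      h <- relu_bwd(h, cx$act)
      if (!is.null(cx$drop)) h <- dropout_bwd(h, cx$drop)
      bn <- bn_bwd(st$bn, h, cx$bn)
      grads$dec[[j]]$bn <- list(gamma = bn$dgamma, beta = bn$dbeta)
      h <- bn$dx
    } else {
      h <- tanh_bwd(h, cx$act)
    }
    tc <- tconv_bwd(st$tconv, h, cx$tconv)
    grads$dec[[j]]$tconv <- list(W = tc$dW, b = tc$db)
    h <- tc$dx
    if (j > 1) {
      nsplit <- cx$split
      dskip[[L - j + 1]] <- h[-seq_len(nsplit), , , drop = FALSE]
      h <- h[seq_len(nsplit), , , drop = FALSE]
    }
  }
  for (i in rev(seq_len(L))) {
    st <- g$enc[[i]]
    cx <- ctxs$enc[[i]]
    if (!is.null(dskip[[i]])) h <- h + dskip[[i]]
    h <- lrelu_bwd(h, cx$act)
    if (!is.null(st$bn)) {
      bn <- bn_bwd(st$bn, h, cx$bn)
      grads$enc[[i]]$bn <- list(gamma = bn$dgamma, beta = bn$dbeta)
      h <- bn$dx
    }
    cv <- conv_bwd(st$conv, h, cx$conv)
    grads$enc[[i]]$conv <- list(W = cv$dW, b = cv$db)
    h <- cv$dx
  }
  grads
}

discriminator_forward <- function(d, x, op, candidate, train = FALSE) {
  inp <- stack_chw(x, op, candidate)
  ctxs <- vector("list", 5)
  acts <- list()
  h <- inp
  strides <- c(d$spec$strides, 1L)
  for (i in 1:5) {
    st <- d$stages[[i]]
    cv <- conv_fwd(st$conv, h, 4, strides[i], 1)
    ctxs[[i]]$conv <- cv$ctx
    h <- cv$out
    if (i < 5) {
      if (!is.null(st$bn)) {
        bn <- bn_fwd(st$bn, h)
        ctxs[[i]]$bn <- bn$ctx
        h <- bn$out
      }
      ac <- lrelu_fwd(h)
      ctxs[[i]]$act <- ac$ctx
      h <- ac$out
      if (i %in% d$spec$exposed_layers) acts[[as.character(i)]] <- h
    } else {
      ac <- sigmoid_fwd(h)
      ctxs[[i]]$act <- ac$ctx
      h <- ac$out
    }
  }
  list(patch = matrix(h[1, , ], dim(h)[2]), acts = acts,
       ctxs = if (train) ctxs else NULL)
}

# dpatch: gradient at the patch probability matrix; dacts: optional named
# list of gradients at the exposed activations. Returns parameter grads and
# the gradient at the input block.
discriminator_backward <- function(d, dpatch, ctxs, dacts = NULL) {
  grads <- vector("list", 5)
  strides <- c(d$spec$strides, 1L)
  h <- array(dpatch, c(1, nrow(dpatch), ncol(dpatch)))
  for (i in 5:1) {
    st <- d$stages[[i]]
    cx <- ctxs[[i]]
    if (i < 5) {
      if (!is.null(dacts[[as.character(i)]])) {
        h <- h + dacts[[as.character(i)]]
      }
      h <- lrelu_bwd(h, cx$act)
      if (!is.null(st$bn)) {
        bn <- bn_bwd(st$bn, h, cx$bn)
        grads[[i]]$bn <- list(gamma = bn$dgamma, beta = bn$dbeta)
        h <- bn$dx
      }
    } else {
      h <- sigmoid_bwd(h, cx$act)
    }
    cv <- conv_bwd(st$conv, h, cx$conv)
    grads[[i]]$conv <- list(W = cv$dW, b = cv$db)
    h <- cv$dx
  }
  list(grads = grads, dinput = h)
}

#' Adversarial log terms from patch probability matrices
#'
#' Patch probabilities are averaged into the scalar discriminator output and
#' clamped away from 0 and 1 before the logarithm, giving the two terms of
#' the conditional adversarial objective:
#' `log D(x, op, y)` and `log(1 - D(x, op, G(x, op, z)))`.
#'
#' @param real_patch,fake_patch probability matrices from the discriminator
#'   on the target and on the generated image.
#' @param eps probability clamp.
#' @return List with `log_d_real`, `log_one_minus_d_fake`, and the averaged
#'   probabilities `p_real`, `p_fake`.
#' @export
adversarial_terms <- function(real_patch, fake_patch, eps = 1e-7) {
  if (!all(dim(as.matrix(real_patch)) == dim(as.matrix(fake_patch)))) {
    stop("patch matrices must have equal shape")
  }
  p_real <- mean(real_patch)
  p_fake <- mean(fake_patch)
  list(log_d_real = log(pmin(pmax(p_real, eps), 1 - eps)),
       log_one_minus_d_fake = log(pmin(pmax(1 - p_fake, eps), 1 - eps)),
       p_real = p_real, p_fake = p_fake)
}

#' Mean absolute (L1) reconstruction term
#'
#' @param g_out,y images on the normalized pixel scale, equal shape.
#' @return Mean absolute difference.
#' @export
l1_term <- function(g_out, y) {
  if (!all(dim(as.matrix(g_out)) == dim(as.matrix(y)))) {
    stop("images must have equal shape")
  }
  mean(abs(g_out - y))
}

#' Per-layer perceptual feature deviation and its weighted sum
#'
#' For each exposed discriminator layer i, the deviation is the
#' size-normalized elementwise absolute difference of the activations,
#' `S_i = (1 / (C_i H_i W_i)) * sum |h_i(y) - h_i(G)|`; the weighted sum uses
#' the per-layer weights (defaults 1, 2, 2 for layers 2-4).
#'
#' @param acts_y,acts_g lists of activation arrays from the discriminator
#'   forward pass on the target and generated image.
#' @param layer_weights per-layer weights, recycled to the number of layers.
#' @return List with `per_layer` deviations and `weighted_sum`.
#' @export
perceptual_deviation <- function(acts_y, acts_g, layer_weights = c(1, 2, 2)) {
  if (length(acts_y) != length(acts_g)) stop("layer lists must match")
  s <- mapply(function(a, b) {
    if (!all(dim(a) == dim(b))) stop("mismatched activation shapes")
    mean(abs(a - b))
  }, acts_y, acts_g)
  w <- rep_len(layer_weights, length(s))
  list(per_layer = s, weighted_sum = sum(w * s))
}

#' Generator objective value
#'
#' Combines the (non-saturating) adversarial term with the weighted L1 and
#' perceptual terms according to the ablation group: group 1 uses the
#' adversarial term alone, group 2 adds `lambda_l1 * l1`, group 3 adds
#' `lambda_pg * perceptual` as well.
#'
#' @param config a [gan_config].
#' @param adversarial generator adversarial term (`-log D(fake)`).
#' @param l1 L1 term from [l1_term()].
#' @param perceptual weighted perceptual sum from [perceptual_deviation()].
#' @return Scalar loss.
#' @export
generator_loss <- function(config, adversarial, l1 = 0, perceptual = 0) {
  stopifnot(inherits(config, "gan_config"))
  if (!all(is.finite(c(adversarial, l1, perceptual)))) {
    stop("loss components must be finite")
  }
  switch(config$group,
         adversarial,
         adversarial + config$lambda_l1 * l1,
         adversarial + config$lambda_l1 * l1 + config$lambda_pg * perceptual)
}

#' Discriminator objective value
#'
#' The negated adversarial terms `-(log D(real) + log(1 - D(fake)))`
#' (minimized), plus — in group 3 — the hinge feature term
#' `lambda_pd * max(0, m - sum_i lambda_i S_i)`, which is inactive once the
#' feature deviation reaches the margin.
#'
#' @param config a [gan_config].
#' @param adv_terms list from [adversarial_terms()].
#' @param perceptual_sum weighted deviation sum from [perceptual_deviation()].
#' @return Scalar loss.
#' @export
discriminator_loss <- function(config, adv_terms, perceptual_sum = 0) {
  stopifnot(inherits(config, "gan_config"))
  base <- -(adv_terms$log_d_real + adv_terms$log_one_minus_d_fake)
  if (config$group == 3) {
    base + config$lambda_pd * max(0, config$margin - perceptual_sum)
  } else {
    base
  }
}

#' Train the pit-and-fissure generation network
#'
#' Alternates single-sample discriminator and generator updates (Adam, batch
#' size 1) over the training split of a dataset manifest. All randomness —
#' initialization, per-epoch shuffling, generator dropout — derives from
#' `config$seed`, so runs are exactly reproducible.
#'
#' @param manifest dataset manifest tibble (from [generate_dataset()] or
#'   [read_manifest()]); rows with `role == "train"` are used.
#' @param config a [gan_config].
#' @param iterations optional cap on update iterations (default
#'   `epochs * n_train`).
#' @return List with `checkpoint` (class `gan_checkpoint`) and `history`
#'   (tibble with per-iteration loss components).
#' @export
train_gan <- function(manifest, config = gan_config(), iterations = NULL) {
  stopifnot(inherits(config, "gan_config"))
  train_rows <- manifest[manifest$role == "train", , drop = FALSE]
  if (nrow(train_rows) == 0) stop("manifest has no training samples")
  data <- lapply(seq_len(nrow(train_rows)), function(i) {
    list(x = img_to_net(read_depth_image(train_rows$x_path[i])),
         op = img_to_net(read_depth_image(train_rows$op_path[i])),
         y = img_to_net(read_depth_image(train_rows$y_path[i])))
  })
  res <- nrow(data[[1]]$x)
  n <- length(data)
  n_iter <- as.integer(iterations %||% (config$epochs * n))

  with_preserved_seed(config$seed, {
    g <- build_generator(generator_spec(res, base_width = config$base_width))
    d <- build_discriminator(discriminator_spec(res,
                                                base_width = config$base_width))
    # parameter trees alias the networks' own matrices (in-place updates)
    par_g <- list(enc = lapply(g$enc, strip_params),
                  dec = lapply(g$dec, strip_params))
    par_d <- list(stages = lapply(d$stages, strip_params))
    opt_g <- adam_init(par_g)
    opt_d <- adam_init(par_d)
    hist <- vector("list", n_iter)
    order <- integer(0)
    use_dropout <- config$noise_mode == "dropout"
    for (it in seq_len(n_iter)) {
      if (length(order) == 0) order <- sample.int(n)
      s <- data[[order[1]]]
      order <- order[-1]
      step <- gan_train_step(g, d, s, config, par_g, par_d, opt_g, opt_d,
                             use_dropout)
      opt_g <- step$opt_g; opt_d <- step$opt_d
      row <- step$metrics
      if (!all(is.finite(unlist(row)))) {
        stop("non-finite loss at iteration ", it)
      }
      hist[[it]] <- tibble::tibble(iteration = it, loss_g = row$loss_g,
                                   loss_d = row$loss_d, adv_g = row$adv_g,
                                   adv_d = row$adv_d, l1 = row$l1,
                                   perceptual = row$perceptual)
    }
    checkpoint <- structure(list(generator = g, discriminator = d,
                                 config = config, resolution = res),
                            class = "gan_checkpoint")
    list(checkpoint = checkpoint, history = do.call(rbind, hist))
  })
}

strip_params <- function(stage) {
  stage[intersect(names(stage), c("conv", "tconv", "bn"))]
}

# one alternating D-then-G update on a single (x, op, y) sample;
# par_g / par_d alias the networks' parameters, which are updated in place
gan_train_step <- function(g, d, s, config, par_g, par_d, opt_g, opt_d,
                           use_dropout) {
  eps <- config$eps
  lw <- config$layer_weights
  np_clamp <- function(p) pmin(pmax(p, eps), 1 - eps)

  gf <- generator_forward(g, s$x, s$op, train = TRUE, dropout = use_dropout)
  g_out <- gf$out

  # ---- discriminator update (generator frozen) --------------------------
  fr <- discriminator_forward(d, s$x, s$op, s$y, train = TRUE)
  ff <- discriminator_forward(d, s$x, s$op, g_out, train = TRUE)
  adv <- adversarial_terms(fr$patch, ff$patch, eps)
  perc <- if (config$group == 3 && length(fr$acts) > 0) {
    perceptual_deviation(fr$acts, ff$acts, lw)
  } else {
    list(per_layer = numeric(0), weighted_sum = 0)
  }
  loss_d <- discriminator_loss(config, adv, perc$weighted_sum)

  np <- length(fr$patch)
  dpatch_real <- matrix(-1 / (np_clamp(adv$p_real) * np),
                        nrow(fr$patch), ncol(fr$patch))
  dpatch_fake <- matrix(1 / (np_clamp(1 - adv$p_fake) * np),
                        nrow(ff$patch), ncol(ff$patch))
  dacts_real <- NULL
  dacts_fake_d <- NULL
  hinge_active <- config$group == 3 && perc$weighted_sum < config$margin
  if (hinge_active) {
    dacts_real <- list()
    dacts_fake_d <- list()
    for (k in seq_along(fr$acts)) {
      nm <- names(fr$acts)[k]
      sg <- sign(fr$acts[[k]] - ff$acts[[k]]) / length(fr$acts[[k]])
      dacts_real[[nm]] <- -config$lambda_pd * lw[k] * sg
      dacts_fake_d[[nm]] <- config$lambda_pd * lw[k] * sg
    }
  }
  br <- discriminator_backward(d, dpatch_real, fr$ctxs, dacts_real)
  bf <- discriminator_backward(d, dpatch_fake, ff$ctxs, dacts_fake_d)
  gd <- add_grads(br$grads, bf$grads)
  opt_d <- adam_step_inplace(par_d, list(stages = gd), opt_d,
                             config$learning_rate, config$beta1, config$beta2)

  # ---- generator update (against the updated discriminator) -------------
  fr2 <- discriminator_forward(d, s$x, s$op, s$y, train = FALSE)
  ff2 <- discriminator_forward(d, s$x, s$op, g_out, train = TRUE)
  p_fake2 <- mean(ff2$patch)
  adv_g <- -log(np_clamp(p_fake2))
  l1 <- l1_term(g_out, s$y)
  perc2 <- if (config$group == 3 && length(ff2$acts) > 0) {
    perceptual_deviation(fr2$acts, ff2$acts, lw)
  } else {
    list(per_layer = numeric(0), weighted_sum = 0)
  }
  loss_g <- generator_loss(config, adv_g,
                           if (config$group >= 2) l1 else 0,
                           perc2$weighted_sum)

  np2 <- length(ff2$patch)
  dpatch_g <- matrix(-1 / (np_clamp(p_fake2) * np2),
                     nrow(ff2$patch), ncol(ff2$patch))
  dacts_g <- NULL
  if (config$group == 3 && length(ff2$acts) > 0) {
    dacts_g <- list()
    for (k in seq_along(ff2$acts)) {
      nm <- names(ff2$acts)[k]
      dacts_g[[nm]] <- config$lambda_pg * lw[k] *
        sign(ff2$acts[[k]] - fr2$acts[[k]]) / length(ff2$acts[[k]])
    }
  }
  bg <- discriminator_backward(d, dpatch_g, ff2$ctxs, dacts_g)
  dg_out <- matrix(bg$dinput[3, , ], dim(bg$dinput)[2])
  if (config$group >= 2) {
    dg_out <- dg_out + config$lambda_l1 * sign(g_out - s$y) / length(g_out)
  }
  grads_g <- generator_backward(g, dg_out, gf$ctxs)
  opt_g <- adam_step_inplace(par_g,
                             list(enc = grads_g$enc, dec = grads_g$dec), opt_g,
                             config$learning_rate, config$beta1, config$beta2)

  list(opt_g = opt_g, opt_d = opt_d,
       metrics = list(loss_g = loss_g, loss_d = loss_d, adv_g = adv_g,
                      adv_d = -(adv$log_d_real + adv$log_one_minus_d_fake),
                      l1 = l1, perceptual = perc2$weighted_sum))
}

add_grads <- function(a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- add_grads(a[[nm]], b[[nm]])
    out
  } else {
    a + b
  }
}


#' Generate a pit-and-fissure image from a trained checkpoint
#'
#' Single forward pass in inference mode (dropout off), quantized back to
#' 8-bit with round-half-up. Deterministic for fixed inputs.
#'
#' @param checkpoint a `gan_checkpoint` from [train_gan()].
#' @param x mask [depth_image] (or plain matrix of 0-255 values).
#' @param op opposing [depth_image] on the same raster.
#' @return A [depth_image] carrying `x`'s projection metadata, if any.
#' @export
gan_generate <- function(checkpoint, x, op) {
  stopifnot(inherits(checkpoint, "gan_checkpoint"))
  if (nrow(as.matrix(x)) != checkpoint$resolution) {
    stop("input resolution ", nrow(as.matrix(x)),
         " does not match checkpoint resolution ", checkpoint$resolution)
  }
  out <- generator_forward(checkpoint$generator, img_to_net(x), img_to_net(op),
                           train = FALSE, dropout = FALSE)$out
  depth_image(net_to_img(out), attr(x, "config"))
}

#' Save / load a training checkpoint
#'
#' @param checkpoint a `gan_checkpoint`.
#' @param path file path (RDS).
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "gan_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no checkpoint at ", path)
  ck <- readRDS(path)
  stopifnot(inherits(ck, "gan_checkpoint"))
  ck
}
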