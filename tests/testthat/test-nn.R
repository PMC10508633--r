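# The layer engine is validated against finite differences and against
# shape/algebra identities; network-level checks live in test-gan.R.

test_that("convolution and transposed convolution are shape-inverse", {
  set.seed(1)
  x <- array(stats::rnorm(3 * 16 * 16), c(3, 16, 16))
  cv <- occlugen:::nn_init_conv(3, 5)
  f <- occlugen:::conv_fwd(cv, x, 4, 2, 1)
  expect_equal(dim(f$out), c(5, 8, 8))
  tc <- occlugen:::nn_init_tconv(5, 3)
  u <- occlugen:::tconv_fwd(tc, f$out)
  expect_equal(dim(u$out), c(3, 16, 16))
})

test_that("layer backward passes match central finite differences", {
  set.seed(2)
  x <- array(stats::rnorm(2 * 8 * 8), c(2, 8, 8))
  cv <- occlugen:::nn_init_conv(2, 3)
  target <- array(stats::rnorm(3 * 4 * 4), c(3, 4, 4))
  loss <- function(par, xx) {
    sum((occlugen:::conv_fwd(par, xx, 4, 2, 1)$out - target)^2)
  }
  f <- occlugen:::conv_fwd(cv, x, 4, 2, 1)
  b <- occlugen:::conv_bwd(cv, 2 * (f$out - target), f$ctx)
  eps <- 1e-6
  for (ii in c(1, 17, 60)) {
    pp <- cv; pp$W[ii] <- pp$W[ii] + eps
    pm <- cv; pm$W[ii] <- pm$W[ii] - eps
    expect_equal(b$dW[ii], (loss(pp, x) - loss(pm, x)) / (2 * eps),
                 tolerance = 1e-5)
  }
  xp <- x; xp[31] <- xp[31] + eps
  xm <- x; xm[31] <- xm[31] - eps
  expect_equal(b$dx[31], (loss(cv, xp) - loss(cv, xm)) / (2 * eps),
               tolerance = 1e-5)

  # batch normalization
  bn <- occlugen:::nn_init_bn(2)
  tgt2 <- array(stats::rnorm(2 * 8 * 8), c(2, 8, 8))
  lossbn <- function(par, xx) sum((occlugen:::bn_fwd(par, xx)$out - tgt2)^2)
  fb <- occlugen:::bn_fwd(bn, x)
  bb <- occlugen:::bn_bwd(bn, 2 * (fb$out - tgt2), fb$ctx)
  xp <- x; xp[5] <- xp[5] + eps
  xm <- x; xm[5] <- xm[5] - eps
  expect_equal(bb$dx[5], (lossbn(bn, xp) - lossbn(bn, xm)) / (2 * eps),
               tolerance = 1e-4)
  gp <- bn; gp$gamma[2] <- gp$gamma[2] + eps
  gm <- bn; gm$gamma[2] <- gm$gamma[2] - eps
  expect_equal(bb$dgamma[2], (lossbn(gp, x) - lossbn(gm, x)) / (2 * eps),
               tolerance = 1e-4)

  # transposed convolution
  tc <- occlugen:::nn_init_tconv(2, 3)
  tgt3 <- array(stats::rnorm(3 * 16 * 16), c(3, 16, 16))
  losstc <- function(par, xx) sum((occlugen:::tconv_fwd(par, xx)$out - tgt3)^2)
  ft <- occlugen:::tconv_fwd(tc, x)
  bt <- occlugen:::tconv_bwd(tc, 2 * (ft$out - tgt3), ft$ctx)
  for (ii in c(3, 40)) {
    pp <- tc; pp$W[ii] <- pp$W[ii] + eps
    pm <- tc; pm$W[ii] <- pm$W[ii] - eps
    expect_equal(bt$dW[ii], (losstc(pp, x) - losstc(pm, x)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("the in-place Adam kernel reproduces the reference update", {
  set.seed(3)
  p <- stats::rnorm(50)
  g <- stats::rnorm(50)
  p0 <- p
  m <- numeric(50)
  v <- numeric(50)
  lr <- 2e-4; b1 <- 0.5; b2 <- 0.999; eps <- 1e-8
  t <- 1
  lr_t <- lr * sqrt(1 - b2^t) / (1 - b1^t)
  m_ref <- (1 - b1) * g
  v_ref <- (1 - b2) * g^2
  p_ref <- p0 - lr_t * m_ref / (sqrt(v_ref) + eps)
  occlugen:::cpp_adam_update(p, g, m, v, lr_t, b1, b2, eps)
  expect_equal(p, p_ref, tolerance = 1e-14)
  expect_equal(m, m_ref, tolerance = 1e-14)
  expect_equal(v, v_ref, tolerance = 1e-14)
})

test_that("generator parameter gradients match finite differences", {
  set.seed(5)
  res <- 32
  g <- build_generator(generator_spec(res, base_width = 2))
  d <- build_discriminator(discriminator_spec(res, base_width = 2))
  xs <- matrix(stats::runif(res^2, -1, 1), res)
  ops <- matrix(stats::runif(res^2, -1, 1), res)
  ys <- matrix(stats::runif(res^2, -1, 1), res)
  cfg <- gan_config(group = 3, base_width = 2, noise_mode = "off")

  loss_of <- function(gt) {
    gf <- occlugen:::generator_forward(gt, xs, ops, train = TRUE,
                                       dropout = FALSE)
    fr <- occlugen:::discriminator_forward(d, xs, ops, ys)
    ff <- occlugen:::discriminator_forward(d, xs, ops, gf$out)
    adv <- -log(min(max(mean(ff$patch), cfg$eps), 1 - cfg$eps))
    pc <- perceptual_deviation(fr$acts, ff$acts, cfg$layer_weights)
    generator_loss(cfg, adv, l1_term(gf$out, ys), pc$weighted_sum)
  }
  gf <- occlugen:::generator_forward(g, xs, ops, train = TRUE, dropout = FALSE)
  fr <- occlugen:::discriminator_forward(d, xs, ops, ys)
  ff <- occlugen:::discriminator_forward(d, xs, ops, gf$out, train = TRUE)
  pf <- mean(ff$patch)
  dpatch <- matrix(-1 / (pf * length(ff$patch)),
                   nrow(ff$patch), ncol(ff$patch))
  dacts <- list()
  for (k in seq_along(ff$acts)) {
    nm <- names(ff$acts)[k]
    dacts[[nm]] <- cfg$lambda_pg * cfg$layer_weights[k] *
      sign(ff$acts[[k]] - fr$acts[[k]]) / length(ff$acts[[k]])
  }
  bg <- occlugen:::discriminator_backward(d, dpatch, ff$ctxs, dacts)
  dg_out <- matrix(bg$dinput[3, , ], res) +
    cfg$lambda_l1 * sign(gf$out - ys) / length(gf$out)
  grads <- occlugen:::generator_backward(g, dg_out, gf$ctxs)

  eps <- 1e-5
  set.seed(6)
  checks <- list(
    list(get = function() g$enc[[2]]$conv$W,
         set = function(G, p) { G$enc[[2]]$conv$W[] <- p; G },
         grad = grads$enc[[2]]$conv$W),
    list(get = function() g$dec[[2]]$tconv$W,
         set = function(G, p) { G$dec[[2]]$tconv$W[] <- p; G },
         grad = grads$dec[[2]]$tconv$W),
    list(get = function() g$dec[[1]]$bn$gamma,
         set = function(G, p) { G$dec[[1]]$bn$gamma[] <- p; G },
         grad = grads$dec[[1]]$bn$gamma)
  )
  for (ch in checks) {
    p0 <- ch$get()
    for (ii in sample(length(p0), 3)) {
      pp <- p0; pp[ii] <- pp[ii] + eps
      pm <- p0; pm[ii] <- pm[ii] - eps
      fd <- (loss_of(ch$set(g, pp)) - loss_of(ch$set(g, pm))) / (2 * eps)
      an <- ch$grad[ii]
      expect_lt(abs(fd - an) / max(abs(fd) + abs(an), 1e-8), 5e-3)
    }
  }
})

test_that("discriminator gradients (incl. active hinge) match finite differences", {
  set.seed(7)
  res <- 32
  d <- build_discriminator(discriminator_spec(res, base_width = 2))
  xs <- matrix(stats::runif(res^2, -1, 1), res)
  ops <- matrix(stats::runif(res^2, -1, 1), res)
  ys <- matrix(stats::runif(res^2, -1, 1), res)
  gg <- matrix(stats::runif(res^2, -1, 1), res)
  # a large margin keeps the hinge active so its gradient path is exercised
  cfg <- gan_config(group = 3, base_width = 2, margin = 5)

  loss_of <- function(dt) {
    fr <- occlugen:::discriminator_forward(dt, xs, ops, ys)
    ff <- occlugen:::discriminator_forward(dt, xs, ops, gg)
    adv <- adversarial_terms(fr$patch, ff$patch, cfg$eps)
    pc <- perceptual_deviation(fr$acts, ff$acts, cfg$layer_weights)
    discriminator_loss(cfg, adv, pc$weighted_sum)
  }
  fr <- occlugen:::discriminator_forward(d, xs, ops, ys, train = TRUE)
  ff <- occlugen:::discriminator_forward(d, xs, ops, gg, train = TRUE)
  adv <- adversarial_terms(fr$patch, ff$patch, cfg$eps)
  pc <- perceptual_deviation(fr$acts, ff$acts, cfg$layer_weights)
  expect_lt(pc$weighted_sum, cfg$margin)
  np <- length(fr$patch)
  dpr <- matrix(-1 / (adv$p_real * np), nrow(fr$patch), ncol(fr$patch))
  dpf <- matrix(1 / ((1 - adv$p_fake) * np), nrow(ff$patch), ncol(ff$patch))
  da_r <- list(); da_f <- list()
  for (k in seq_along(fr$acts)) {
    nm <- names(fr$acts)[k]
    sg <- sign(fr$acts[[k]] - ff$acts[[k]]) / length(fr$acts[[k]])
    da_r[[nm]] <- -cfg$lambda_pd * cfg$layer_weights[k] * sg
    da_f[[nm]] <- cfg$lambda_pd * cfg$layer_weights[k] * sg
  }
  br <- occlugen:::discriminator_backward(d, dpr, fr$ctxs, da_r)
  bf <- occlugen:::discriminator_backward(d, dpf, ff$ctxs, da_f)
  gd <- occlugen:::add_grads(br$grads, bf$grads)

  eps <- 1e-5
  set.seed(8)
  for (st in c(2, 5)) {
    W0 <- d$stages[[st]]$conv$W
    for (ii in sample(length(W0), 3)) {
      dp <- d; dp$stages[[st]]$conv$W[ii] <- W0[ii] + eps
      dm <- d; dm$stages[[st]]$conv$W[ii] <- W0[ii] - eps
      fd <- (loss_of(dp) - loss_of(dm)) / (2 * eps)
      an <- gd[[st]]$conv$W[ii]
      expect_lt(abs(fd - an) / max(abs(fd) + abs(an), 1e-8), 5e-3)
    }
  }
})
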