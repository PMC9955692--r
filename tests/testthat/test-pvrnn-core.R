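# Core network computations: deterministic dynamics, prior/posterior heads,
# the Gaussian KL, free energy, the compiled engine against the plain-R
# reference path, and analytic gradients against finite differences.

test_that("deterministic update obeys the leaky-integrator form", {
  specs <- pvrnn_specs(d = c(3L, 2L), z = c(2L, 1L), tau = c(1, 4),
                       wt1 = 1, wt_factor = 1)
  params <- pvrnn_init(specs, seed = 3)
  h_prev <- lapply(specs$d, function(k) runif(k, -1, 1))
  d_prev <- lapply(h_prev, tanh)
  z_now <- lapply(specs$z, function(k) rnorm(k))
  upd <- deterministic_update(h_prev, d_prev, z_now, params, specs)
  # tau = 1: no leak; h equals the drive alone
  ly <- params$layers[[1]]
  drive <- drop(ly$Wdd %*% d_prev[[1]] + ly$Wzd %*% z_now[[1]] +
                  ly$Wdu %*% d_prev[[2]] + ly$bh)
  expect_equal(upd$h[[1]], drive, tolerance = 1e-12)
  expect_equal(upd$d[[1]], tanh(drive), tolerance = 1e-12)
  # tau = 4: convex mixture of old state and drive
  ly2 <- params$layers[[2]]
  drive2 <- drop(ly2$Wdd %*% d_prev[[2]] + ly2$Wzd %*% z_now[[2]] +
                   ly2$Wdl %*% d_prev[[1]] + ly2$bh)
  expect_equal(upd$h[[2]], 0.75 * h_prev[[2]] + 0.25 * drive2,
               tolerance = 1e-12)
  expect_error(
    deterministic_update(h_prev, d_prev, list(rnorm(5), rnorm(1)),
                         params, specs),
    "dimension mismatch")
})

test_that("zero-drive recursion converges to the bias fixed point", {
  specs <- pvrnn_specs(d = 2L, z = 1L, tau = 4, wt1 = 1, wt_factor = 1)
  params <- pvrnn_init(specs, seed = 5)
  params$layers[[1]]$Wdd[] <- 0
  params$layers[[1]]$Wzd[] <- 0
  params$layers[[1]]$bh <- c(0.3, -0.2)
  h <- list(c(1, 1))
  d <- lapply(h, tanh)
  for (i in 1:300) {
    upd <- deterministic_update(h, d, list(0), params, specs)
    # solve the scalar recursion analytically at step 1:
    if (i == 1) {
      expect_equal(upd$h[[1]], 0.75 * c(1, 1) + 0.25 * c(0.3, -0.2),
                   tolerance = 1e-12)
    }
    h <- upd$h
    d <- upd$d
  }
  expect_equal(h[[1]], c(0.3, -0.2), tolerance = 1e-9)
})

test_that("slower layers drift more slowly (timescale hierarchy)", {
  specs <- pvrnn_specs() # reference: tau = (2, 4, 8)
  expect_identical(specs$d, c(40L, 20L, 10L))
  expect_identical(specs$z, c(4L, 2L, 1L))
  expect_equal(specs$tau, c(2, 4, 8))
  expect_equal(specs$wt, c(3.5, 35, 350))
  params <- pvrnn_init(specs, seed = 8)
  set.seed(9)
  h <- lapply(specs$d, function(k) rep(0, k))
  d <- h
  traj <- lapply(1:3, function(l) matrix(0, 200, specs$d[l]))
  for (t in 1:200) {
    z <- lapply(specs$z, function(k) rnorm(k))
    upd <- deterministic_update(h, d, z, params, specs)
    h <- upd$h
    d <- upd$d
    for (l in 1:3) traj[[l]][t, ] <- d[[l]]
  }
  ac1 <- function(m) {
    mean(vapply(seq_len(ncol(m)), function(j) {
      v <- m[, j]
      if (sd(v) < 1e-10) return(1)
      cor(v[-1], v[-length(v)])
    }, numeric(1)))
  }
  acs <- vapply(traj, ac1, numeric(1))
  expect_true(acs[1] < acs[2] && acs[2] < acs[3])
})

test_that("prior head: unit Gaussian at t = 1, conditional afterwards", {
  specs <- tiny_specs()
  params <- pvrnn_init(specs, seed = 2)
  ly <- params$layers[[1]]
  d_prev <- runif(specs$d[1], -1, 1)
  p1 <- compute_prior(d_prev, ly, t = 1)
  expect_equal(p1$mu, rep(0, specs$z[1]))
  expect_equal(p1$sigma, rep(1, specs$z[1]))
  p2 <- compute_prior(d_prev, ly, t = 2)
  expect_equal(p2$mu, drop(tanh(ly$Wmu_q %*% d_prev + ly$bmu_p)))
  expect_true(all(p2$sigma > 0))
  # zero weights and biases give the unit Gaussian at any step
  ly0 <- ly
  ly0$Wmu_q[] <- 0; ly0$Wsig_q[] <- 0
  p0 <- compute_prior(d_prev, ly0, t = 5)
  expect_equal(p0$mu, rep(0, specs$z[1]))
  expect_equal(p0$sigma, rep(1, specs$z[1]))
})

test_that("posterior equals the prior when A = 0 and the heads coincide", {
  specs <- tiny_specs()
  params <- pvrnn_init(specs, seed = 2)
  ly <- params$layers[[2]]
  ly$bmu_q <- ly$bmu_p
  ly$bsig_q <- ly$bsig_p
  d_prev <- runif(specs$d[2], -1, 1)
  a0 <- list(mu = rep(0, specs$z[2]), sigma = rep(0, specs$z[2]))
  q <- compute_posterior(d_prev, a0, ly)
  p <- compute_prior(d_prev, ly, t = 2)
  expect_equal(q$mu, p$mu, tolerance = 1e-12)
  expect_equal(q$sigma, p$sigma, tolerance = 1e-12)
  # sigma stays strictly positive however negative A_sigma becomes
  aneg <- list(mu = rep(0, specs$z[2]), sigma = rep(-40, specs$z[2]))
  expect_true(all(compute_posterior(d_prev, aneg, ly)$sigma > 0))
  expect_error(compute_posterior(d_prev, list(mu = NULL, sigma = NULL), ly),
               "adaptive variables")
})

test_that("latent sampling is reparameterized and unbiased", {
  g <- list(mu = c(0.4, -1.2), sigma = c(1e-12, 1e-12))
  expect_equal(sample_latent(g), g$mu, tolerance = 1e-9)
  set.seed(10)
  g2 <- list(mu = 0.7, sigma = 2)
  draws <- vapply(seq_len(1e4), function(i) sample_latent(g2), numeric(1))
  se <- g2$sigma / sqrt(length(draws))
  expect_lt(abs(mean(draws) - g2$mu), 4 * se)
  set.seed(77)
  a <- sample_latent(list(mu = 0, sigma = 1))
  set.seed(77)
  b <- sample_latent(list(mu = 0, sigma = 1))
  expect_identical(a, b)
})

test_that("Gaussian KL matches the closed form and numerical quadrature", {
  expect_equal(kl_unit(0.3, 0.7, 0.3, 0.7), 0)
  expect_equal(kl_unit(0, 1, 1, 1), 0.5)
  expect_error(kl_unit(0, -1, 0, 1), "positive")
  quad_kl <- function(mp, sp, mq, sq) {
    f <- function(x) {
      dnorm(x, mq, sq) * (dnorm(x, mq, sq, log = TRUE) -
                            dnorm(x, mp, sp, log = TRUE))
    }
    integrate(f, mq - 12 * sq, mq + 12 * sq, rel.tol = 1e-10)$value
  }
  set.seed(21)
  for (i in 1:20) {
    mp <- rnorm(1); mq <- rnorm(1)
    sp <- exp(rnorm(1, 0, 0.5)); sq <- exp(rnorm(1, 0, 0.5))
    d <- kl_unit(mp, sp, mq, sq)
    expect_gte(d, 0)
    expect_equal(d, quad_kl(mp, sp, mq, sq), tolerance = 1e-6)
  }
})

test_that("output map is bounded with the correct channel count", {
  specs <- tiny_specs()
  params <- pvrnn_init(specs, seed = 6)
  d1 <- runif(specs$d[1], -1, 1)
  out <- output_map(d1, params)
  expect_length(out, 10)
  expect_true(all(abs(out) < 1))
  p0 <- params
  p0$Wout[] <- 0
  p0$bout <- seq(-0.9, 0.9, length.out = 10)
  expect_equal(output_map(d1, p0), tanh(p0$bout))
  # Jacobian against finite differences
  jac_fd <- sapply(seq_along(d1), function(j) {
    h <- 1e-6
    dp <- d1; dp[j] <- dp[j] + h
    dm <- d1; dm[j] <- dm[j] - h
    (output_map(dp, params) - output_map(dm, params)) / (2 * h)
  })
  jac_an <- diag(1 - out^2) %*% params$Wout
  expect_equal(jac_fd, jac_an, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("free energy is zero for a perfect, prior-matching window", {
  g <- list(mu = c(0.1, -0.2), sigma = c(0.5, 2))
  states <- replicate(3, list(list(prior = g, posterior = g),
                              list(prior = g, posterior = g)),
                      simplify = FALSE)
  X <- matrix(runif(30), 3, 10)
  expect_equal(as.numeric(free_energy(states, X, X, w = c(1, 1))), 0)
  # with zero complexity weights only the error term remains
  Xh <- X + 0.1
  fe <- free_energy(states, X, Xh, w = c(0, 0))
  expect_equal(as.numeric(fe), 3 * 0.1^2 * 10 / 10, tolerance = 1e-12)
  expect_error(free_energy(states, X, X, w = c(1, 1), mask = rep(0, 10)),
               "mask")
})

test_that("free energy matches hand arithmetic on a two-step toy case", {
  # 1 layer, 1 latent unit, 1 channel
  s1 <- list(list(prior = list(mu = 0, sigma = 1),
                  posterior = list(mu = 0.5, sigma = 0.8)))
  s2 <- list(list(prior = list(mu = -0.2, sigma = 0.6),
                  posterior = list(mu = 0.1, sigma = 0.6)))
  X <- matrix(c(0.3, -0.4), 2, 1)
  Xb <- matrix(c(0.1, -0.1), 2, 1)
  d1 <- log(1 / 0.8) + (0.5^2 + 0.8^2) / 2 - 0.5
  d2 <- log(0.6 / 0.6) + ((0.1 + 0.2)^2 + 0.6^2) / (2 * 0.36) - 0.5
  hand <- 2 * (d1 + d2) + (0.2^2 + 0.3^2) / 1
  fe <- free_energy(list(s1, s2), X, Xb, w = 2)
  expect_equal(as.numeric(fe), hand, tolerance = 1e-10)
})

test_that("compiled engine reproduces the plain-R reference free energy", {
  pb <- tiny_problem()
  res <- pvrnndyad:::cpp_free_energy(
    pb$params, pb$sp, pb$X, pb$Amu, pb$Asig, pb$w, pb$mask,
    unit_start = TRUE, deterministic = FALSE, eps = pb$eps,
    want_param_grads = FALSE, want_A_grads = FALSE)
  Fref <- 0
  for (b in seq_len(pb$B)) {
    take <- function(a, l) matrix(a[[l]][, b, ], nrow = pb$specs$z[l])
    Fref <- Fref + as.numeric(pvrnndyad:::pvrnn_forward_ref(
      pb$params, pb$specs, t(pb$X[, b, ]),
      lapply(seq_len(3), function(l) take(pb$Amu, l)),
      lapply(seq_len(3), function(l) take(pb$Asig, l)),
      lapply(seq_len(3), function(l) take(pb$eps, l)),
      pb$w, pb$mask))
  }
  expect_equal(res$F, Fref, tolerance = 1e-12)
  expect_gte(res$complexity, 0)
  expect_gte(res$error, 0)
})

test_that("engine gradients match central finite differences", {
  pb <- tiny_problem()
  res <- pvrnndyad:::cpp_free_energy(
    pb$params, pb$sp, pb$X, pb$Amu, pb$Asig, pb$w, pb$mask,
    unit_start = TRUE, deterministic = FALSE, eps = pb$eps,
    want_param_grads = TRUE, want_A_grads = TRUE)
  fe <- function(p, am = pb$Amu, as_ = pb$Asig) {
    pvrnndyad:::cpp_free_energy(
      p, pb$sp, pb$X, am, as_, pb$w, pb$mask, TRUE, FALSE, eps = pb$eps,
      want_param_grads = FALSE, want_A_grads = FALSE)$F
  }
  h <- 1e-6
  rel_err <- function(fd, an) abs(fd - an) / max(abs(fd), abs(an), 1e-10)
  fields <- list(c(1, "Wdd"), c(2, "Wdd"), c(1, "Wzd"), c(3, "bh"),
                 c(1, "Wmu_q"), c(2, "Wsig_q"), c(1, "bmu_p"),
                 c(1, "bsig_p"), c(2, "bmu_q"), c(1, "bsig_q"),
                 c(1, "Wdu"), c(2, "Wdl"))
  for (f in fields) {
    l <- as.integer(f[1]); nm <- f[2]
    p2 <- pb$params; p2$layers[[l]][[nm]][1] <- p2$layers[[l]][[nm]][1] + h
    p1 <- pb$params; p1$layers[[l]][[nm]][1] <- p1$layers[[l]][[nm]][1] - h
    fd <- (fe(p2) - fe(p1)) / (2 * h)
    expect_lt(rel_err(fd, res$grads$layers[[l]][[nm]][1]), 1e-4)
  }
  p2 <- pb$params; p2$Wout[2, 3] <- p2$Wout[2, 3] + h
  p1 <- pb$params; p1$Wout[2, 3] <- p1$Wout[2, 3] - h
  expect_lt(rel_err((fe(p2) - fe(p1)) / (2 * h), res$grads$Wout[2, 3]), 1e-4)
  for (l in 1:3) {
    for (tt in c(1L, pb$T_len)) {
      a2 <- pb$Amu; a2[[l]][1, 1, tt] <- a2[[l]][1, 1, tt] + h
      a1 <- pb$Amu; a1[[l]][1, 1, tt] <- a1[[l]][1, 1, tt] - h
      fd <- (fe(pb$params, a2) - fe(pb$params, a1)) / (2 * h)
      expect_lt(rel_err(fd, res$gAmu[[l]][1, 1, tt]), 1e-4)
      s2 <- pb$Asig; s2[[l]][1, 1, tt] <- s2[[l]][1, 1, tt] + h
      s1 <- pb$Asig; s1[[l]][1, 1, tt] <- s1[[l]][1, 1, tt] - h
      fd <- (fe(pb$params, pb$Amu, s2) - fe(pb$params, pb$Amu, s1)) / (2 * h)
      expect_lt(rel_err(fd, res$gAsig[[l]][1, 1, tt]), 1e-4)
    }
  }
})

test_that("prior rollouts are bounded, finite and seed-reproducible", {
  specs <- tiny_specs()
  model <- pvrnn_model(pvrnn_init(specs, seed = 14), specs)
  r1 <- prior_generate(model, 100, seed = 5)
  expect_true(all(is.finite(r1$outputs)))
  expect_true(all(abs(r1$outputs) < 1))
  r2 <- prior_generate(model, 100, seed = 5)
  expect_identical(r1$outputs, r2$outputs)
  r3 <- prior_generate(model, 100, seed = 6)
  expect_false(identical(r1$outputs, r3$outputs))
})
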