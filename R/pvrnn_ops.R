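# Elementary network operations in plain R. These mirror the compiled engine
# one-to-one and double as a slow reference path: tests step tiny networks
# through these functions and compare against the compiled forward pass.

#' One deterministic multiple-timescale update
#'
#' Leaky-integrator update of the deterministic units of every layer:
#' \deqn{h_t = (1 - 1/\tau) h_{t-1} + (1/\tau)(W_{dd} \tilde d_{t-1} +
#'   W_{zd} z_t + \mathrm{cross\ terms} + b_h), \quad \tilde d_t = \tanh h_t}
#' Layer \code{l} receives deterministic context from layers \code{l - 1} and
#' \code{l + 1} only.
#'
#' @param h_prev,d_prev Lists (one element per layer) of numeric vectors.
#' @param z_now List of latent samples per layer.
#' @param params Network parameters (see \code{\link{pvrnn_init}}).
#' @param specs A \code{\link{pvrnn_specs}} object.
#' @return List with elements \code{h} and \code{d}, each a per-layer list.
#' @export
deterministic_update <- function(h_prev, d_prev, z_now, params, specs) {
  L <- length(specs$d)
  stopifnot(length(h_prev) == L, length(z_now) == L)
  h <- vector("list", L)
  d <- vector("list", L)
  for (l in seq_len(L)) {
    ly <- params$layers[[l]]
    if (length(z_now[[l]]) != specs$z[l]) {
      stop("latent dimension mismatch in layer ", l, call. = FALSE)
    }
    u <- ly$Wdd %*% d_prev[[l]] + ly$Wzd %*% z_now[[l]] + ly$bh
    if (l < L) u <- u + ly$Wdu %*% d_prev[[l + 1]]
    if (l > 1) u <- u + ly$Wdl %*% d_prev[[l - 1]]
    a <- 1 / specs$tau[l]
    h[[l]] <- drop((1 - a) * h_prev[[l]] + a * u)
    d[[l]] <- tanh(h[[l]])
  }
  list(h = h, d = d)
}

#' Conditional Gaussian prior of one layer
#'
#' At the first time step the prior is the unit Gaussian; afterwards it is a
#' deterministic map of the previous deterministic state:
#' \eqn{\mu^p = \tanh(W_\mu \tilde d_{t-1} + b_\mu^p)},
#' \eqn{\sigma^p = \exp(W_\sigma \tilde d_{t-1} + b_\sigma^p)}.
#'
#' @param d_prev Deterministic state of the layer at the previous step.
#' @param layer One element of \code{params$layers}.
#' @param t Absolute time step (1-based).
#' @param share_heads Whether prior and posterior share head weights.
#' @return List with \code{mu} and \code{sigma}.
#' @export
compute_prior <- function(d_prev, layer, t, share_heads = TRUE) {
  z_dim <- length(layer$bmu_p)
  if (t == 1L) {
    return(list(mu = rep(0, z_dim), sigma = rep(1, z_dim)))
  }
  Wmu <- if (share_heads) layer$Wmu_q else layer$Wmu_p
  Wsig <- if (share_heads) layer$Wsig_q else layer$Wsig_p
  list(mu = drop(tanh(Wmu %*% d_prev + layer$bmu_p)),
       sigma = drop(exp(Wsig %*% d_prev + layer$bsig_p)))
}

#' Adaptive-variable posterior of one layer
#'
#' \eqn{\mu^q = \tanh(W_\mu \tilde d_{t-1} + A_\mu + b_\mu^q)},
#' \eqn{\sigma^q = \exp(W_\sigma \tilde d_{t-1} + A_\sigma + b_\sigma^q)}.
#'
#' @param d_prev Deterministic state at the previous step.
#' @param a List with \code{mu} and \code{sigma} adaptive variables for this
#'   step; missing entries are an error.
#' @param layer One element of \code{params$layers}.
#' @return List with \code{mu} and \code{sigma}.
#' @export
compute_posterior <- function(d_prev, a, layer) {
  if (is.null(a$mu) || is.null(a$sigma)) {
    stop("adaptive variables undefined for this step", call. = FALSE)
  }
  list(mu = drop(tanh(layer$Wmu_q %*% d_prev + a$mu + layer$bmu_q)),
       sigma = drop(exp(layer$Wsig_q %*% d_prev + a$sigma + layer$bsig_q)))
}

#' Reparameterized Gaussian sample
#'
#' \eqn{z = \mu + \sigma \odot \epsilon}, \eqn{\epsilon \sim N(0, I)}.
#'
#' @param g List with \code{mu} and \code{sigma}.
#' @param eps Optional fixed noise vector (defaults to a fresh draw).
#' @export
sample_latent <- function(g, eps = NULL) {
  stopifnot(all(g$sigma > 0))
  if (is.null(eps)) eps <- stats::rnorm(length(g$mu))
  g$mu + g$sigma * eps
}

#' Elementwise Gaussian Kullback-Leibler divergence
#'
#' The per-dimension divergence between a diagonal-Gaussian posterior
#' \code{(mu_q, sigma_q)} and prior \code{(mu_p, sigma_p)}:
#' \deqn{\delta = \log(\sigma_p/\sigma_q) +
#'   \frac{(\mu_q-\mu_p)^2 + \sigma_q^2}{2\sigma_p^2} - \frac12}
#' Vectorized over dimensions; the caller sums.
#'
#' @param mu_p,sigma_p,mu_q,sigma_q Numeric vectors; sigmas strictly positive.
#' @return Nonnegative numeric vector of per-dimension divergences.
#' @export
kl_unit <- function(mu_p, sigma_p, mu_q, sigma_q) {
  if (any(sigma_p <= 0) || any(sigma_q <= 0)) {
    stop("standard deviations must be strictly positive", call. = FALSE)
  }
  log(sigma_p / sigma_q) +
    ((mu_q - mu_p)^2 + sigma_q^2) / (2 * sigma_p^2) - 0.5
}

#' Output map from the first-layer deterministic state
#'
#' \eqn{\bar X = \tanh(W_{out} \tilde d^1 + b_{out})}: 10 channels, the first
#' six proprioceptive joint angles and the last four normalized hand
#' coordinates (rescale by the fixed kinematic constant to obtain physical
#' exteroception).
#'
#' @param d1 First-layer deterministic state.
#' @param params Network parameters.
#' @export
output_map <- function(d1, params) {
  drop(tanh(params$Wout %*% d1 + params$bout))
}

#' Normalized variational free energy of a window
#'
#' \deqn{F = \sum_t \sum_l w_l\, \overline{\delta}(l, t) + \frac{1}{R_X}
#'   \sum_t \lVert m \odot (X_t - \bar X_t) \rVert^2}
#' where \eqn{\overline{\delta}} is the per-dimension mean Gaussian KL of
#' layer \code{l} at step \code{t} and \eqn{R_X} the number of channels
#' selected by the mask \code{m}.
#'
#' @param states List over time steps; each element a list over layers with
#'   components \code{prior} and \code{posterior}, both \code{list(mu,
#'   sigma)}.
#' @param targets T x R matrix of observed channels.
#' @param predictions T x R matrix of network outputs.
#' @param w Per-layer complexity weights (recycled over time) or an L x T
#'   matrix.
#' @param mask Logical or 0/1 vector over the R channels; at least one channel
#'   must be selected.
#' @return Scalar free energy with attributes \code{complexity} and
#'   \code{error}.
#' @export
free_energy <- function(states, targets, predictions, w, mask = NULL) {
  targets <- as.matrix(targets)
  predictions <- as.matrix(predictions)
  T_len <- length(states)
  stopifnot(T_len >= 1, nrow(targets) == T_len,
            all(dim(targets) == dim(predictions)))
  if (is.null(mask)) mask <- rep(1, ncol(targets))
  mask <- as.numeric(as.logical(mask))
  RX <- sum(mask)
  if (RX == 0) stop("mask selects no channels", call. = FALSE)
  L <- length(states[[1]])
  if (is.matrix(w)) stopifnot(nrow(w) == L, ncol(w) == T_len)
  else w <- matrix(w, nrow = L, ncol = T_len)
  comp <- 0
  for (t in seq_len(T_len)) {
    for (l in seq_len(L)) {
      s <- states[[t]][[l]]
      d <- kl_unit(s$prior$mu, s$prior$sigma, s$posterior$mu,
                   s$posterior$sigma)
      comp <- comp + w[l, t] * mean(d)
    }
  }
  err <- sum(sweep((targets - predictions)^2, 2, mask, `*`)) / RX
  structure(comp + err, complexity = comp, error = err)
}

# Slow reference forward pass over one sequence; used in tests as the
# independent oracle for the compiled engine. A, eps: lists per layer of
# z x T matrices. Returns F with complexity/error attributes and the
# prediction matrix.
pvrnn_forward_ref <- function(params, specs, X, A_mu, A_sig, eps, w,
                              mask = rep(1, ncol(X)), unit_start = TRUE,
                              h0 = NULL, d0 = NULL) {
  L <- length(specs$d)
  T_len <- nrow(X)
  if (is.null(h0)) h0 <- lapply(specs$d, function(k) rep(0, k))
  if (is.null(d0)) d0 <- lapply(specs$d, function(k) rep(0, k))
  h <- h0
  d <- d0
  states <- vector("list", T_len)
  xbar <- matrix(0, T_len, ncol(X))
  share <- isTRUE(params$share_heads)
  for (t in seq_len(T_len)) {
    st_l <- vector("list", L)
    z <- vector("list", L)
    for (l in seq_len(L)) {
      ly <- params$layers[[l]]
      prior <- if (t == 1 && unit_start) {
        list(mu = rep(0, specs$z[l]), sigma = rep(1, specs$z[l]))
      } else {
        compute_prior(d[[l]], ly, t = 2L, share_heads = share)
      }
      post <- compute_posterior(
        d[[l]], list(mu = A_mu[[l]][, t], sigma = A_sig[[l]][, t]), ly)
      z[[l]] <- sample_latent(post, eps = eps[[l]][, t])
      st_l[[l]] <- list(prior = prior, posterior = post)
    }
    upd <- deterministic_update(h, d, z, params, specs)
    h <- upd$h
    d <- upd$d
    states[[t]] <- st_l
    xbar[t, ] <- output_map(d[[1]], params)
  }
  fe <- free_energy(states, X, xbar, w, mask)
  attr(fe, "xbar") <- xbar
  fe
}
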