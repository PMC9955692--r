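# Sliding-window error regression: at each interaction step the adaptive
# posterior variables inside a past window are re-optimized against the
# observed exteroception while the network weights stay frozen.

#' Online inference configuration
#'
#' @param window_len Regression window length in steps (default 70).
#' @param iterations Gradient iterations per interaction step (default 50).
#' @param inner_lr Adam learning rate for the adaptive variables.
#' @param error_channels Which output channels carry prediction error:
#'   \code{"extero"} (dyadic interaction) or \code{"all"}.
#' @param resample_noise Re-sample the reparameterization noise at every
#'   iteration (stochastic variational inference); turn off for exact
#'   regression tests.
#' @param deterministic Propagate posterior means without sampling.
#' @param init_A New-step initialization: \code{"zero"} or \code{"copy"}
#'   (copy the previous step's adaptive variables).
#' @export
inference_config <- function(window_len = 70L, iterations = 50L,
                             inner_lr = 0.001,
                             error_channels = c("extero", "all"),
                             resample_noise = TRUE, deterministic = FALSE,
                             init_A = c("zero", "copy")) {
  stopifnot(window_len >= 1, iterations >= 0, inner_lr > 0)
  structure(list(window_len = as.integer(window_len),
                 iterations = as.integer(iterations), inner_lr = inner_lr,
                 error_channels = match.arg(error_channels),
                 resample_noise = resample_noise,
                 deterministic = deterministic,
                 init_A = match.arg(init_A)),
            class = "inference_config")
}

channel_mask <- function(error_channels) {
  if (error_channels == "extero") c(rep(0, 6), rep(1, 4)) else rep(1, 10)
}

#' Meta-prior schedule for the interaction phase
#'
#' Either a constant layer-1 meta-prior or a slow sinusoid between
#' \code{lower} and \code{upper} with the given period, starting after an
#' onset plateau at \code{onset_value} (midline by default). Per-layer
#' scaling (x10, x100 above layer 1) is applied by the inference engine, so
#' schedules are specified by their layer-1 value only.
#'
#' @param kind \code{"constant"} or \code{"sinusoid"}.
#' @param value Constant layer-1 meta-prior.
#' @param lower,upper Sinusoid extremes (layer-1 values).
#' @param period Oscillation period in steps (>= 2).
#' @param phase Phase offset in radians; an anti-phase pair differs by pi.
#' @param onset_len Plateau length before the oscillation starts.
#' @param onset_value Plateau value (defaults to the midline).
#' @export
meta_prior_schedule <- function(kind = c("constant", "sinusoid"),
                                value = NULL, lower = NULL, upper = NULL,
                                period = NULL, phase = 0, onset_len = 0L,
                                onset_value = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    stopifnot(is.numeric(value), value >= 0)
    return(structure(list(kind = kind, value = value),
                     class = "meta_prior_schedule"))
  }
  stopifnot(is.numeric(lower), is.numeric(upper), lower >= 0, upper > lower,
            period >= 2)
  if (is.null(onset_value)) onset_value <- (lower + upper) / 2
  structure(list(kind = kind, lower = lower, upper = upper, period = period,
                 phase = phase, onset_len = as.integer(onset_len),
                 onset_value = onset_value),
            class = "meta_prior_schedule")
}

#' Evaluate a meta-prior schedule at a time step
#'
#' @param s A \code{\link{meta_prior_schedule}}.
#' @param t Time step (>= 1).
#' @return The layer-1 meta-prior at step \code{t}.
#' @export
eval_schedule <- function(s, t) {
  stopifnot(inherits(s, "meta_prior_schedule"), all(t >= 1))
  if (s$kind == "constant") return(rep(s$value, length(t)))
  mid <- (s$lower + s$upper) / 2
  amp <- (s$upper - s$lower) / 2
  out <- mid + amp * sin(2 * pi * (t - s$onset_len) / s$period + s$phase)
  out[t <= s$onset_len] <- s$onset_value
  out
}

#' Create an empty posterior window
#'
#' The window grows one step at a time from the start of an interaction
#' until it reaches \code{window_len}, then slides. It carries the adaptive
#' variables of every step inside the window, the frozen network state just
#' before the window, and a permanent record of evicted posteriors.
#'
#' @param model A \code{pvrnn_model}.
#' @param config An \code{\link{inference_config}}.
#' @return An environment of class \code{posterior_window}.
#' @export
new_posterior_window <- function(model, config = inference_config()) {
  w <- new.env(parent = emptyenv())
  specs <- model$specs
  w$model <- model
  w$config <- config
  w$start_t <- 1L
  w$len <- 0L
  w$Amu <- lapply(specs$z, function(zl) array(0, dim = c(zl, 1L, 0L)))
  w$Asig <- lapply(specs$z, function(zl) array(0, dim = c(zl, 1L, 0L)))
  w$obs <- matrix(0, nrow = 0L, ncol = 10L)
  w$h0 <- lapply(specs$d, function(k) matrix(0, k, 1L))
  w$d0 <- lapply(specs$d, function(k) matrix(0, k, 1L))
  w$states_first <- NULL   # h/d after the first window step (for eviction)
  w$record <- list()       # frozen posteriors of evicted steps
  class(w) <- c("posterior_window", "environment")
  w
}

append_step_arrays <- function(A, init_cols) {
  lapply(seq_along(A), function(l) {
    a <- A[[l]]
    zl <- dim(a)[1]
    new <- array(0, dim = c(zl, 1L, dim(a)[3] + 1L))
    if (dim(a)[3] > 0) new[, , seq_len(dim(a)[3])] <- a
    new[, , dim(new)[3]] <- init_cols[[l]]
    new
  })
}

#' Slide the window by one observation
#'
#' Appends step \code{t + 1} with freshly initialized adaptive variables
#' (older entries retained as a warm start) and evicts the oldest step when
#' the window exceeds its capacity; the evicted step's posterior is frozen
#' into the permanent record and the pre-window network state advances.
#'
#' @param window A \code{posterior_window}.
#' @param new_observation Length-10 channel vector (proprio channels are
#'   ignored when the error mask is extero-only).
#' @return The window, invisibly (modified in place).
#' @export
slide_window <- function(window, new_observation) {
  stopifnot(length(new_observation) == 10L)
  cfg <- window$config
  specs <- window$model$specs
  if (window$len == cfg$window_len) {
    # evict the oldest step: freeze its posterior, advance the initial state
    if (!is.null(window$states_first)) {
      window$h0 <- window$states_first$h
      window$d0 <- window$states_first$d
    }
    if (!is.null(window$last_info)) {
      window$record[[length(window$record) + 1L]] <- list(
        t = window$start_t,
        mu = window$last_info$muq_first,
        sigma = window$last_info$sigq_first)
    }
    window$Amu <- lapply(window$Amu, function(a) {
      a[, , -1L, drop = FALSE]
    })
    window$Asig <- lapply(window$Asig, function(a) {
      a[, , -1L, drop = FALSE]
    })
    window$obs <- window$obs[-1L, , drop = FALSE]
    window$start_t <- window$start_t + 1L
    window$len <- window$len - 1L
  }
  init_mu <- init_sig <- lapply(specs$z, function(zl) rep(0, zl))
  if (cfg$init_A == "copy" && window$len > 0) {
    init_mu <- lapply(window$Amu, function(a) a[, 1, dim(a)[3]])
    init_sig <- lapply(window$Asig, function(a) a[, 1, dim(a)[3]])
  }
  window$Amu <- append_step_arrays(window$Amu, init_mu)
  window$Asig <- append_step_arrays(window$Asig, init_sig)
  window$obs <- rbind(window$obs, matrix(new_observation, 1L))
  window$len <- window$len + 1L
  invisible(window)
}

#' One step of sliding-window error regression
#'
#' Runs \code{iterations} Adam steps on the adaptive posterior variables of
#' the current window (network weights frozen), with prediction error on the
#' configured channels and the complexity term weighted by the current
#' layer-1 meta-prior scaled x10/x100 in layers 2/3.
#'
#' @param window A \code{posterior_window} holding at least one observation.
#' @param wi1 Layer-1 interaction meta-prior for this step.
#' @param predict_deterministic Use the prior mean (not a sample) for the
#'   one-step-ahead prediction.
#' @return Invisibly, a list with the free-energy trace over iterations
#'   (\code{ftrace}), final \code{F}, per-layer KL at the newest step,
#'   layer-wise posterior/prior means, and the one-step-ahead prediction
#'   \code{pred_next}; also stored in \code{window$last_info}.
#' @export
infer_step <- function(window, wi1, predict_deterministic = FALSE) {
  stopifnot(window$len >= 1)
  cfg <- window$config
  model <- window$model
  L <- length(model$specs$d)
  w_layers <- wi1 * 10^(seq_len(L) - 1)
  res <- cpp_infer_window(
    model$params, specs_for_cpp(model$specs), window$obs,
    window$Amu, window$Asig, w_layers, channel_mask(cfg$error_channels),
    cfg$iterations, cfg$inner_lr,
    unit_start = (window$start_t == 1L),
    resample_noise = cfg$resample_noise,
    deterministic = cfg$deterministic,
    h0 = window$h0, d0 = window$d0,
    predict_deterministic = predict_deterministic || cfg$deterministic)
  window$Amu <- res$Amu
  window$Asig <- res$Asig
  window$states_first <- list(h = res$h_first, d = res$d_first)
  if (!is.finite(res$F)) {
    stop(sprintf(
      "online inference diverged (window start %d, length %d): F = %s",
      window$start_t, window$len, format(res$F)), call. = FALSE)
  }
  info <- list(ftrace = res$ftrace, F = res$F, complexity = res$complexity,
               error = res$error, kl_last = drop(res$kl_last),
               kl_window = drop(res$kl_window),
               muq_last = res$muq_last, mup_last = res$mup_last,
               muq_first = res$muq_first, sigq_first = res$sigq_first,
               pred_next = drop(res$pred_next), xbar = res$xbar,
               wi1 = wi1)
  window$last_info <- info
  invisible(info)
}

#' One-step-ahead generation from the current window
#'
#' Re-runs the generative pass over the inferred window and takes one
#' further step with the latent state drawn from the conditional prior; the
#' proprioceptive channels of the result are the action to execute, the
#' exteroceptive channels the prediction of the partner's hands.
#'
#' @param window An inferred \code{posterior_window}.
#' @param deterministic Propagate means instead of sampling.
#' @return List with \code{proprio} (6), \code{extero_pred} (4, normalized
#'   channels) and the raw 10-channel output.
#' @export
predict_next <- function(window, deterministic = FALSE) {
  cfg <- window$config
  model <- window$model
  L <- length(model$specs$d)
  wi1 <- if (!is.null(window$last_info)) window$last_info$wi1 else 1
  res <- cpp_infer_window(
    model$params, specs_for_cpp(model$specs), window$obs,
    window$Amu, window$Asig, wi1 * 10^(seq_len(L) - 1),
    channel_mask(cfg$error_channels), 0L, cfg$inner_lr,
    unit_start = (window$start_t == 1L),
    resample_noise = cfg$resample_noise,
    deterministic = deterministic || cfg$deterministic,
    h0 = window$h0, d0 = window$d0,
    predict_deterministic = deterministic || cfg$deterministic)
  out <- drop(res$pred_next)
  list(proprio = out[1:6], extero_pred = out[7:10], output = out)
}
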