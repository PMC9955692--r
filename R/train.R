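# Batch training by backpropagation through time, prior-generation
# evaluation, and network selection.

# ---- structure-walking helpers (parameters are nested lists of arrays) ----

# apply f elementwise across parallel nested lists, iterating the structure
# of the first argument (names preferred over positions when present)
zip_map <- function(f, ...) {
  xs <- list(...)
  x1 <- xs[[1]]
  if (is.list(x1)) {
    keys <- if (!is.null(names(x1))) names(x1) else seq_along(x1)
    out <- x1
    for (k in keys) {
      out[[k]] <- do.call(zip_map, c(list(f), lapply(xs, `[[`, k)))
    }
    out
  } else {
    do.call(f, xs)
  }
}

leaf_sum <- function(x, f = identity) {
  if (is.list(x)) sum(vapply(x, leaf_sum, numeric(1), f = f)) else sum(f(x))
}

zero_like <- function(x) zip_map(function(a) a * 0, x)

# one Adam step over a nested-list parameter structure; `state` carries
# (m, v, t) shaped like `grads`
adam_step <- function(theta, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- zip_map(function(m, g) beta1 * m + (1 - beta1) * g,
                     state$m, grads)
  state$v <- zip_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                     state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  theta <- zip_map(function(th, m, v) {
    th - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, theta, state$m, state$v)
  list(theta = theta, state = state)
}

#' Training configuration
#'
#' Desk-scale defaults keep a full training run in the order of a minute;
#' the full-scale protocol (70,000 epochs over 20 sequences of 400 steps
#' with the reference network size) sits behind \code{full_scale = TRUE}.
#'
#' @param epochs Training epochs; default 2,000 (70,000 when
#'   \code{full_scale}).
#' @param lr Adam learning rate.
#' @param w_t1 Complexity weight applied at the first time step of every
#'   sequence in all layers (keeps initial-step sensitivity).
#' @param clip Global gradient-norm clip; 0 (the default) disables it. Adam
#'   already rescales per coordinate, and norm clipping was found to slow
#'   optimization considerably; the option remains as a guard against
#'   divergence.
#' @param seed Integer seed.
#' @param full_scale Use the full-scale epoch count.
#' @export
training_config <- function(epochs = NULL, lr = 0.001, w_t1 = 1.0,
                            clip = 0, seed = NULL, full_scale = FALSE) {
  if (is.null(epochs)) epochs <- if (full_scale) 70000L else 2000L
  stopifnot(epochs >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs), lr = lr, w_t1 = w_t1,
                 clip = clip, seed = seed, full_scale = full_scale),
            class = "training_config")
}

#' Train a network on a set of trajectories
#'
#' Jointly optimizes the generative/inference parameters and the
#' per-sequence adaptive posterior variables by Adam on the normalized free
#' energy, with the squared error taken over all 10 output channels. The
#' per-layer complexity weights come from the specs (\code{wt}); the first
#' time step of every sequence is weighted by \code{w_t1} in all layers.
#'
#' @param dataset List of \code{trajectory} objects of equal length.
#' @param specs A \code{\link{pvrnn_specs}}.
#' @param config A \code{\link{training_config}}.
#' @param share_heads Share prior/posterior head weights.
#' @param verbose Print the loss every 100 epochs.
#' @return A \code{\link{pvrnn_model}} with loss history and per-sequence
#'   adaptive variables.
#' @export
train_pvrnn <- function(dataset, specs, config = training_config(),
                        share_heads = TRUE, verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  T_len <- nrow(dataset[[1]]$proprio)
  if (!all(vapply(dataset, function(tr) nrow(tr$proprio), 1L) == T_len)) {
    stop("all trajectories must have equal length", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  B <- length(dataset)
  L <- length(specs$d)
  X <- array(0, dim = c(10L, B, T_len))
  for (b in seq_len(B)) {
    X[, b, ] <- t(trajectory_to_targets(dataset[[b]]))
  }
  params <- pvrnn_init(specs, share_heads = share_heads)
  Amu <- lapply(specs$z, function(zl) array(0, dim = c(zl, B, T_len)))
  Asig <- lapply(specs$z, function(zl) array(0, dim = c(zl, B, T_len)))
  w <- build_w_matrix(specs, T_len, config$w_t1)
  mask <- rep(1, 10)
  sp <- specs_for_cpp(specs)

  opt_p <- NULL
  opt_a <- NULL
  loss <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    res <- cpp_free_energy(params, sp, X, Amu, Asig, w, mask,
                           unit_start = TRUE, deterministic = FALSE,
                           want_param_grads = TRUE, want_A_grads = TRUE,
                           want_states = FALSE)
    if (!is.finite(res$F)) {
      stop(sprintf(
        "training diverged at epoch %d (F = %s); last finite F = %s",
        epoch, format(res$F),
        if (epoch > 1) format(loss[epoch - 1]) else "none"), call. = FALSE)
    }
    loss[epoch] <- res$F
    g <- res$grads
    gA <- list(mu = res$gAmu, sig = res$gAsig)
    if (config$clip > 0) {
      gnorm <- sqrt(leaf_sum(g, function(x) x^2) +
                      leaf_sum(gA, function(x) x^2))
      if (gnorm > config$clip) {
        sc <- config$clip / gnorm
        g <- zip_map(function(x) x * sc, g)
        gA <- zip_map(function(x) x * sc, gA)
      }
    }
    if (is.null(opt_p)) {
      opt_p <- list(m = zero_like(g), v = zero_like(g), t = 0L)
      opt_a <- list(m = zero_like(gA), v = zero_like(gA), t = 0L)
    }
    # parameters: update only fields present in the gradient structure
    theta <- list(layers = lapply(seq_len(L), function(l) {
      params$layers[[l]][names(g$layers[[l]])]
    }), Wout = params$Wout, bout = params$bout)
    stepped <- adam_step(theta, g, opt_p, config$lr)
    opt_p <- stepped$state
    for (l in seq_len(L)) {
      params$layers[[l]][names(g$layers[[l]])] <- stepped$theta$layers[[l]]
    }
    params$Wout <- stepped$theta$Wout
    params$bout <- stepped$theta$bout
    a_stepped <- adam_step(list(mu = Amu, sig = Asig), gA, opt_a, config$lr)
    opt_a <- a_stepped$state
    Amu <- a_stepped$theta$mu
    Asig <- a_stepped$theta$sig
    if (verbose && epoch %% 100 == 0) {
      message(sprintf("epoch %6d  F = %.5f (complexity %.5f, error %.5f)",
                      epoch, res$F, res$complexity, res$error))
    }
  }
  pvrnn_model(params, specs, config = config,
              A_train = list(mu = Amu, sig = Asig), loss_history = loss)
}

#' Evaluate the movement preference expressed in prior generation
#'
#' Generates \code{n_rollouts} closed-loop rollouts from the prior,
#' classifies each into primitive labels and returns the mean percentage of
#' A/B/C labels. \code{model} may also be a function \code{(T_steps, seed)}
#' returning a T x 6 proprioception matrix (useful for stub oracles).
#'
#' @param model A \code{pvrnn_model} or a generator function.
#' @param classifier A fitted \code{\link{fit_readout}} classifier.
#' @param n_rollouts Number of rollouts (default 10).
#' @param T_steps Rollout length (default 1000).
#' @param seed Optional integer seed.
#' @return Named percentage vector over \code{A}, \code{B}, \code{C}
#'   (sums to 100).
#' @export
evaluate_preference <- function(model, classifier, n_rollouts = 10L,
                                T_steps = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- vapply(seq_len(n_rollouts), function(i) {
    proprio <- if (is.function(model)) {
      model(T_steps, NULL)
    } else {
      prior_generate(model, T_steps)$proprio
    }
    labels <- label_sequence(classifier, proprio)
    movement_frequency(labels)
  }, numeric(3))
  100 * rowMeans(freqs)
}

#' Rank candidate networks by how well they express a target preference
#'
#' Candidates are ranked by the L1 distance between their evaluated
#' percentage vector and \code{target} (for instance \code{c(50, 10, 40)});
#' ties break toward lower final training free energy.
#'
#' @param candidates List of \code{pvrnn_model} objects.
#' @param evals Matrix (candidates x 3) of evaluated percentages, e.g. rows
#'   of \code{\link{evaluate_preference}} output.
#' @param target Target percentage vector of length 3.
#' @param k Number of networks to keep (default 5).
#' @return List with \code{order} (indices, best first, length
#'   \code{min(k, n)}), \code{distance}, and \code{ranked} (the selected
#'   candidates).
#' @export
select_best_networks <- function(candidates, evals, target, k = 5L) {
  stopifnot(length(candidates) >= 1)
  evals <- matrix(evals, ncol = 3)
  stopifnot(nrow(evals) == length(candidates))
  dist <- rowSums(abs(sweep(evals, 2, target)))
  final_loss <- vapply(candidates, function(m) {
    if (!is.null(m$loss_history)) utils::tail(m$loss_history, 1) else Inf
  }, numeric(1))
  ord <- order(dist, final_loss)
  if (k > length(candidates)) {
    warning("k exceeds the number of candidates; returning all")
    k <- length(candidates)
  }
  keep <- ord[seq_len(k)]
  list(order = keep, distance = dist[keep],
       ranked = candidates[keep])
}
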