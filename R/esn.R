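# Echo state network classifier converting a joint-angle trajectory into a
# per-step sequence of primitive labels. The reservoir is a fixed sparse
# leaky-integrator recurrence; the readout is ridge regression onto one-hot
# labels with an argmax decision, evaluated on a sliding window.

#' Echo state network configuration
#'
#' @param reservoir_size Reservoir units (default 25).
#' @param connectivity Fraction of nonzero recurrent weights (default 0.25).
#' @param leakage Leaky-integrator rate in (0, 1] (default 0.60).
#' @param window Sliding-window length in steps (default 12).
#' @param spectral_radius Spectral radius of the scaled recurrent matrix.
#' @param ridge_lambda Ridge penalty of the readout.
#' @param n_inputs Input channels (6 joint angles).
#' @param seed Seed fixing the random reservoir.
#' @export
esn_config <- function(reservoir_size = 25L, connectivity = 0.25,
                       leakage = 0.60, window = 12L, spectral_radius = 0.9,
                       ridge_lambda = 1e-2, n_inputs = 6L, seed = 1L) {
  stopifnot(connectivity > 0, connectivity <= 1, leakage > 0, leakage <= 1,
            window >= 1, reservoir_size >= 1, spectral_radius > 0)
  structure(list(reservoir_size = as.integer(reservoir_size),
                 connectivity = connectivity, leakage = leakage,
                 window = as.integer(window),
                 spectral_radius = spectral_radius,
                 ridge_lambda = ridge_lambda, n_inputs = as.integer(n_inputs),
                 seed = as.integer(seed)),
            class = "esn_config")
}

#' Build the fixed random reservoir
#'
#' Recurrent weights are uniform in (-1, 1), kept with probability
#' \code{connectivity} and rescaled so the spectral radius equals the
#' configured value; the input map is dense uniform in (-1, 1).
#'
#' @param cfg An \code{\link{esn_config}}.
#' @return Object of class \code{esn_reservoir}.
#' @export
build_reservoir <- function(cfg) {
  set.seed(cfg$seed)
  N <- cfg$reservoir_size
  W <- matrix(stats::runif(N * N, -1, 1), N, N)
  keep <- matrix(stats::runif(N * N) < cfg$connectivity, N, N)
  W[!keep] <- 0
  rho <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rho > 0) W <- W * (cfg$spectral_radius / rho)
  Win <- matrix(stats::runif(N * cfg$n_inputs, -1, 1), N, cfg$n_inputs)
  structure(list(cfg = cfg, W = W, Win = Win), class = "esn_reservoir")
}

# leaky-integrator state sequence for a T x n_inputs series: returns T x N
esn_states <- function(reservoir, u) {
  u <- as.matrix(u)
  N <- reservoir$cfg$reservoir_size
  a <- reservoir$cfg$leakage
  T_len <- nrow(u)
  states <- matrix(0, T_len, N)
  x <- rep(0, N)
  tWin <- t(reservoir$Win)
  tW <- t(reservoir$W)
  for (t in seq_len(T_len)) {
    x <- (1 - a) * x + a * tanh(drop(u[t, ] %*% tWin + x %*% tW))
    states[t, ] <- x
  }
  states
}

# features of window starting at i: reservoir state at the window end plus
# the current input
esn_features <- function(reservoir, proprio) {
  win <- reservoir$cfg$window
  T_len <- nrow(proprio)
  n_lab <- max(T_len - win, 0L)
  if (n_lab == 0L) {
    return(matrix(0, 0, reservoir$cfg$reservoir_size +
                    reservoir$cfg$n_inputs + 1L))
  }
  states <- esn_states(reservoir, proprio)
  idx_end <- seq_len(n_lab) + win - 1L
  cbind(1, states[idx_end, , drop = FALSE], proprio[idx_end, , drop = FALSE])
}

#' Fit the ridge readout on labeled trajectories
#'
#' Collects reservoir states at the end of every sliding window of every
#' trajectory and fits a ridge regression onto one-hot primitive labels
#' (argmax decision). The ground-truth label of a window is the majority
#' per-step label inside it.
#'
#' @param reservoir An \code{\link{build_reservoir}} reservoir.
#' @param trajectories List of labeled \code{trajectory} objects covering
#'   all three primitives.
#' @return Object of class \code{esn_classifier}.
#' @export
fit_readout <- function(reservoir, trajectories) {
  win <- reservoir$cfg$window
  feats <- list()
  labs <- character(0)
  for (tr in trajectories) {
    if (is.null(tr$labels)) stop("trajectories must carry labels",
                                 call. = FALSE)
    f <- esn_features(reservoir, tr$proprio)
    if (nrow(f) == 0L) next
    wl <- vapply(seq_len(nrow(f)), function(i) {
      seg <- tr$labels[i:(i + win - 1L)]
      names(sort(table(seg), decreasing = TRUE))[1]
    }, character(1))
    feats[[length(feats) + 1L]] <- f
    labs <- c(labs, wl)
  }
  if (!all(PRIMITIVE_LABELS %in% labs)) {
    stop("training data must contain all three primitive classes",
         call. = FALSE)
  }
  Phi <- do.call(rbind, feats)
  Y <- stats::model.matrix(~ 0 + factor(labs, levels = PRIMITIVE_LABELS))
  lambda <- reservoir$cfg$ridge_lambda
  beta <- solve(crossprod(Phi) + lambda * diag(ncol(Phi)),
                crossprod(Phi, Y))
  cls <- structure(list(reservoir = reservoir, beta = beta),
                   class = "esn_classifier")
  pred <- label_sequence_features(cls, Phi)
  attr(cls, "train_accuracy") <- mean(pred == labs)
  cls
}

label_sequence_features <- function(classifier, Phi) {
  scores <- Phi %*% classifier$beta
  PRIMITIVE_LABELS[max.col(scores, ties.method = "first")]
}

#' Label a trajectory with sliding-window primitive classes
#'
#' One label per window with stride 1; label \code{i} covers the window
#' starting at step \code{i}. Following the reference counting convention a
#' length-T input yields \code{T - window} labels (the final full window is
#' discarded), so 1000 steps give 988 labels for the default window of 12.
#'
#' @param classifier An \code{\link{fit_readout}} classifier.
#' @param proprio T x 6 joint-angle matrix.
#' @return Character vector of labels, length \code{max(T - window, 0)}.
#' @export
label_sequence <- function(classifier, proprio) {
  proprio <- as.matrix(proprio)
  win <- classifier$reservoir$cfg$window
  if (nrow(proprio) <= win) {
    warning("trajectory no longer than the window; returning no labels")
    return(character(0))
  }
  Phi <- esn_features(classifier$reservoir, proprio)
  label_sequence_features(classifier, Phi)
}

#' Fit the standard primitive classifier on synthetic rendered primitives
#'
#' Convenience wrapper: builds the default reservoir and fits the readout on
#' fresh trajectories sampled from both agents' preference machines.
#'
#' @param cfg An \code{\link{esn_config}}.
#' @param waveforms Waveform library used to render the training sequences.
#' @param n_per_robot Training sequences rendered per preference machine.
#' @param T_steps Steps per training sequence.
#' @param seed Seed for the training sequences.
#' @export
standard_classifier <- function(cfg = esn_config(),
                                waveforms = primitive_waveforms(),
                                n_per_robot = 6L, T_steps = 400L,
                                seed = 42L) {
  reservoir <- build_reservoir(cfg)
  set.seed(seed)
  trajs <- c(
    generate_training_set(robot_fsm(1), n_per_robot, T_steps, waveforms),
    generate_training_set(robot_fsm(2), n_per_robot, T_steps, waveforms)
  )
  fit_readout(reservoir, trajs)
}
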