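# Network construction: layer specifications, parameter initialization, the
# model container, and closed-loop generation from the learned prior.

#' Layer specifications of a hierarchical variational recurrent network
#'
#' Defaults follow the reference three-layer configuration: deterministic
#' units d = (40, 20, 10), latent units z = (4, 2, 1), time constants
#' tau = (2, 4, 8), and a training complexity weight of 3.5 in the first
#' layer increasing by a factor of 10 per layer. Layer 1 is closest to the
#' output.
#'
#' @param d Integer vector of deterministic unit counts per layer.
#' @param z Integer vector of latent dimensions per layer.
#' @param tau Time constants (steps, >= 1) per layer.
#' @param wt1 Training meta-prior of layer 1.
#' @param wt_factor Per-layer multiplier of the training meta-prior.
#' @return Object of class \code{pvrnn_specs}.
#' @export
pvrnn_specs <- function(d = c(40L, 20L, 10L), z = c(4L, 2L, 1L),
                        tau = c(2, 4, 8), wt1 = 3.5, wt_factor = 10) {
  L <- length(d)
  stopifnot(L >= 1, length(z) == L, length(tau) == L,
            all(d >= 1), all(z >= 1), all(tau >= 1), wt1 >= 0)
  structure(list(d = as.integer(d), z = as.integer(z), tau = as.numeric(tau),
                 wt = wt1 * wt_factor^(seq_len(L) - 1)),
            class = "pvrnn_specs")
}

#' @export
print.pvrnn_specs <- function(x, ...) {
  cat("<pvrnn_specs>\n")
  print(data.frame(layer = seq_along(x$d), d = x$d, z = x$z, tau = x$tau,
                   wt = x$wt))
  invisible(x)
}

runif_mat <- function(nr, nc, scale) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

#' Initialize network parameters
#'
#' Weights are drawn uniformly in \code{(-1/sqrt(fan_in), 1/sqrt(fan_in))};
#' biases start at zero (so all initial sigmas are 1). By default the prior
#' and posterior heads share their weight matrices and differ only in biases
#' and the per-step adaptive variables.
#'
#' @param specs A \code{\link{pvrnn_specs}}.
#' @param n_out Output channels (6 proprio + 4 extero).
#' @param share_heads Share prior/posterior head weights.
#' @param seed Optional integer seed.
#' @return Parameter list (class \code{pvrnn_params}).
#' @export
pvrnn_init <- function(specs, n_out = 10L, share_heads = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(specs$d)
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    dl <- specs$d[l]
    zl <- specs$z[l]
    fan <- dl + zl + (if (l < L) specs$d[l + 1] else 0L) +
      (if (l > 1) specs$d[l - 1] else 0L)
    s <- 1 / sqrt(fan)
    sh <- 1 / sqrt(dl)
    ly <- list(
      Wdd = runif_mat(dl, dl, s),
      Wzd = runif_mat(dl, zl, s),
      bh = rep(0, dl),
      Wmu_q = runif_mat(zl, dl, sh),
      Wsig_q = runif_mat(zl, dl, sh),
      bmu_p = rep(0, zl), bsig_p = rep(0, zl),
      bmu_q = rep(0, zl), bsig_q = rep(0, zl)
    )
    if (!share_heads) {
      ly$Wmu_p <- runif_mat(zl, dl, sh)
      ly$Wsig_p <- runif_mat(zl, dl, sh)
    }
    if (l < L) ly$Wdu <- runif_mat(dl, specs$d[l + 1], s)
    if (l > 1) ly$Wdl <- runif_mat(dl, specs$d[l - 1], s)
    layers[[l]] <- ly
  }
  structure(list(
    layers = layers,
    Wout = runif_mat(n_out, specs$d[1], 1 / sqrt(specs$d[1])),
    bout = rep(0, n_out),
    share_heads = share_heads
  ), class = "pvrnn_params")
}

specs_for_cpp <- function(specs) {
  list(d = as.integer(specs$d), z = as.integer(specs$z),
       tau = as.numeric(specs$tau))
}

# per-layer x per-step complexity weight matrix for training
build_w_matrix <- function(specs, T_len, w_t1 = 1.0) {
  w <- matrix(specs$wt, nrow = length(specs$d), ncol = T_len)
  w[, 1] <- w_t1
  w
}

#' Model container
#'
#' @param params Network parameters.
#' @param specs Layer specifications.
#' @param config Optional training configuration echo.
#' @param A_train Optional per-sequence adaptive posterior variables.
#' @param loss_history Optional per-epoch free-energy trace.
#' @export
pvrnn_model <- function(params, specs, config = NULL, A_train = NULL,
                        loss_history = NULL) {
  structure(list(params = params, specs = specs, config = config,
                 A_train = A_train, loss_history = loss_history),
            class = "pvrnn_model")
}

#' @export
print.pvrnn_model <- function(x, ...) {
  cat(sprintf("<pvrnn_model> %d layers, d = (%s), z = (%s), tau = (%s)\n",
              length(x$specs$d), paste(x$specs$d, collapse = ", "),
              paste(x$specs$z, collapse = ", "),
              paste(x$specs$tau, collapse = ", ")))
  if (!is.null(x$loss_history)) {
    cat(sprintf("  trained %d epochs, final F = %.4f\n",
                length(x$loss_history), utils::tail(x$loss_history, 1)))
  }
  invisible(x)
}

#' Closed-loop generation from the learned prior
#'
#' Rolls the network forward for \code{T_steps} sampling the latent state
#' from the conditional prior at every step (unit Gaussian at the first
#' step); no sensory inference is performed. This is the network's
#' spontaneous behavior.
#'
#' @param model A \code{pvrnn_model} (or bare parameter/spec pair).
#' @param T_steps Rollout length.
#' @param seed Optional integer seed.
#' @param deterministic Propagate the prior mean instead of sampling.
#' @return List with \code{outputs} (T x 10 network outputs), \code{proprio},
#'   \code{extero} (physical units), and the prior mean trace \code{mup} per
#'   layer.
#' @export
prior_generate <- function(model, T_steps, seed = NULL,
                           deterministic = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_prior_generate(model$params, specs_for_cpp(model$specs),
                            as.integer(T_steps), TRUE, deterministic)
  parts <- targets_to_trajectory(res$xbar)
  list(outputs = res$xbar, proprio = parts$proprio, extero = parts$extero,
       mup = res$mup, sigp = res$sigp)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS archive of the parameter list together with a
#' JSON sidecar describing the layer specification; the loader validates
#' shapes against the sidecar.
#'
#' @param model A \code{pvrnn_model}.
#' @param path Checkpoint path (the sidecar gets extension \code{.json}).
#' @export
pvrnn_save <- function(model, path) {
  saveRDS(model, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(d = model$specs$d, z = model$specs$z, tau = model$specs$tau,
         wt = model$specs$wt),
    sidecar, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname pvrnn_save
#' @export
pvrnn_load <- function(path) {
  model <- readRDS(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    ok <- identical(as.integer(meta$d), as.integer(model$specs$d)) &&
      identical(as.integer(meta$z), as.integer(model$specs$z))
    if (!ok) stop("checkpoint sidecar does not match parameter shapes",
                  call. = FALSE)
  }
  model
}

#' Arm-swap conjugate of a trained model
#'
#' The imitation task is mirror-symmetric: swapping the two arms (joint
#' channels 1-3 with 4-6) maps the left-dominant primitive onto the
#' right-dominant one, and the planar kinematics satisfy
#' \code{forward_kinematics(swap(q)) = mirror_hands(forward_kinematics(q))}.
#' Because the output nonlinearity is odd, conjugating the output map by
#' this signed channel permutation turns a trained B-preferring network
#' into an exactly equivalent C-preferring network (and vice versa): its
#' rollouts are the channel-mirrored rollouts of the original.
#'
#' @param model A trained \code{pvrnn_model}.
#' @return A \code{pvrnn_model} expressing the mirrored preference.
#' @export
mirror_model <- function(model) {
  S <- matrix(0, 10, 10)
  S[1, 4] <- S[2, 5] <- S[3, 6] <- 1   # left joints <- right joints
  S[4, 1] <- S[5, 2] <- S[6, 3] <- 1
  S[7, 9] <- -1                        # lx <- -rx
  S[8, 10] <- 1                        # ly <-  ry
  S[9, 7] <- -1                        # rx <- -lx
  S[10, 8] <- 1                        # ry <-  ly
  model$params$Wout <- S %*% model$params$Wout
  model$params$bout <- drop(S %*% model$params$bout)
  model
}
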