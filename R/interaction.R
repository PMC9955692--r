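# Dyadic coupling: each agent's exteroception is the mirrored hand position
# of the partner's executed movement; both agents run sliding-window online
# inference every step.

#' Bundle a trained model into an interaction agent
#'
#' @param model A \code{pvrnn_model}.
#' @param config An \code{\link{inference_config}}.
#' @param schedule A \code{\link{meta_prior_schedule}} for the layer-1
#'   interaction meta-prior.
#' @param name Label used in traces.
#' @export
agent <- function(model, config = inference_config(),
                  schedule = meta_prior_schedule("constant", value = 1),
                  name = "agent") {
  structure(list(model = model, config = config, schedule = schedule,
                 name = name), class = "pvrnn_agent")
}

#' Run a dyadic interaction
#'
#' Updates are synchronous: at every step both agents first execute the
#' action generated from their previous window, then observe the partner's
#' executed movement (mirrored hand positions), extend and re-optimize
#' their posterior window, and generate the next action from the prior.
#' Proprioceptive predictions are executed perfectly (actuation is
#' abstracted away).
#'
#' @param agent1,agent2 \code{\link{agent}} objects.
#' @param T_steps Interaction length (default 1000).
#' @param seed Optional integer seed.
#' @return A \code{tibble} trace with one row per step per agent: executed
#'   proprioception \code{j1..j6}, observed and predicted exteroception,
#'   the meta-prior \code{wi}, first/last free energy of the inference
#'   iterations, per-layer KL at the newest step, and the layer-1 prior and
#'   posterior means (first latent unit).
#' @export
run_interaction <- function(agent1, agent2, T_steps = 1000L, seed = NULL) {
  stopifnot(inherits(agent1, "pvrnn_agent"), inherits(agent2, "pvrnn_agent"))
  if (!is.null(seed)) set.seed(seed)
  agents <- list(agent1, agent2)
  windows <- lapply(agents, function(a) new_posterior_window(a$model, a$config))
  # initial action: one generative step from the unit-Gaussian prior
  action <- lapply(agents, function(a) {
    out <- cpp_prior_generate(a$model$params, specs_for_cpp(a$model$specs),
                              1L, TRUE, a$config$deterministic)
    drop(out$xbar)
  })
  rows <- vector("list", 2L * T_steps)
  aborted <- FALSE
  for (t in seq_len(T_steps)) {
    # synchronous exchange: both agents observe the partner's step-t action
    obs <- list(observe_partner(action[[1]][1:6]),
                observe_partner(action[[2]][1:6]))
    next_action <- action
    for (i in 1:2) {
      j <- 3L - i
      obs_row <- c(rep(0, 6), obs[[j]] / EXTERO_SCALE)
      slide_window(windows[[i]], obs_row)
      wi <- eval_schedule(agents[[i]]$schedule, t)
      info <- tryCatch(infer_step(windows[[i]], wi),
                       error = function(e) e)
      if (inherits(info, "error")) {
        warning(sprintf("interaction aborted at step %d (%s): %s",
                        t, agents[[i]]$name, conditionMessage(info)))
        aborted <- TRUE
        break
      }
      rows[[2L * (t - 1L) + i]] <- c(
        list(t = t, agent = i),
        as.list(stats::setNames(action[[i]][1:6], paste0("j", 1:6))),
        as.list(stats::setNames(obs[[j]], c("olx", "oly", "orx", "ory"))),
        as.list(stats::setNames(action[[i]][7:10] * EXTERO_SCALE,
                                c("plx", "ply", "prx", "pry"))),
        list(wi = wi,
             F_first = info$ftrace[1],
             F_last = if (length(info$ftrace)) {
               info$ftrace[length(info$ftrace)]
             } else info$F,
             F = info$F),
        as.list(stats::setNames(info$kl_last,
                                paste0("kl", seq_along(info$kl_last)))),
        as.list(stats::setNames(info$kl_window,
                                paste0("klw", seq_along(info$kl_window)))),
        list(mu_p1 = info$mup_last[[1]][1], mu_q1 = info$muq_last[[1]][1])
      )
      next_action[[i]] <- info$pred_next
    }
    if (aborted) break
    action <- next_action
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE)
  })))
}

#' Extract one agent's executed proprioception from a trace
#'
#' @param trace Output of \code{\link{run_interaction}}.
#' @param which_agent 1 or 2.
#' @return T x 6 matrix of joint angles.
#' @export
trace_proprio <- function(trace, which_agent) {
  as.matrix(trace[trace$agent == which_agent, paste0("j", 1:6)])
}

#' Anti-phase oscillating meta-prior experiment
#'
#' Installs sinusoidal anti-phase meta-prior schedules in both agents (both
#' starting from the midline during an onset plateau) and runs an
#' interaction of \code{n_periods * period + onset} steps.
#'
#' @param agent1,agent2 \code{\link{agent}} objects (their schedules are
#'   replaced).
#' @param lower,upper Layer-1 meta-prior extremes (defaults 0.0048 and
#'   1.0461, grid points 10 and 41 of the standard 50-point log grid).
#' @param period Oscillation period (default 1280 steps).
#' @param onset Onset plateau length (default 80 steps).
#' @param n_periods Number of oscillation periods (default 3).
#' @param seed Optional integer seed.
#' @return Interaction trace (see \code{\link{run_interaction}}), with the
#'   total length \code{n_periods * period + onset}.
#' @export
run_oscillation_experiment <- function(agent1, agent2, lower = 0.0048,
                                       upper = 1.0461, period = 1280L,
                                       onset = 80L, n_periods = 3L,
                                       seed = NULL) {
  stopifnot(lower < upper)
  mid <- (lower + upper) / 2
  s1 <- meta_prior_schedule("sinusoid", lower = lower, upper = upper,
                            period = period, phase = 0,
                            onset_len = onset, onset_value = mid)
  s2 <- meta_prior_schedule("sinusoid", lower = lower, upper = upper,
                            period = period, phase = pi,
                            onset_len = onset, onset_value = mid)
  agent1$schedule <- s1
  agent2$schedule <- s2
  T_total <- as.integer(n_periods * period + onset)
  run_interaction(agent1, agent2, T_steps = T_total, seed = seed)
}
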