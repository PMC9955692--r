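# Shared fixtures. Heavy objects (trained networks, the standard classifier)
# are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- builder()
  }
  .fixture_cache[[name]]
}

tiny_specs <- function() {
  pvrnn_specs(d = c(5L, 4L, 3L), z = c(2L, 2L, 1L), tau = c(1, 2, 4),
              wt1 = 0.7, wt_factor = 3)
}

# small random training problem for engine-level tests
tiny_problem <- function(T_len = 6L, B = 2L, seed = 11L) {
  specs <- tiny_specs()
  set.seed(seed)
  params <- pvrnn_init(specs, seed = seed)
  X <- array(runif(10 * B * T_len, -0.5, 0.5), dim = c(10L, B, T_len))
  Amu <- lapply(specs$z, function(zl) {
    array(rnorm(zl * B * T_len, 0, 0.3), c(zl, B, T_len))
  })
  Asig <- lapply(specs$z, function(zl) {
    array(rnorm(zl * B * T_len, 0, 0.3), c(zl, B, T_len))
  })
  eps <- lapply(specs$z, function(zl) {
    array(rnorm(zl * B * T_len), c(zl, B, T_len))
  })
  list(specs = specs, params = params, X = X, Amu = Amu, Asig = Asig,
       eps = eps, T_len = T_len, B = B,
       w = pvrnndyad:::build_w_matrix(specs, T_len, 1.0),
       mask = rep(1, 10), sp = pvrnndyad:::specs_for_cpp(specs))
}

get_classifier <- function() {
  cache_fixture("classifier", function() standard_classifier())
}

# Desk-scale trained agents. The protocol trains two B-preferring networks
# with different seeds and derives the C-preferring agent by the exact
# arm-swap conjugation (mirror_model); using two independent trainings
# avoids the artificial resonance of coupling a network with its own
# mirror image.
desk_specs <- function() {
  pvrnn_specs(d = c(16L, 8L, 4L), z = c(2L, 1L, 1L), tau = c(2, 4, 8))
}

train_desk_net <- function(data_seed, net_seed, epochs = 30000L) {
  ds <- generate_training_set(robot_fsm(2), 8L, 200L, seed = data_seed)
  train_pvrnn(ds, desk_specs(),
              training_config(epochs = epochs, lr = 0.003,
                              seed = net_seed))
}

get_trained_model <- function(robot) {
  if (robot == 2L) {
    cache_fixture("model_r2", function() train_desk_net(8L, 4L))
  } else {
    cache_fixture("model_r1", function() {
      mirror_model(cache_fixture("model_r1_base",
                                 function() train_desk_net(6L, 3L)))
    })
  }
}

desk_agent <- function(robot, wi) {
  agent(get_trained_model(robot), inference_config(),
        meta_prior_schedule("constant", value = wi),
        name = paste0("robot", robot))
}

# shared heavy interaction artifacts: the diagonal of the coarse sweep
# (small, medium and large equal meta-prior pairs)
get_sweep_cells <- function() {
  cache_fixture("sweep_cells", function() {
    run_phase_sweep(get_trained_model(1), get_trained_model(2),
                    get_classifier(), build_meta_prior_grid(),
                    indices = integer(0),
                    pairs = data.frame(idx1 = c(10L, 35L, 50L),
                                       idx2 = c(10L, 35L, 50L)),
                    T_steps = 600L, repeats = 1L, min_run = 10L, seed = 7L)
  })
}

get_oscillation_result <- function() {
  cache_fixture("oscillation", function() {
    a1 <- desk_agent(1, 0.5255)
    a2 <- desk_agent(2, 0.5255)
    tr <- run_oscillation_experiment(a1, a2, period = 480L, onset = 40L,
                                     n_periods = 2L, seed = 21L)
    cls <- get_classifier()
    lab1 <- label_sequence(cls, trace_proprio(tr, 1))
    lab2 <- label_sequence(cls, trace_proprio(tr, 2))
    win <- 120L
    te12 <- sliding_transfer_entropy(lab1, lab2, win)
    te21 <- sliding_transfer_entropy(lab2, lab1, win)
    w1 <- tr$wi[tr$agent == 1]
    w2 <- tr$wi[tr$agent == 2]
    centers <- seq.int(win, length(lab1)) - win %/% 2L
    list(trace = tr, te_diff = te12 - te21,
         w1_larger = w1[centers] > w2[centers])
  })
}

# fixed-noise smoke interaction: with the reparameterization noise held
# fixed within each step's inner iterations, the windowed objective is
# deterministic and the free-energy trace isolates the optimizer
get_smoke_trace <- function() {
  cache_fixture("smoke_trace", function() {
    mk <- function(robot) {
      agent(get_trained_model(robot),
            inference_config(resample_noise = FALSE),
            meta_prior_schedule("constant", value = 0.369),
            name = paste0("robot", robot))
    }
    run_interaction(mk(1), mk(2), T_steps = 150L, seed = 5L)
  })
}

# majority per-step label of each sliding window: the ground-truth
# convention the classifier is trained with
majority_window_labels <- function(labels, window = 12L) {
  n <- length(labels) - window
  vapply(seq_len(n), function(i) {
    names(sort(table(labels[i:(i + window - 1L)]), decreasing = TRUE))[1]
  }, character(1))
}
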