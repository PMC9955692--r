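# Experiment drivers: the log-spaced meta-prior grid, the two-dimensional
# phase sweep over meta-prior pairs, region summaries and heat-map plots.

#' Log-spaced interaction meta-prior grid
#'
#' \code{n} values from \code{w_min} to \code{w_max} inclusive, equally
#' spaced on a logarithmic scale:
#' \eqn{w_i = w_{min} (w_{max}/w_{min})^{(i-1)/(n-1)}}. Layers 2 and 3 use
#' 10 and 100 times the layer-1 value.
#'
#' @param w_min,w_max Grid endpoints (defaults 0.001 and 5).
#' @param n Number of grid points (default 50).
#' @return Object of class \code{meta_prior_grid} with \code{values} and
#'   \code{layer_multipliers}.
#' @export
build_meta_prior_grid <- function(w_min = 0.001, w_max = 5, n = 50L) {
  if (!(w_min > 0 && w_min < w_max)) {
    stop("need 0 < w_min < w_max", call. = FALSE)
  }
  stopifnot(n >= 2)
  values <- w_min * (w_max / w_min)^((seq_len(n) - 1) / (n - 1))
  structure(list(values = values, layer_multipliers = c(1, 10, 100)),
            class = "meta_prior_grid")
}

#' @export
print.meta_prior_grid <- function(x, ...) {
  cat(sprintf("<meta_prior_grid> %d values from %g to %g (log scale)\n",
              length(x$values), x$values[1],
              x$values[length(x$values)]))
  invisible(x)
}

# deterministic per-cell seed below 2^31
cell_seed <- function(base_seed, idx1, idx2, rep) {
  (base_seed * 7919L + idx1 * 104729L + idx2 * 1299709L + rep * 15485863L) %%
    2147483647L
}

#' Sweep dyadic interactions over meta-prior pairs
#'
#' For every requested pair of grid indices (and repeat), runs a full
#' interaction with constant meta-prior schedules, classifies both agents'
#' movements and computes the behavioral statistics; repeats are averaged.
#'
#' @param models1,models2 Lists of trained models for agent 1 and agent 2
#'   (paired by index across repeats).
#' @param classifier A fitted primitive classifier.
#' @param grid A \code{\link{build_meta_prior_grid}} grid.
#' @param indices Integer vector of grid indices to sweep on both axes.
#' @param pairs Optional two-column data frame (\code{idx1}, \code{idx2}) of
#'   explicit cells, overriding the \code{indices} product.
#' @param T_steps Interaction length per cell.
#' @param repeats Interactions per cell (network pairs used in order).
#' @param config Inference configuration for both agents.
#' @param min_run Minimum synchronized run for turn detection.
#' @param seed Base seed; each cell derives its own recorded seed.
#' @return Tibble with one row per cell: indices, meta-priors, per-robot
#'   label frequencies, synchronization rates, turn count, transfer
#'   entropies and the cell seed of the first repeat.
#' @export
run_phase_sweep <- function(models1, models2, classifier, grid,
                            indices, T_steps = 1000L, repeats = 1L,
                            config = inference_config(), min_run = 1L,
                            seed = 1L, pairs = NULL) {
  if (inherits(models1, "pvrnn_model")) models1 <- list(models1)
  if (inherits(models2, "pvrnn_model")) models2 <- list(models2)
  cells <- if (is.null(pairs)) {
    expand.grid(idx1 = indices, idx2 = indices)
  } else {
    as.data.frame(pairs)
  }
  stopifnot(repeats >= 1, all(cells$idx1 >= 1), all(cells$idx2 >= 1),
            all(cells$idx1 <= length(grid$values)),
            all(cells$idx2 <= length(grid$values)))
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    idx1 <- cells$idx1[ci]
    idx2 <- cells$idx2[ci]
    w1 <- grid$values[idx1]
    w2 <- grid$values[idx2]
    stats_rep <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      m1 <- models1[[((r - 1L) %% length(models1)) + 1L]]
      m2 <- models2[[((r - 1L) %% length(models2)) + 1L]]
      s <- cell_seed(seed, idx1, idx2, r)
      trace <- run_interaction(
        agent(m1, config, meta_prior_schedule("constant", value = w1), "r1"),
        agent(m2, config, meta_prior_schedule("constant", value = w2), "r2"),
        T_steps = T_steps, seed = s)
      lab1 <- label_sequence(classifier, trace_proprio(trace, 1))
      lab2 <- label_sequence(classifier, trace_proprio(trace, 2))
      f1 <- movement_frequency(lab1)
      f2 <- movement_frequency(lab2)
      sy <- synchronization_rate(lab1, lab2)
      stats_rep[[r]] <- c(
        freq_A1 = f1[["A"]], freq_B1 = f1[["B"]], freq_C1 = f1[["C"]],
        freq_A2 = f2[["A"]], freq_B2 = f2[["B"]], freq_C2 = f2[["C"]],
        sync_all = sy$overall,
        sync_A = sy$per_label[["A"]], sync_B = sy$per_label[["B"]],
        sync_C = sy$per_label[["C"]],
        turns = count_turn_taking(lab1, lab2, min_run),
        te12 = transfer_entropy(lab1, lab2),
        te21 = transfer_entropy(lab2, lab1))
    }
    avg <- colMeans(do.call(rbind, stats_rep), na.rm = TRUE)
    out[[ci]] <- c(list(idx1 = idx1, idx2 = idx2, w1 = w1, w2 = w2),
                   as.list(avg),
                   list(seed = cell_seed(seed, idx1, idx2, 1L)))
  }
  tibble::as_tibble(do.call(rbind, lapply(out, function(r) {
    as.data.frame(r, check.names = FALSE)
  })))
}

#' Summarize the region structure of a classified phase grid
#'
#' @param grid A grid tibble carrying a \code{region} column (see
#'   \code{\link{classify_phase_regions}}).
#' @return List with per-region cell counts, fractions and the cell index
#'   sets; serializable to JSON.
#' @export
summarize_regions <- function(grid) {
  stopifnot("region" %in% names(grid))
  regions <- c("ignoring", "robot1_leads", "robot2_leads", "turn_taking")
  counts <- vapply(regions, function(r) sum(grid$region == r), numeric(1))
  cells <- lapply(regions, function(r) {
    idx <- grid$region == r
    data.frame(idx1 = grid$idx1[idx], idx2 = grid$idx2[idx])
  })
  names(cells) <- regions
  list(n_cells = nrow(grid), counts = as.list(counts),
       fractions = as.list(counts / nrow(grid)), cells = cells)
}

#' Heat-map plot of one phase-grid statistic
#'
#' @param grid A sweep tibble.
#' @param stat Column name to plot.
#' @return A \code{ggplot} object (grid indices on both axes).
#' @importFrom ggplot2 .data
#' @export
plot_phase_grid <- function(grid, stat = "sync_all") {
  stopifnot(stat %in% names(grid))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$idx1, y = .data$idx2,
                                     fill = .data[[stat]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = stat) +
    ggplot2::labs(x = "meta-prior index, robot 1",
                  y = "meta-prior index, robot 2") +
    ggplot2::theme_minimal()
}
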