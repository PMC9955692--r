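# Behavioral statistics of dyadic interactions: label frequencies,
# synchronization, turn-taking counts, transfer entropy on the 3-symbol
# label alphabet, and phase-region classification.

#' Per-label movement frequencies
#'
#' @param labels Character vector of primitive labels.
#' @return Named fractions over \code{A}, \code{B}, \code{C} summing to 1.
#' @export
movement_frequency <- function(labels) {
  stopifnot(length(labels) >= 1)
  tab <- table(factor(labels, levels = PRIMITIVE_LABELS))
  stats::setNames(as.numeric(tab) / length(labels), PRIMITIVE_LABELS)
}

#' Synchronization rate between two label sequences
#'
#' The overall rate is the fraction of steps at which the two sequences
#' agree. The per-label rate for primitive M is the number of steps at which
#' both show M divided by the number of steps at which either shows M
#' (0 to 1; \code{NaN} when M never occurs).
#'
#' @param labels1,labels2 Equal-length label vectors.
#' @return List with \code{overall} and named \code{per_label} rates.
#' @export
synchronization_rate <- function(labels1, labels2) {
  if (length(labels1) != length(labels2)) {
    stop("label sequences must have equal length", call. = FALSE)
  }
  per <- vapply(PRIMITIVE_LABELS, function(m) {
    both <- sum(labels1 == m & labels2 == m)
    either <- sum(labels1 == m | labels2 == m)
    if (either == 0) NaN else both / either
  }, numeric(1))
  list(overall = mean(labels1 == labels2), per_label = per)
}

#' Chance-level synchronization of independent label processes
#'
#' Under independence, the probability that two agents show the same label
#' at a step is \eqn{\sum_M p_1(M) p_2(M)}. Inputs are per-label occurrence
#' probabilities in [0, 1]; they are usually a distribution over the labels,
#' but the standard operating point of the imitation task quotes the
#' deterministic primitive at its per-step rate (0.5) and the two
#' probabilistic primitives at their transition biases (0.8/0.2), giving
#' \code{0.5 * 0.5 + 0.2 * 0.8 + 0.8 * 0.2 = 0.57}.
#'
#' @param p1,p2 Per-label probabilities (equal length, each in [0, 1]).
#' @return Scalar chance-level synchronization.
#' @export
chance_level_sync <- function(p1, p2) {
  stopifnot(length(p1) == length(p2),
            all(p1 >= 0), all(p1 <= 1), all(p2 >= 0), all(p2 <= 1))
  sum(p1 * p2)
}

#' Per-label chance synchronization (intersection over union)
#'
#' The per-label synchronization rate of \code{\link{synchronization_rate}}
#' is an intersection-over-union; under independence its chance level for
#' label M is \eqn{p_1 p_2 / (p_1 + p_2 - p_1 p_2)}.
#'
#' @param p1,p2 Label distributions (named over A, B, C).
#' @return Named per-label chance rates.
#' @export
chance_level_sync_per_label <- function(p1, p2) {
  stats::setNames(p1 * p2 / (p1 + p2 - p1 * p2), names(p1))
}

# maximal synchronized B/C segments of minimum length: returns the segment
# label sequence in temporal order
sync_segments <- function(labels1, labels2, min_run = 1L) {
  sync <- ifelse(labels1 == labels2 & labels1 %in% c("B", "C"),
                 labels1, "-")
  r <- rle(sync)
  keep <- r$values %in% c("B", "C") & r$lengths >= min_run
  r$values[keep]
}

#' Count turn-taking events between two preferred movements
#'
#' A turn is a switch of the jointly synchronized primitive from B to C or
#' C to B: maximal segments during which both sequences show the same label
#' B or C (of at least \code{min_run} steps) are extracted, and each change
#' of label between consecutive segments counts as one turn, regardless of
#' intervening A steps or unsynchronized stretches.
#'
#' @param labels1,labels2 Equal-length label vectors.
#' @param min_run Minimum synchronized run length for a segment to count
#'   (filters single-step label flicker).
#' @return Integer number of turns.
#' @export
count_turn_taking <- function(labels1, labels2, min_run = 1L) {
  if (length(labels1) != length(labels2)) {
    stop("label sequences must have equal length", call. = FALSE)
  }
  seg <- sync_segments(labels1, labels2, min_run)
  if (length(seg) < 2) return(0L)
  sum(seg[-1] != seg[-length(seg)])
}

# k-step history strings ending at position i (i >= k)
history_key <- function(x, i, k) {
  vapply(i, function(j) paste(x[(j - k + 1L):j], collapse = ""), character(1))
}

#' Transfer entropy between two symbolic sequences
#'
#' Plug-in estimator (no bias correction) of the directed information flow
#' from \code{source} to \code{target} over the label alphabet, in bits:
#' \deqn{TE_{X \to Y} = \sum p(y_{t+1}, y_t^{(k)}, x_t^{(l)}) \log_2
#'   \frac{p(y_{t+1} | y_t^{(k)}, x_t^{(l)})}{p(y_{t+1} | y_t^{(k)})}}
#'
#' @param source,target Equal-length symbol vectors.
#' @param k Target history length (default 1).
#' @param l Source history length (default 1).
#' @return Nonnegative transfer entropy in bits.
#' @export
transfer_entropy <- function(source, target, k = 1L, l = 1L) {
  n <- length(target)
  if (length(source) != n) {
    stop("source and target must have equal length", call. = FALSE)
  }
  m <- max(k, l)
  if (n < m + 1L) stop("sequences too short for the chosen histories",
                       call. = FALSE)
  idx <- (m):(n - 1L)             # time of the last history symbol
  y1 <- target[idx + 1L]
  yk <- history_key(target, idx, k)
  xl <- history_key(source, idx, l)
  N <- length(idx)
  n_y1yk_xl <- table(paste(y1, yk, xl))
  n_yk_xl <- table(paste(yk, xl))
  n_y1yk <- table(paste(y1, yk))
  n_yk <- table(paste(yk))
  key_full <- paste(y1, yk, xl)
  key_cond <- paste(yk, xl)
  key_joint <- paste(y1, yk)
  # evaluate the sum over observed tuples without double counting
  tup <- !duplicated(key_full)
  p_full <- as.numeric(n_y1yk_xl[key_full[tup]]) / N
  logterm <- log2(
    as.numeric(n_y1yk_xl[key_full[tup]]) *
      as.numeric(n_yk[yk[tup]]) /
      (as.numeric(n_yk_xl[key_cond[tup]]) *
         as.numeric(n_y1yk[key_joint[tup]]))
  )
  te <- sum(p_full * logterm)
  max(te, 0)
}

#' Sliding-window transfer entropy
#'
#' Transfer entropy over the trailing window \code{[t - window + 1, t]} for
#' every valid \code{t}.
#'
#' @inheritParams transfer_entropy
#' @param window Window length (default 320).
#' @return Numeric vector of length \code{length(target) - window + 1}.
#' @export
sliding_transfer_entropy <- function(source, target, window = 320L,
                                     k = 1L, l = 1L) {
  n <- length(target)
  if (n < window) stop("sequences shorter than the window", call. = FALSE)
  vapply(seq.int(window, n), function(t) {
    sl <- (t - window + 1L):t
    transfer_entropy(source[sl], target[sl], k, l)
  }, numeric(1))
}

#' Classify phase-space cells into coordination regions
#'
#' Cells where both B- and C-synchronization exceed their chance level are
#' \code{turn_taking}; neither above chance is \code{ignoring}; only the
#' C-synchronization above chance means the C-preferring agent (robot 1)
#' leads, and only B above chance means robot 2 leads.
#'
#' @param grid A data frame / tibble with columns \code{sync_B} and
#'   \code{sync_C} (per-label synchronization rates per cell).
#' @param chance_B,chance_C Per-label chance thresholds (defaults derived
#'   from the 50/10/40 vs 50/40/10 training marginals).
#' @return The grid with a \code{region} column added.
#' @export
classify_phase_regions <- function(grid,
                                   chance_B = NULL, chance_C = NULL) {
  if (is.null(chance_B) || is.null(chance_C)) {
    p1 <- c(A = 0.5, B = 0.1, C = 0.4)
    p2 <- c(A = 0.5, B = 0.4, C = 0.1)
    ch <- chance_level_sync_per_label(p1, p2)
    if (is.null(chance_B)) chance_B <- ch[["B"]]
    if (is.null(chance_C)) chance_C <- ch[["C"]]
  }
  b <- !is.na(grid$sync_B) & grid$sync_B > chance_B
  c_ <- !is.na(grid$sync_C) & grid$sync_C > chance_C
  grid$region <- ifelse(b & c_, "turn_taking",
                        ifelse(!b & !c_, "ignoring",
                               ifelse(c_, "robot1_leads", "robot2_leads")))
  grid
}
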