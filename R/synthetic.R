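# Synthetic movement-primitive data: probabilistic finite-state machine over
# primitives A/B/C, waveform rendering to 6 joint channels, and the planar
# two-arm kinematics producing the 4-channel hand-position exteroception.

#' Primitive labels
#'
#' The three movement primitives, in their fixed serialization order.
#' @export
PRIMITIVE_LABELS <- c("A", "B", "C")

# Fixed affine constant mapping physical hand coordinates into (-1, 1) for the
# network output channels (|x| <= 0.5 + 3 link lengths).
EXTERO_SCALE <- 3.5

#' Probabilistic preference machine over movement primitives
#'
#' Primitive \code{A} is generated deterministically between every
#' probabilistic choice; after \code{A}, primitive \code{C} is chosen with
#' probability \code{p_ac} and \code{B} with \code{1 - p_ac}. \code{B} and
#' \code{C} return to \code{A} deterministically.
#'
#' @param p_ac Probability of choosing \code{C} after \code{A}.
#' @return An object of class \code{preference_fsm}.
#' @export
preference_fsm <- function(p_ac) {
  if (!is.numeric(p_ac) || length(p_ac) != 1L || is.na(p_ac) ||
      p_ac < 0 || p_ac > 1) {
    stop("`p_ac` must be a single probability in [0, 1]", call. = FALSE)
  }
  structure(list(p_ab = 1 - p_ac, p_ac = p_ac), class = "preference_fsm")
}

#' Preference machines of the two standard agents
#'
#' Agent 1 prefers \code{C} (80\% bias), agent 2 prefers \code{B}.
#'
#' @param robot 1 or 2.
#' @export
robot_fsm <- function(robot) {
  stopifnot(robot %in% c(1L, 2L))
  if (robot == 1L) preference_fsm(p_ac = 0.8) else preference_fsm(p_ac = 0.2)
}

#' Sample a primitive sequence from a preference machine
#'
#' @param fsm A \code{\link{preference_fsm}}.
#' @param n_primitives Number of primitive labels to emit (sequence starts at
#'   \code{A} and alternates \code{A} with a sampled \code{B}/\code{C}).
#' @param seed Optional integer seed.
#' @return Character vector of labels in \code{c("A","B","C")}.
#' @export
sample_primitive_sequence <- function(fsm, n_primitives, seed = NULL) {
  stopifnot(inherits(fsm, "preference_fsm"), n_primitives >= 1)
  if (!is.null(seed)) set.seed(seed)
  labels <- character(n_primitives)
  for (i in seq_len(n_primitives)) {
    if (i %% 2L == 1L) {
      labels[i] <- "A"
    } else {
      labels[i] <- if (stats::runif(1) < fsm$p_ac) "C" else "B"
    }
  }
  labels
}

#' Primitive waveform templates
#'
#' A fixed library of three joint-space templates, one per primitive, each
#' \code{D} steps by 6 joints with values in [-1, 1]. \code{A} is a symmetric
#' full-cycle swing of both arms, \code{B} a left-arm-dominant half-cycle
#' reach, and \code{C} its right-arm mirror. All templates start and end near
#' the rest posture so concatenated primitives remain continuous.
#'
#' @param D Primitive duration in time steps (default 20).
#' @return Object of class \code{primitive_waveforms}: a named list of
#'   \code{D x 6} matrices plus the duration \code{D}.
#' @export
primitive_waveforms <- function(D = 20L) {
  stopifnot(D >= 4)
  s <- seq_len(D) / D
  full <- sin(2 * pi * s)   # full cycle, zero at segment end
  bump <- sin(pi * s)       # half cycle reach
  amp_swing <- c(0.7, 0.45, 0.3)
  amp_reach <- c(0.85, 0.6, 0.4)
  A <- cbind(outer(full, amp_swing), outer(full, amp_swing))
  B <- cbind(outer(bump, amp_reach), outer(full, rep(0.15, 3)))
  C <- cbind(outer(full, rep(0.15, 3)), outer(bump, amp_reach))
  wf <- list(A = A, B = B, C = C)
  wf <- lapply(wf, function(m) {
    colnames(m) <- paste0("j", 1:6)
    m
  })
  structure(list(templates = wf, D = as.integer(D)),
            class = "primitive_waveforms")
}

#' Planar two-arm forward kinematics
#'
#' Each arm is a planar 3-joint chain of unit links; joints 1-3 drive the left
#' arm, joints 4-6 the right. Normalized joint angles in [-1, 1] map to
#' radians by a factor of pi/2. Shoulders sit at (-0.5, 0) and (+0.5, 0) and
#' the rest posture points both arms along +y, so the right arm is the mirror
#' image (x negated) of the left under equal joint values.
#'
#' @param proprio A 6-vector or a T x 6 matrix of normalized joint angles.
#' @return A 4-vector or T x 4 matrix \code{(lx, ly, rx, ry)} of hand
#'   positions.
#' @export
forward_kinematics <- function(proprio) {
  one <- is.null(dim(proprio))
  p <- if (one) matrix(proprio, nrow = 1L) else as.matrix(proprio)
  stopifnot(ncol(p) == 6L)
  th <- p * (pi / 2)
  phiL <- pi / 2 + t(apply(th[, 1:3, drop = FALSE], 1L, cumsum))
  phiR <- pi / 2 - t(apply(th[, 4:6, drop = FALSE], 1L, cumsum))
  if (nrow(p) == 1L) { phiL <- matrix(phiL, 1L); phiR <- matrix(phiR, 1L) }
  out <- cbind(
    lx = -0.5 + rowSums(cos(phiL)),
    ly = rowSums(sin(phiL)),
    rx = 0.5 + rowSums(cos(phiR)),
    ry = rowSums(sin(phiR))
  )
  if (one) out[1L, ] else out
}

#' Mirrored view of a set of hand positions
#'
#' The partner's (or mirror's) view of hand positions: left and right hands
#' swap and x coordinates negate. This single coordinate convention is used
#' both when building training exteroception from an agent's own movement and
#' when coupling two agents.
#'
#' @param hands A 4-vector or T x 4 matrix \code{(lx, ly, rx, ry)}.
#' @export
mirror_hands <- function(hands) {
  one <- is.null(dim(hands))
  h <- if (one) matrix(hands, nrow = 1L) else as.matrix(hands)
  stopifnot(ncol(h) == 4L)
  out <- cbind(lx = -h[, 3L], ly = h[, 4L], rx = -h[, 1L], ry = h[, 2L])
  if (one) out[1L, ] else out
}

#' Exteroception generated by a movement
#'
#' What an observer facing the mover sees: the mover's hand positions in the
#' observer's (mirrored) frame. Used for training data (an agent observing its
#' own mirror image) and for dyadic coupling (observing the partner).
#'
#' @param proprio A 6-vector or T x 6 matrix of normalized joint angles.
#' @return A 4-vector or T x 4 matrix of observed hand positions.
#' @export
observe_partner <- function(proprio) {
  mirror_hands(forward_kinematics(proprio))
}

#' Render a primitive label sequence into a trajectory
#'
#' Concatenates the waveform template of each label and attaches per-step
#' labels and the exteroceptive channels computed through
#' \code{\link{observe_partner}}.
#'
#' @param labels Character vector of primitive labels.
#' @param waveforms A \code{\link{primitive_waveforms}} library.
#' @param smooth Cross-fade width in steps at segment boundaries (0 disables).
#' @return Object of class \code{trajectory}: list with \code{proprio}
#'   (T x 6), \code{extero} (T x 4), \code{labels} (length T) and \code{D}.
#' @export
render_trajectory <- function(labels, waveforms = primitive_waveforms(),
                              smooth = 2L) {
  stopifnot(length(labels) >= 1)
  if (!all(labels %in% PRIMITIVE_LABELS)) {
    stop("unknown primitive label: ",
         paste(setdiff(labels, PRIMITIVE_LABELS), collapse = ", "),
         call. = FALSE)
  }
  D <- waveforms$D
  proprio <- do.call(rbind, lapply(labels, function(l) waveforms$templates[[l]]))
  if (smooth > 0 && length(labels) > 1) {
    # linear bridge across each segment boundary: the `smooth` rows straddling
    # the boundary are interpolated between their outer neighbours
    raw <- proprio
    half_lo <- smooth %/% 2L
    half_hi <- smooth - half_lo
    for (k in seq_len(length(labels) - 1L)) {
      b <- k * D  # last index of segment k
      zone <- (b - half_lo + 1L):(b + half_hi)
      r0 <- raw[zone[1L] - 1L, ]
      r1 <- raw[zone[length(zone)] + 1L, ]
      for (j in seq_along(zone)) {
        a <- j / (length(zone) + 1)
        proprio[zone[j], ] <- (1 - a) * r0 + a * r1
      }
    }
  }
  structure(list(
    proprio = proprio,
    extero = observe_partner(proprio),
    labels = rep(labels, each = D),
    D = D
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d steps, %d joints, primitive duration %d\n",
              nrow(x$proprio), ncol(x$proprio), x$D))
  invisible(x)
}

#' Generate a training set of movement trajectories
#'
#' @param fsm A \code{\link{preference_fsm}}.
#' @param n_sequences Number of trajectories (default 20).
#' @param T_steps Steps per trajectory (default 400); must be divisible by the
#'   primitive duration.
#' @param waveforms Waveform library.
#' @param smooth Cross-fade width passed to \code{\link{render_trajectory}}.
#' @param seed Optional integer seed.
#' @return List of \code{trajectory} objects.
#' @export
generate_training_set <- function(fsm, n_sequences = 20L, T_steps = 400L,
                                  waveforms = primitive_waveforms(),
                                  smooth = 2L, seed = NULL) {
  D <- waveforms$D
  if (T_steps %% D != 0) {
    stop("`T_steps` must be divisible by the primitive duration D = ", D,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_sequences), function(i) {
    labels <- sample_primitive_sequence(fsm, T_steps %/% D)
    render_trajectory(labels, waveforms, smooth = smooth)
  })
}

#' Stack a trajectory into the 10-channel network target matrix
#'
#' Proprioception passes through unchanged; exteroception is divided by the
#' fixed kinematic range constant so all channels live in (-1, 1).
#'
#' @param traj A \code{trajectory}.
#' @return T x 10 matrix (j1..j6, lx, ly, rx, ry scaled).
#' @export
trajectory_to_targets <- function(traj) {
  cbind(traj$proprio, traj$extero / EXTERO_SCALE)
}

#' Split a 10-channel network output into proprio and physical extero
#'
#' @param x T x 10 matrix of network outputs in (-1, 1).
#' @return List with \code{proprio} (T x 6) and \code{extero} (T x 4, physical
#'   units).
#' @export
targets_to_trajectory <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 10L)
  list(proprio = x[, 1:6, drop = FALSE],
       extero = x[, 7:10, drop = FALSE] * EXTERO_SCALE)
}

#' Write / read a trajectory as CSV
#'
#' Columns \code{j1..j6, lx, ly, rx, ry, label}, one row per time step.
#'
#' @param traj A \code{trajectory}.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(traj$proprio, traj$extero,
                   label = if (is.null(traj$labels)) NA_character_ else traj$labels)
  names(df) <- c(paste0("j", 1:6), "lx", "ly", "rx", "ry", "label")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- if (all(is.na(df$label))) NULL else as.character(df$label)
  D <- if (!is.null(labels)) max(rle(labels)$lengths) else NA_integer_
  structure(list(
    proprio = as.matrix(df[, paste0("j", 1:6)]),
    extero = as.matrix(df[, c("lx", "ly", "rx", "ry")]),
    labels = labels,
    D = D
  ), class = "trajectory")
}
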