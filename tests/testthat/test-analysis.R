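# Behavioral statistics: frequencies, synchronization, turn-taking counts,
# transfer entropy and phase-region classification.

test_that("movement frequencies are proper proportions", {
  expect_equal(movement_frequency(rep("A", 7)),
               c(A = 1, B = 0, C = 0))
  f <- movement_frequency(c(rep("A", 5), "B", rep("C", 4)))
  expect_equal(f, c(A = 0.5, B = 0.1, C = 0.4))
  set.seed(3)
  for (i in 1:5) {
    labs <- sample(PRIMITIVE_LABELS, 50, replace = TRUE)
    expect_equal(sum(movement_frequency(labs)), 1)
  }
})

test_that("synchronization rates follow the intersection-over-union rule", {
  l1 <- c("A", "A", "B", "B", "C", "C", "A", "B", "C", "A")
  expect_equal(synchronization_rate(l1, l1)$overall, 1)
  expect_equal(unname(synchronization_rate(l1, l1)$per_label),
               c(1, 1, 1))
  l2 <- c("B", "B", "A", "A", "A", "A", "B", "C", "C", "C")
  # hand count: agreement only at step 9 (C); overall 1/10
  expect_equal(synchronization_rate(l1, l2)$overall, 0.1)
  sy <- synchronization_rate(l1, l2)$per_label
  # A: either at steps 1,2,3,4,5,6,7,10 -> 8; both never -> 0
  expect_equal(sy[["A"]], 0)
  # B: either at 1,2,3,4,7,8 -> 6; both never -> 0
  expect_equal(sy[["B"]], 0)
  # C: either at 5,6,8,9,10 -> 5; both at 9 -> 1
  expect_equal(sy[["C"]], 0.2)
  # disjoint sequences never synchronize
  expect_equal(synchronization_rate(rep("B", 4), rep("C", 4))$overall, 0)
  expect_error(synchronization_rate(l1, l2[-1]), "equal length")
})

test_that("chance-level synchronization reproduces the analytic value", {
  # task operating point: A at its per-step rate, B/C at their 80/20
  # transition biases
  expect_equal(chance_level_sync(c(A = 0.5, B = 0.2, C = 0.8),
                                 c(A = 0.5, B = 0.8, C = 0.2)), 0.57)
  # per-step label marginals of the two training sets
  p1 <- c(A = 0.5, B = 0.1, C = 0.4)
  p2 <- c(A = 0.5, B = 0.4, C = 0.1)
  expect_equal(chance_level_sync(p1, p2), 0.33)
  expect_equal(chance_level_sync(c(1, 0, 0), c(1, 0, 0)), 1)
  expect_equal(chance_level_sync(rep(1 / 3, 3), rep(1 / 3, 3)), 1 / 3)
  # symmetric, and at most 1 with equality only for a shared point mass
  set.seed(8)
  for (i in 1:10) {
    a <- as.vector(stats::rmultinom(1, 50, c(0.3, 0.4, 0.3))) / 50
    b <- as.vector(stats::rmultinom(1, 50, c(0.2, 0.2, 0.6))) / 50
    expect_equal(chance_level_sync(a, b), chance_level_sync(b, a))
    expect_lte(chance_level_sync(a, b), 1)
  }
  ch <- chance_level_sync_per_label(p1, p2)
  expect_equal(ch[["B"]], 0.04 / 0.46)
  expect_equal(ch[["B"]], ch[["C"]])
})

test_that("turn counting follows the synchronized-segment definition", {
  sB <- rep("B", 3); sC <- rep("C", 3); sA <- rep("A", 3)
  mk <- function(...) c(...)
  # one switch: synchronized B then synchronized C
  l <- mk(sB, sA, sC)
  expect_identical(count_turn_taking(l, l), 1L)
  # only synchronized B segments: no turns
  l2 <- mk(sB, sA, sB)
  expect_identical(count_turn_taking(l2, l2), 0L)
  # B, C, B with A separators: two turns
  l3 <- mk(sB, sA, sC, sA, sB)
  expect_identical(count_turn_taking(l3, l3), 2L)
  # unsynchronized stretches do not reset the detector
  a <- mk(sB, rep("B", 3), sC)
  b <- mk(sB, rep("C", 3), sC)
  expect_identical(count_turn_taking(a, b), 1L)
  # short flickers are filtered by the minimum run length
  f1 <- c("B", "A", "A", "C", "A", "A")
  expect_identical(count_turn_taking(f1, f1, min_run = 2L), 0L)
  # invariant under a simultaneous B/C relabeling
  swap <- function(x) chartr("BC", "CB", x)
  set.seed(5)
  for (i in 1:10) {
    u <- sample(PRIMITIVE_LABELS, 60, replace = TRUE)
    v <- sample(PRIMITIVE_LABELS, 60, replace = TRUE)
    expect_identical(count_turn_taking(u, v),
                     count_turn_taking(swap(u), swap(v)))
  }
  expect_error(count_turn_taking(sB, mk(sB, sB)), "equal length")
})

# brute-force plug-in transfer entropy by explicit joint counting
te_brute <- function(src, tgt) {
  n <- length(tgt)
  trip <- data.frame(y1 = tgt[-1], y0 = tgt[-n], x0 = src[-n])
  total <- nrow(trip)
  te <- 0
  for (y1 in unique(trip$y1)) {
    for (y0 in unique(trip$y0)) {
      for (x0 in unique(trip$x0)) {
        nj <- sum(trip$y1 == y1 & trip$y0 == y0 & trip$x0 == x0)
        if (nj == 0) next
        nyx <- sum(trip$y0 == y0 & trip$x0 == x0)
        nyy <- sum(trip$y1 == y1 & trip$y0 == y0)
        ny <- sum(trip$y0 == y0)
        te <- te + (nj / total) * log2((nj * ny) / (nyx * nyy))
      }
    }
  }
  te
}

test_that("transfer entropy matches brute-force counting exactly", {
  set.seed(12)
  for (i in 1:5) {
    x <- sample(PRIMITIVE_LABELS, 120, replace = TRUE)
    y <- c("A", x[-120]) # y copies x with lag 1, first symbol arbitrary
    expect_equal(transfer_entropy(x, y), te_brute(x, y), tolerance = 1e-12)
    y2 <- sample(PRIMITIVE_LABELS, 120, replace = TRUE)
    expect_equal(transfer_entropy(x, y2), te_brute(x, y2),
                 tolerance = 1e-12)
  }
})

test_that("transfer entropy recovers the analytic copy-channel value", {
  set.seed(99)
  n <- 30000
  x <- sample(PRIMITIVE_LABELS, n, replace = TRUE)
  y <- c("A", x[-n])
  expect_equal(transfer_entropy(x, y), log2(3), tolerance = 0.01)
  # the reverse direction carries no information
  expect_lt(transfer_entropy(y, x) - 0, 0.01)
  # independent sequences: near zero (within plug-in bias)
  y2 <- sample(PRIMITIVE_LABELS, n, replace = TRUE)
  expect_lt(transfer_entropy(x, y2), 0.005)
  # constant target: exactly zero
  expect_equal(transfer_entropy(x, rep("A", n)), 0)
  expect_error(transfer_entropy(x, y2[-1]), "equal length")
})

test_that("directed coupling shows the expected transfer-entropy asymmetry", {
  set.seed(42)
  n <- 4000
  x <- sample(PRIMITIVE_LABELS, n, replace = TRUE)
  # target follows the source with one-step lag plus noise
  y <- ifelse(runif(n) < 0.8, c("A", x[-n]),
              sample(PRIMITIVE_LABELS, n, replace = TRUE))
  expect_gt(transfer_entropy(x, y), transfer_entropy(y, x))
})

test_that("sliding transfer entropy tiles the sequence correctly", {
  set.seed(6)
  n <- 500
  x <- sample(PRIMITIVE_LABELS, n, replace = TRUE)
  y <- c("A", x[-n])
  s <- sliding_transfer_entropy(x, y, window = 200)
  expect_length(s, n - 200 + 1)
  expect_true(all(is.finite(s)))
  # full-length window equals the global value
  expect_equal(sliding_transfer_entropy(x, y, window = n),
               transfer_entropy(x, y))
  # stationary coupling: sliding values fluctuate around the global TE
  expect_lt(abs(mean(s) - transfer_entropy(x, y)), 0.1)
  expect_error(sliding_transfer_entropy(x, y, window = n + 1), "shorter")
})

test_that("phase regions partition cells by above-chance synchronization", {
  ch <- chance_level_sync_per_label(c(A = 0.5, B = 0.1, C = 0.4),
                                    c(A = 0.5, B = 0.4, C = 0.1))
  grid <- tibble::tibble(
    idx1 = 1:4, idx2 = 1:4,
    sync_B = c(0.5, 0.01, 0.5, 0.01),
    sync_C = c(0.5, 0.01, 0.01, 0.5))
  out <- classify_phase_regions(grid)
  expect_identical(out$region,
                   c("turn_taking", "ignoring", "robot2_leads",
                     "robot1_leads"))
  # single dominant pattern gives a single-region partition
  g2 <- tibble::tibble(idx1 = 1:3, idx2 = 1:3,
                       sync_B = rep(0.9, 3), sync_C = rep(0.9, 3))
  expect_identical(unique(classify_phase_regions(g2)$region), "turn_taking")
  expect_true(all(out$sync_B[out$region == "turn_taking"] > ch[["B"]]))
})
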