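test_that("first-passage time matches the closed form and flags misses", {
  tr <- data.frame(time = 0:10, Q = 40 + 3 * (0:10))
  expect_equal(as.numeric(time_to_mark(tr, 49)), 3)
  expect_equal(as.numeric(time_to_mark(tr, 50.5)), 3.5) # interpolated
  miss <- time_to_mark(tr, 200)
  expect_true(is.na(miss))
  expect_false(attr(miss, "reached"))
  # monotone in the mark
  tms <- vapply(seq(41, 70, by = 3), function(m)
    as.numeric(time_to_mark(tr, m)), numeric(1))
  expect_true(all(diff(tms) >= 0))
})

test_that("first-passage interpolation is within one frame of a dense oracle", {
  set.seed(3)
  tt <- seq(0, 100, by = 0.01)
  q <- 40 + 0.8 * tt + 5 * sin(tt / 9)
  dense <- data.frame(time = tt, Q = q)
  sparse <- dense[seq(1, nrow(dense), by = 400), ] # frame interval 4
  for (mark in c(60, 80, 100)) {
    expect_lt(abs(as.numeric(time_to_mark(sparse, mark)) -
                    as.numeric(time_to_mark(dense, mark))), 4)
  }
})

test_that("the regime detector recovers planted breakpoints", {
  set.seed(12)
  for (rep in 1:5) {
    tb <- 50
    v1 <- 2; v2 <- 1
    tt <- seq(0, 100, length.out = 60)
    q <- 40 + ifelse(tt < tb, v1 * tt, v1 * tb + v2 * (tt - tb)) +
      rnorm(60, sd = 0.05 * v1 * tb)
    res <- detect_velocity_regimes(data.frame(time = tt, Q = q))
    expect_false(res$single_regime)
    expect_lt(abs(res$breakpoint_time - tb) / tb, 0.1)
    expect_lt(abs(res$v1 - v1) / v1, 0.15)
    expect_lt(abs(res$v2 - v2) / v2, 0.15)
  }
  # a pure line is declared single-regime
  lin <- data.frame(time = 0:39, Q = 40 + 2 * (0:39) + rnorm(40, sd = 0.3))
  expect_true(detect_velocity_regimes(lin)$single_regime)
})

test_that("heterogeneity ratio is simple arithmetic over first passages", {
  mk <- function(v) data.frame(time = 0:100, Q = 40 + v * (0:100))
  expect_equal(as.numeric(heterogeneity_ratio(list(mk(1), mk(1)), 90)), 1)
  # times to the mark 1, 2, 3 -> ratio 3
  tr3 <- list(mk(50), mk(25), mk(50 / 3))
  expect_equal(as.numeric(heterogeneity_ratio(tr3, 90)), 3, tolerance = 1e-10)
  expect_gte(as.numeric(heterogeneity_ratio(tr3, 60)), 1)
  # not-reached traces are dropped and flagged
  short <- data.frame(time = 0:10, Q = rep(41, 11))
  r <- heterogeneity_ratio(list(mk(1), mk(2), short), 90)
  expect_false(attr(r, "all_reached"))
})

test_that("knot length uses the inclusive index convention", {
  kymo <- data.frame(time = 0, b_pore = 1, k1 = 10L, k2 = 59L,
                     k3 = NA_integer_, k4 = NA_integer_,
                     found = TRUE, anomaly = FALSE)
  expect_equal(knot_length_series(kymo)$L1, 50L)
})

test_that("winding of a hand-built helix around a straight stem is exact", {
  # trajectory scaffold: straight stem of intact pairs below the pore, and a
  # broken-pair strand-B section wrapped around it in 3 full turns
  n_lead <- 2; nd <- 40
  n_stem <- 20
  b <- 0.5
  zs <- -(seq_len(nd) - 1) * b - 0.5
  A <- cbind(-0.5, 0, zs)
  B <- cbind(0.5, 0, zs)
  # broken section: B beads 21..40 lie on a helix about the stem axis
  hel <- seq_len(nd - n_stem)
  theta <- 3 * 2 * pi * (hel - 1) / (length(hel) - 1)
  zh <- seq(-1, -9.5, length.out = length(hel))
  B[n_stem + hel, ] <- cbind(1.5 * cos(theta), 1.5 * sin(theta), zh)
  lead <- cbind(0, 0, c(1, 0.5))
  ch <- duplex_chain(rbind(lead, A, B),
                     c(rep("lead", n_lead), rep("A", nd), rep("B", nd)),
                     pair_state = c(rep(TRUE, n_stem), rep(FALSE, nd - n_stem)))
  traj <- list(frames = list(ch$pos), pair_frames = list(ch$pair_state),
               time = 0, Q = n_lead, chain0 = ch,
               pore = slab_pore("narrow"))
  class(traj) <- "kp_trajectory"
  kymo <- data.frame(time = 0, b_pore = n_lead, k1 = n_lead + n_stem,
                     k2 = n_lead + nd, k3 = NA, k4 = NA, found = TRUE,
                     anomaly = FALSE)
  w <- wrapping_turns(traj, kymo)
  expect_equal(abs(w$turns), 3, tolerance = 0.1)
  # a strand lying straight beside the stem winds zero times
  ch0 <- ch
  ch0$pos[ch$pair_b, ] <- cbind(1.5, 0, zs)
  traj0 <- traj
  traj0$frames <- list(ch0$pos)
  traj0$chain0 <- ch0
  expect_equal(wrapping_turns(traj0, kymo)$turns, 0, tolerance = 1e-8)
  # stems shorter than 3 beads are reported as missing
  kymo_short <- kymo
  kymo_short$k1 <- n_lead + 1
  expect_true(is.na(wrapping_turns(traj, kymo_short)$turns))
})
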