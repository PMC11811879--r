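ff <- forcefield_params()
narrow <- slab_pore("narrow")
wide <- slab_pore("wide")
kT <- ff$temperature

line_scan <- function(pos0, pore, zs = seq(-1.5, 10, by = 0.02)) {
  vapply(zs, function(z) {
    p <- pos0
    p[, 3] <- p[, 3] + z
    confinement_forces(p, pore)$energy
  }, numeric(1))
}

test_that("confinement force is zero away from the wall and radial on it", {
  # far above the cis face, outside the mouth
  expect_equal(confinement_forces(matrix(c(5, 0, 5 + 8.52), 1, 3), narrow)$energy, 0)
  expect_equal(max(abs(confinement_forces(matrix(c(0, 0, -6), 1, 3), narrow)$forces)), 0)
  # mid-pore on the axis: zero radial force by symmetry (narrow squeeze is axial-free)
  f <- confinement_forces(matrix(c(0, 0, 4.26), 1, 3), narrow)$forces
  expect_equal(f[1, 1], 0)
  expect_equal(f[1, 2], 0)
  expect_equal(f[1, 3], 0)
  # force matches the numeric gradient for beads inside the ramp
  set.seed(1)
  pts <- rbind(c(1.2, 0.3, -0.3), c(0.7, 0, 4), c(2, 1, 8.7), c(0.2, 0.1, 0.5))
  for (r in seq_len(nrow(pts))) {
    p <- matrix(pts[r, ], 1, 3)
    f <- confinement_forces(p, narrow)$forces
    g <- matrix(0, 1, 3)
    for (d in 1:3) {
      pp <- p; pp[1, d] <- pp[1, d] + 1e-7
      pm <- p; pm[1, d] <- pm[1, d] - 1e-7
      g[1, d] <- -(confinement_forces(pp, narrow)$energy -
                     confinement_forces(pm, narrow)$energy) / 2e-7
    }
    expect_lt(max(abs(f - g)), 1e-4 * max(1, max(abs(g))))
  }
})

test_that("slab material presents a large barrier off-pore", {
  e <- line_scan(matrix(c(5, 0, 0), 1, 3), narrow)
  expect_gt(max(e) / kT, 100)
})

test_that("narrow pore passes one strand but blocks a paired dimer", {
  single <- line_scan(matrix(c(0, 0, 0), 1, 3), narrow)
  expect_lt(max(single) / kT, 2) # mild squeeze only
  dimer <- matrix(c(ff$pair_r0 / 2, 0, 0, -ff$pair_r0 / 2, 0, 0), 2, 3,
                  byrow = TRUE)
  expect_gt(max(line_scan(dimer, narrow)) / kT, 50)
})

test_that("wide pore passes a duplex but blocks a three-duplex bundle", {
  dimer <- matrix(c(ff$pair_r0 / 2, 0, 0, -ff$pair_r0 / 2, 0, 0), 2, 3,
                  byrow = TRUE)
  expect_equal(max(line_scan(dimer, wide)), 0)
  # three duplexes at realistic contact packing (centres 2.24 nm apart)
  ang <- c(0, 2 * pi / 3, 4 * pi / 3)
  ctr <- cbind(2.24 / sqrt(3) * cos(ang), 2.24 / sqrt(3) * sin(ang), 0)
  bundle <- do.call(rbind, lapply(1:3, function(i) {
    off <- 0.5 * c(cos(ang[i] + pi / 2), sin(ang[i] + pi / 2), 0)
    rbind(ctr[i, ] + off, ctr[i, ] - off)
  }))
  expect_gt(max(line_scan(bundle, wide)) / kT, 50)
})

test_that("in-pore membership follows the cylinder geometry", {
  # 3-bead straw spanning the slab: only the mid bead is inside
  straw <- matrix(c(0, 0, -1, 0, 0, 4.26, 0, 0, 9.5), 3, 3, byrow = TRUE)
  expect_identical(in_pore_indices(straw, narrow), 2L)
  # off-axis beads inside the slab but outside the pore radius do not count
  expect_length(in_pore_indices(matrix(c(1.5, 0, 4), 1, 3), narrow), 0)
  expect_length(in_pore_indices(matrix(c(0, 0, -5), 1, 3), narrow), 0)
})

test_that("driving force splits equally and sums exactly", {
  f <- distribute_driving_force(50, 1:5, 10)
  expect_equal(unname(f[1:5, 3]), rep(10, 5))
  expect_equal(sum(f), 50, tolerance = 1e-12)
  expect_equal(sum(abs(f[, 1:2])), 0)
  # empty pore: no force at all
  expect_equal(sum(abs(distribute_driving_force(50, integer(0), 10))), 0)
  expect_error(distribute_driving_force(-1, 1:2, 5), "non-negative")
})

test_that("translocated count obeys its bookkeeping invariants", {
  ch <- straight_ladder(nd = 6, n_lead = 10)
  q0 <- count_translocated(ch, narrow)
  expect_equal(q0, 10) # the threaded lead
  # invariant under rigid translation perpendicular to the axis
  ch2 <- ch
  ch2$pos[, 1] <- ch2$pos[, 1] + 3.7
  ch2$pos[, 2] <- ch2$pos[, 2] - 1.2
  expect_equal(count_translocated(ch2, narrow), q0)
  # fully translocated chain counts every strand-A bead
  ch3 <- ch
  ch3$pos[, 3] <- ch3$pos[, 3] + 100
  expect_equal(count_translocated(ch3, narrow), 16)
  # fully cis chain counts none
  ch4 <- ch
  ch4$pos[, 3] <- ch4$pos[, 3] - 100
  expect_equal(count_translocated(ch4, narrow), 0)
})

test_that("pore constructor validates its geometry", {
  expect_error(slab_pore(0.5), "exceed steric_range")
  expect_error(slab_pore("narrow", slab_thickness = -1), "positive")
  expect_equal(slab_pore("wide")$nominal_diameter, 4.25)
  expect_equal(slab_pore("narrow")$slab_thickness, 8.52)
})
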