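test_that("KMT simplification reduces trivial shapes and preserves topology", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  poly <- cbind(cos(th), sin(th), 0)
  expect_lte(nrow(kmt_simplify(poly, closed = TRUE)), 3)
  line <- cbind(0, 0, seq(0, 24.5, by = 0.5))
  expect_equal(nrow(kmt_simplify(line)), 2)
  x <- parametric_knot("3_1", 200)
  red <- kmt_simplify(x, closed = TRUE)
  expect_lt(nrow(red), 30)
  expect_equal(classify_knot(red, closed = TRUE), "3_1")
  # determinants are invariant under the reduction
  expect_equal(alexander_determinants(x), alexander_determinants(red))
})

test_that("minimally interfering closure picks the right branch", {
  # endpoints adjacent in space but buried deep inside the hull of an
  # enclosing spherical coil: direct bridge
  th <- seq(0.15, pi - 0.15, length.out = 120)
  sp <- cbind(5 * sin(th) * cos(8 * th), 5 * sin(th) * sin(8 * th), 5 * cos(th))
  buried <- rbind(c(0, 0, 0.05), c(0, 0, 2.5), sp, c(0, 0, -2.5), c(0, 0, -0.05))
  expect_equal(attr(minimally_interfering_closure(buried), "closure"), "bridge")
  # endpoints on the hull surface of a C-shaped arc: outward closure whose
  # auxiliary arc crosses no chain segment
  th <- seq(-2.4, 2.4, length.out = 60)
  arc <- cbind(cos(th), sin(th), 0.02 * th)
  cl <- minimally_interfering_closure(arc)
  expect_equal(attr(cl, "closure"), "outward")
  n0 <- nrow(arc)
  segs_chain <- lapply(seq_len(n0 - 1), function(i) arc[i:(i + 1), ])
  aux <- rbind(cl[n0:nrow(cl), , drop = FALSE], cl[1, ])
  segs_aux <- lapply(seq_len(nrow(aux) - 1), function(i) aux[i:(i + 1), ])
  expect_false(segments_cross(segs_aux, segs_chain))
  # degenerate collinear input falls back to bridging without error
  line <- cbind(0, 0, seq(0, 5, by = 0.5))
  expect_equal(attr(minimally_interfering_closure(line), "closure"), "bridge")
})

test_that("closure classification is stable over random rigid rotations", {
  ks <- build_tight_knot("3_1")
  x <- ks$centerline
  set.seed(5)
  hits <- 0
  for (k in 1:100) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    R <- knotpore:::rot_about(u, runif(1, 0, 2 * pi))
    if (classify_knot(x %*% R) == "3_1") hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("Alexander determinants match the minimal-diagram oracle", {
  # oracle: Alexander matrix of the standard 3-crossing trefoil diagram,
  # built by hand (three generators; overpass of underpass k is generator
  # k+2 cyclically; all crossings share one sign)
  tref_det <- function(tval) {
    A <- matrix(0, 3, 3)
    for (k in 1:3) {
      k1 <- k %% 3 + 1
      i <- (k + 1) %% 3 + 1
      A[k, k] <- 1; A[k, k1] <- -tval; A[k, i] <- tval - 1
    }
    abs(det(A[-3, -3]))
  }
  expect_equal(tref_det(-1), 3)
  expect_equal(tref_det(-2), 7)
  expect_equal(alexander_determinants(parametric_knot("3_1", 200)), c(3L, 7L))
  # circle: unknot
  th <- seq(0, 2 * pi, length.out = 51)[-51]
  expect_equal(alexander_determinants(cbind(cos(th), sin(th), 0)), c(1L, 1L))
  # figure-eight
  expect_equal(alexander_determinants(parametric_knot("4_1", 240)), c(5L, 11L))
})

test_that("determinants are multiplicative under connected sum", {
  # granny: 3 x 3 and 7 x 7
  kg <- build_tight_knot("3_1#3_1")
  cl <- minimally_interfering_closure(kg$centerline)
  expect_equal(alexander_determinants(cl), c(9L, 49L))
  # trefoil # figure-eight: 3 x 5 and 7 x 11
  a <- knotpore:::orient_by_chord(knotpore:::scale_contour(
    parametric_knot("3_1", 60, open = TRUE), 30))
  b <- knotpore:::orient_by_chord(knotpore:::scale_contour(
    parametric_knot("4_1", 60, open = TRUE), 30))
  b <- sweep(b, 2, a[nrow(a), ] + c(0, 0, -2), `+`)
  comp <- rbind(a, b)
  expect_equal(alexander_determinants(minimally_interfering_closure(comp)),
               c(15L, 77L))
})

test_that("determinants are invariant under rigid motion, scale and reversal", {
  x <- parametric_knot("4_1", 200)
  d0 <- alexander_determinants(x)
  set.seed(8)
  for (k in 1:12) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    R <- knotpore:::rot_about(u, runif(1, 0, 2 * pi))
    y <- sweep(x %*% R * runif(1, 0.3, 5), 2, rnorm(3, sd = 10), `+`)
    expect_equal(alexander_determinants(y), d0)
  }
  expect_equal(alexander_determinants(x[rev(seq_len(nrow(x))), ]), d0)
})

test_that("classification labels the supported set and flags the rest", {
  expect_equal(classify_knot(parametric_knot("3_1", 150)), "3_1")
  expect_equal(classify_knot(parametric_knot("4_1", 150)), "4_1")
  expect_equal(classify_knot(cbind(0, 0, 1:20 / 2)), "0_1")
  # a 5-crossing torus knot (Solomon's seal) is outside the supported set
  tt <- seq(0, 2 * pi, length.out = 201)[-201]
  cinq <- cbind((2 + cos(5 * tt)) * cos(2 * tt),
                (2 + cos(5 * tt)) * sin(2 * tt), sin(5 * tt))
  expect_equal(classify_knot(cinq, closed = TRUE), "unknown")
})

test_that("bottom-up search localizes a planted knot to a few beads", {
  pk <- planted_knot_chain(n_before = 100, n_after = 450)
  arc <- shortest_knotted_arc(pk$chain, "3_1")
  expect_true(arc$found)
  expect_lte(abs(arc$k1 - pk$k1), 5)
  expect_lte(abs(arc$k2 - pk$k2), 5)
  # padding invariance: appending straight beads far away changes nothing
  pad <- cbind(0, 0, -(seq_len(100)) * 0.5)
  pad <- sweep(pad, 2, pk$chain[nrow(pk$chain), ], `+`)
  arc2 <- shortest_knotted_arc(rbind(pk$chain, pad), "3_1")
  expect_lte(abs(arc2$k1 - arc$k1), 2)
  expect_lte(abs(arc2$k2 - arc$k2), 2)
  # absent target: explicit not-found, no exception
  miss <- shortest_knotted_arc(cbind(0, 0, 1:80 / 2), "3_1")
  expect_false(miss$found)
})

test_that("composite decomposition returns ordered prime components", {
  kg <- build_tight_knot("3_1#3_1")
  comps <- decompose_composite(kg$centerline)
  expect_length(comps, 2)
  expect_equal(vapply(comps, `[[`, "", "label"), c("3_1", "3_1"))
  # non-overlapping, ordered by the pore-proximal end
  expect_lt(comps[[1]]$k2, comps[[2]]$k1)
  # each component is shorter than the full-knot arc
  whole <- shortest_knotted_arc(kg$centerline, "3_1#3_1")
  for (cmp in comps)
    expect_lt(cmp$k2 - cmp$k1, whole$k2 - whole$k1)
  # prime knot: one component; unknot: none
  k3 <- build_tight_knot("3_1")
  expect_length(decompose_composite(k3$centerline), 1)
  expect_length(decompose_composite(cbind(0, 0, 1:60 / 2)), 0)
})

test_that("crossing numbers map the supported set and reject others", {
  expect_identical(crossing_number_of_type("0_1"), 0L)
  expect_identical(crossing_number_of_type("3_1"), 3L)
  expect_identical(crossing_number_of_type("4_1"), 4L)
  expect_identical(crossing_number_of_type("3_1#3_1"), 6L)
  expect_error(crossing_number_of_type("5_1"), "unsupported")
})
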