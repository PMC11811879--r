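ff <- forcefield_params()
narrow <- slab_pore("narrow")

test_that("recipes validate their inputs", {
  expect_error(setup_recipe(n_bp = 30), "at least 40")
  expect_error(setup_recipe(knot_type = "5_1"))
  r <- setup_recipe()
  expect_equal(r$n_bp, 500L)
  expect_equal(r$lead_ss_bases, 40L)
  expect_equal(r$tight_core_target_bp, 50L)
})

test_that("equilibrated chains have the target stiffness and size statistics", {
  rec <- setup_recipe(n_bp = 100, seed = 2)
  chains <- lapply(1:30, function(k) sample_semiflexible_chain(rec, counter = k))
  # all samples are unknotted
  expect_true(all(vapply(chains, classify_knot, "") == "0_1"))
  # persistence length from the tangent-correlation decay
  lp <- fit_persistence_length(chains, rec$bond, max_lag = 30)
  expect_lt(abs(lp - rec$persistence_length) / rec$persistence_length, 0.1)
  # mean-square end-to-end distance against the worm-like-chain closed form
  L <- (rec$n_bp - 1) * rec$bond
  r2 <- mean(vapply(chains, function(x)
    sum((x[nrow(x), ] - x[1, ])^2), numeric(1)))
  r2_wlc <- knotpore:::wlc_r2(L, rec$persistence_length)
  expect_lt(abs(r2 - r2_wlc) / r2_wlc, 0.1)
})

test_that("tight knot construction hits its type and core-length target", {
  for (ty in c("3_1", "4_1")) {
    ks <- build_tight_knot(ty)
    expect_equal(classify_knot(ks$centerline), ty)
    arc <- shortest_knotted_arc(ks$centerline, ty)
    expect_lte(abs((arc$k2 - arc$k1 + 1) - 50), 10)
  }
  # the unknot adds nothing
  expect_null(build_tight_knot("0_1"))
  # deterministic construction
  expect_identical(build_tight_knot("3_1")$centerline,
                   build_tight_knot("3_1")$centerline)
})

test_that("granny lead decomposes into two like-typed prime components", {
  kg <- build_tight_knot("3_1#3_1")
  expect_equal(classify_knot(kg$centerline), "3_1#3_1")
  comps <- decompose_composite(kg$centerline)
  expect_length(comps, 2)
  expect_true(all(vapply(comps, `[[`, "", "label") == "3_1"))
})

test_that("assembly meets its full contract and is reproducible", {
  rec <- setup_recipe(n_bp = 50, knot_type = "3_1", seed = 1)
  cl <- sample_semiflexible_chain(rec)
  ks <- build_tight_knot(rec$knot_type, rec$tight_core_target_bp, rec$bond)
  st <- assemble_initial_state(cl, ks, narrow, rec, ff)
  expect_equal(count_translocated(st, narrow), rec$lead_ss_bases)
  expect_equal(classify_knot(knotpore:::strand_a_path(st)), "3_1")
  # knot core entirely on the cis side
  cis <- knotpore:::cis_centerline(st)
  expect_true(all(cis[, 3] < narrow$slab_z0 + 0.5))
  # no steric overlap above the hard minimum; finite energy
  expect_gte(knotpore:::min_nonbonded_distance(st), 0.9)
  expect_true(is.finite(chain_energy(st, ff, narrow)))
  # same seed, same coordinates
  st2 <- assemble_initial_state(sample_semiflexible_chain(rec), ks, narrow,
                                rec, ff)
  expect_identical(st$pos, st2$pos)
})

test_that("pinned relaxation loosens the core and preserves the topology", {
  rec <- setup_recipe(n_bp = 50, knot_type = "3_1", relax_duration = 12000,
                      seed = 1)
  cl <- sample_semiflexible_chain(rec)
  ks <- build_tight_knot(rec$knot_type, rec$tight_core_target_bp, rec$bond)
  st <- assemble_initial_state(cl, ks, narrow, rec, ff)
  a0 <- shortest_knotted_arc(knotpore:::strand_a_path(st), "3_1")
  re <- relax_pinned(st, ff, narrow, rec$relax_duration, seed = 3)
  expect_equal(classify_knot(knotpore:::strand_a_path(re)), "3_1")
  a1 <- shortest_knotted_arc(knotpore:::strand_a_path(re), "3_1")
  expect_gt(a1$k2 - a1$k1, a0$k2 - a0$k1)
})
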