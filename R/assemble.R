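#' Recipe for building an initial study state
#'
#' Collects every choice that defines one synthetic starting configuration:
#' the equilibrated chain length, the knot type of the tight lead, the
#' threaded single-stranded lead, and the Monte Carlo / relaxation controls.
#'
#' @param n_bp length of the main equilibrated duplex, base pairs (>= 40).
#' @param knot_type `"0_1"`, `"3_1"`, `"4_1"` or `"3_1#3_1"`.
#' @param lead_ss_bases length of the single-stranded lead pre-threaded
#'   through the pore (the translocated count starts here).
#' @param tight_core_target_bp target core length of the constructed tight
#'   knot, bp.
#' @param bond bead spacing, nm.
#' @param persistence_length target duplex persistence length, nm.
#' @param hard_core hard-core diameter of the centreline during Monte Carlo
#'   sampling, nm (effective dsDNA diameter at high salt).
#' @param mc_sweeps Monte Carlo sweeps per equilibration block (`NULL` =
#'   automatic).
#' @param relax_duration steps of pinned Langevin relaxation.
#' @param seed study seed; all stage seeds are derived from it.
#' @return object of class `"setup_recipe"`.
#' @export
setup_recipe <- function(n_bp = 500, knot_type = c("0_1", "3_1", "4_1", "3_1#3_1"),
                         lead_ss_bases = 40, tight_core_target_bp = 50,
                         bond = 0.5, persistence_length = 50, hard_core = 2.4,
                         mc_sweeps = NULL, relax_duration = 20000, seed = 1) {
  knot_type <- match.arg(knot_type)
  if (n_bp < 40) stop("n_bp must be at least 40")
  structure(list(n_bp = as.integer(n_bp), knot_type = knot_type,
                 lead_ss_bases = as.integer(lead_ss_bases),
                 tight_core_target_bp = as.integer(tight_core_target_bp),
                 bond = bond, persistence_length = persistence_length,
                 hard_core = hard_core, mc_sweeps = mc_sweeps,
                 relax_duration = as.integer(relax_duration), seed = seed),
            class = "setup_recipe")
}

# align an open polyline so its first segment points along `tangent` and its
# first vertex sits at `origin`
align_polyline <- function(x, origin, tangent) {
  x <- sweep(x, 2, x[1, ])
  t1 <- x[2, ] - x[1, ]
  t1 <- t1 / sqrt(sum(t1^2))
  tangent <- tangent / sqrt(sum(tangent^2))
  ax <- c(t1[2] * tangent[3] - t1[3] * tangent[2],
          t1[3] * tangent[1] - t1[1] * tangent[3],
          t1[1] * tangent[2] - t1[2] * tangent[1])
  na <- sqrt(sum(ax^2))
  if (na > 1e-9) {
    th <- acos(max(-1, min(1, sum(t1 * tangent))))
    x <- x %*% t(rot_about(ax / na, th))
  } else if (sum(t1 * tangent) < 0) {
    perp <- if (abs(tangent[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * tangent) * tangent
    x <- x %*% t(rot_about(perp / sqrt(sum(perp^2)), pi))
  }
  sweep(x, 2, origin, `+`)
}

#' Assemble the threaded initial state
#'
#' Splices the single-stranded lead (threaded along the pore axis with its
#' tip on the trans side), the tight knotted segment (at the cis pore mouth)
#' and the equilibrated chain into one duplex centreline, builds the two
#' strands by parallel transport at the pairing separation, and verifies the
#' assembly contract: translocated count equal to the lead length, knot
#' entirely on the cis side, correct topology, and no steric overlap above
#' the hard minimum (gentle gradient-descent declash plus deterministic
#' re-orientation retries).
#'
#' @param chain n_bp x 3 equilibrated centreline
#'   ([sample_semiflexible_chain()]).
#' @param knot_segment a `knot_segment` from [build_tight_knot()], or `NULL`
#'   for the unknotted case.
#' @param pore a `slab_pore`.
#' @param recipe the `setup_recipe`.
#' @param forcefield a `forcefield_params`.
#' @param hard_min smallest allowed non-bonded bead separation, nm (default
#'   just inside the excluded-volume diameter, so residual contacts carry
#'   only modest energy).
#' @return a threaded `duplex_chain`.
#' @export
assemble_initial_state <- function(chain, knot_segment, pore, recipe,
                                   forcefield, hard_min = 0.9) {
  b <- recipe$bond
  nl <- recipe$lead_ss_bases
  z0 <- pore$slab_z0
  if ((nl - 1) * b + b / 2 <= pore$slab_thickness)
    stop("ss lead too short to span the pore")
  half_sep <- forcefield$pair_r0 / 2

  lead <- cbind(0, 0, z0 + b / 2 + (nl - seq_len(nl)) * b)

  kcl <- if (is.null(knot_segment)) NULL else orient_by_chord(knot_segment$centerline)
  rise <- if (is.null(kcl)) 0 else max(kcl[, 3]) - kcl[1, 3]
  n_stem <- max(3, ceiling((0.8 + rise) / b) + 1)
  stem <- cbind(-half_sep, 0, z0 - b / 2 - (seq_len(n_stem) - 1) * b)

  parts <- stem
  if (!is.null(kcl)) {
    entry <- stem[n_stem, ] - c(0, 0, b)
    kcl <- sweep(kcl, 2, entry, `+`)
    parts <- rbind(parts, kcl)
  }

  # attach the equilibrated chain, re-orienting it (deterministically) until
  # it stays clear of the slab
  t_exit <- parts[nrow(parts), ] - parts[nrow(parts) - 1, ]
  if (sqrt(sum(t_exit^2)) < 1e-9) t_exit <- c(0, 0, -1)
  t_exit <- t_exit / sqrt(sum(t_exit^2))
  origin <- parts[nrow(parts), ] + b * t_exit
  # try the exit tangent first, then spin the chain and progressively tilt
  # the attachment direction toward -z until the coil clears the slab (the
  # junction kink this may introduce relaxes away in the pinned stage)
  placed <- NULL
  best <- NULL
  golden <- pi * (3 - sqrt(5))
  for (k in 0:79) {
    w <- min(1, (k %/% 8) / 6)
    dir <- (1 - w) * t_exit + w * c(0, 0, -1)
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-6) dir <- c(0, 0, -1) else dir <- dir / nd
    cand <- if (k > 0) chain %*% t(rot_about(c(0, 0, 1), golden * k)) else chain
    cand <- align_polyline(cand, origin, dir)
    if (max(cand[, 3]) < z0 - 0.5) { placed <- cand; break }
    if (is.null(best) || max(cand[, 3]) < max(best[, 3])) best <- cand
  }
  if (is.null(placed)) {
    # no orientation clears the slab (large coils usually rise above their
    # attachment point): descend a straight duplex spacer deep enough that
    # the best orientation fits below the cis face
    need <- max(best[, 3]) - (z0 - 0.6)
    n_extra <- ceiling(need / b) + 2
    pe <- parts[nrow(parts), ]
    spacer <- cbind(pe[1], pe[2], pe[3] - seq_len(n_extra) * b)
    parts <- rbind(parts, spacer)
    origin2 <- parts[nrow(parts), ] - c(0, 0, b)
    # translate (no rotation: the rise is measured in this orientation)
    placed <- sweep(best, 2, origin2 - best[1, ], `+`)
    if (max(placed[, 3]) >= z0 - 0.5)
      stop("could not place the cis chain clear of the slab")
  }
  parts <- rbind(parts, placed)

  cl <- resample_polyline(parts, b)
  if (max(cl[, 3]) > z0 - 0.2)
    stop("assembled centreline intrudes into the slab region")
  st <- duplex_strands_from_centerline(cl, half_sep)
  pos <- rbind(lead, st$A, st$B)
  strand <- c(rep("lead", nl), rep("A", nrow(cl)), rep("B", nrow(cl)))
  obj <- duplex_chain(pos, strand, n_bp = recipe$n_bp,
                      meta = list(knot_type = recipe$knot_type,
                                  recipe = recipe, n_stem = n_stem))

  obj <- declash(obj, forcefield, pore, hard_min)

  q <- count_translocated(obj, pore)
  if (q != nl)
    stop(sprintf("assembly contract violated: Q = %d, expected %d", q, nl))
  cis <- cis_centerline(obj)
  if (any(cis[, 3] > z0 + 0.5))
    stop("knotted duplex not confined to the cis side at assembly")
  lab <- classify_knot(strand_a_path(obj))
  if (lab != recipe$knot_type)
    stop(sprintf("assembled topology %s does not match recipe %s",
                 lab, recipe$knot_type))
  obj
}

# gentle overlap resolution: short gradient descent on the excluded-volume
# and wall terms only, with a capped per-iteration displacement
declash <- function(chain, ff, pore, hard_min, max_iter = 2000) {
  for (it in seq_len(max_iter)) {
    if (min_nonbonded_distance(chain) >= hard_min) return(chain)
    f <- nonbonded_forces(chain, ff)$forces
    if (!is.null(pore)) f <- f + confinement_forces(chain, pore)$forces
    fn <- sqrt(rowSums(f^2))
    stepv <- f * (pmin(fn, 50) / pmax(fn, 1e-12)) * 4e-4
    chain$pos <- chain$pos + stepv
  }
  d <- min_nonbonded_distance(chain)
  if (d < hard_min)
    stop(sprintf("overlap resolution failed: min distance %.3f < %.3f after %d iterations",
                 d, hard_min, max_iter))
  chain
}

#' Pinned relaxation of an assembled state
#'
#' Short Langevin relaxation with one in-pore lead nucleotide held fixed and
#' no driving force.  The initially tight knotted core loosens to lower its
#' bending energy; the knot type must be preserved (a change is a hard
#' failure).
#'
#' @param state assembled `duplex_chain`.
#' @param forcefield a `forcefield_params`.
#' @param pore a `slab_pore`.
#' @param relax_duration number of steps (default from the recipe carried in
#'   the state's metadata, else 4000).
#' @param seed seed for the relaxation noise stream.
#' @return the relaxed `duplex_chain`.
#' @export
relax_pinned <- function(state, forcefield, pore, relax_duration = NULL,
                         seed = 1) {
  if (is.null(relax_duration)) {
    relax_duration <- if (!is.null(state$meta$recipe))
      state$meta$recipe$relax_duration else 4000
  }
  inp <- in_pore_indices(state, pore)
  inp <- inp[state$strand[inp] == "lead"]
  if (length(inp) == 0) stop("no lead bead inside the pore to pin")
  zc <- pore$slab_z0 + pore$slab_thickness / 2
  pin <- inp[which.min(abs(state$pos[inp, 3] - zc))]
  before <- classify_knot(strand_a_path(state))
  # athermal quench at a reduced timestep first: the spliced construction
  # carries bond/bend kinks whose forces would otherwise kick the thermal run
  ff0 <- forcefield
  ff0$temperature <- 0
  quench <- run_protocol("pinned", pinned_bead = pin,
                         duration = 2000, timestep = 0.0005, gamma = 20,
                         seed = seed, snapshot_stride = 2000L,
                         terminate_on_complete = FALSE)
  state <- run_pinned(state, ff0, pore, quench)$chain
  state$vel[] <- 0
  prot <- run_protocol("pinned", pinned_bead = pin,
                       duration = relax_duration, seed = seed,
                       snapshot_stride = max(1L, as.integer(relax_duration)),
                       terminate_on_complete = FALSE)
  traj <- run_pinned(state, forcefield, pore, prot)
  out <- traj$chain
  after <- classify_knot(strand_a_path(out))
  if (!identical(before, after))
    stop(sprintf("topology changed during relaxation: %s -> %s", before, after))
  out
}

#' Build a complete initial state from a recipe
#'
#' Convenience pipeline: sample the equilibrated chain, construct the tight
#' knotted lead, assemble the threaded state, and (optionally) relax it with
#' a pinned nucleotide.
#'
#' @param recipe a `setup_recipe`.
#' @param forcefield a `forcefield_params`.
#' @param pore a `slab_pore`.
#' @param relax run the pinned relaxation stage?
#' @param chain_counter stream counter for the chain sample (replicates).
#' @return a threaded (optionally relaxed) `duplex_chain`.
#' @export
prepare_initial_state <- function(recipe, forcefield = forcefield_params(),
                                  pore = slab_pore("narrow"), relax = TRUE,
                                  chain_counter = 0) {
  cl <- sample_semiflexible_chain(recipe, counter = chain_counter)
  ks <- build_tight_knot(recipe$knot_type, recipe$tight_core_target_bp,
                         recipe$bond)
  st <- assemble_initial_state(cl, ks, pore, recipe, forcefield)
  if (relax)
    st <- relax_pinned(st, forcefield, pore, recipe$relax_duration,
                       seed = kp_seed(recipe$seed, "relax", chain_counter))
  st
}
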