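#' Bonded forces and energy
#'
#' Harmonic backbone bonds plus Kratky-Porod bending on each strand.  Forces
#' are the exact negative gradient of the declared energy and sum to zero
#' over all beads.
#'
#' @param chain a `duplex_chain`.
#' @param params a `forcefield_params`.
#' @return list with `forces` (n x 3, pN) and `energy` (pN nm).
#' @export
bonded_forces <- function(chain, params) {
  validate_chain(chain)
  kappa <- ifelse(chain$angle_ss, params$bend_kappa_ss, params$bend_kappa)
  res <- cpp_bonded_forces(chain$pos, chain$bonds - 1L, params$bond_k,
                           params$bond_r0, chain$angles - 1L, as.numeric(kappa))
  res
}

#' Base-pairing forces, energy and updated pairing state
#'
#' Intact pairs interact through a finite-range Morse well; a pair stretched
#' beyond `pair_break_cutoff` is flagged broken and contributes nothing
#' afterwards (re-formation only if enabled in the force field).
#'
#' @inheritParams bonded_forces
#' @return list with `forces`, `energy`, and `chain` carrying the updated
#'   `pair_state`.
#' @export
pairing_forces <- function(chain, params) {
  validate_chain(chain)
  res <- cpp_pairing_forces(chain$pos, chain$pair_a - 1L, chain$pair_b - 1L,
                            chain$pair_state, params$pair_depth, params$pair_r0,
                            params$pair_a, params$pair_break_cutoff,
                            params$pair_perp, params$pair_reform)
  chain$pair_state <- as.logical(res$state)
  list(forces = res$forces, energy = res$energy, chain = chain)
}

#' Non-bonded forces: excluded volume and screened electrostatics
#'
#' WCA (purely repulsive) excluded volume plus a shifted-force Debye-Hueckel
#' repulsion truncated at `dh_cutoff`.  Bonded first neighbours and paired
#' beads are excluded.
#'
#' @inheritParams bonded_forces
#' @param pore optional `slab_pore`; accepted for interface symmetry with the
#'   other force terms (the wall itself is handled by
#'   [confinement_forces()]).
#' @return list with `forces` and `energy`.
#' @export
nonbonded_forces <- function(chain, params, pore = NULL) {
  validate_chain(chain)
  ex <- nb_exclusions(chain)
  cpp_nonbonded_forces(chain$pos, ex[, 1] - 1L, ex[, 2] - 1L, params$ev_sigma,
                       params$ev_epsilon, params$debye_prefactor,
                       params$debye_length, params$dh_cutoff)
}

#' Total potential energy of a chain
#'
#' Sum of bonded, pairing, non-bonded and (if a pore is given) confinement
#' terms, without altering the pairing state.
#'
#' @inheritParams nonbonded_forces
#' @return scalar energy in pN nm.
#' @export
chain_energy <- function(chain, params, pore = NULL) {
  e <- bonded_forces(chain, params)$energy +
    cpp_pairing_forces(chain$pos, chain$pair_a - 1L, chain$pair_b - 1L,
                       chain$pair_state, params$pair_depth, params$pair_r0,
                       params$pair_a, params$pair_break_cutoff,
                       params$pair_perp, FALSE)$energy +
    nonbonded_forces(chain, params)$energy
  if (!is.null(pore))
    e <- e + confinement_forces(chain, pore)$energy
  e
}
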