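#' Force-field parameters for the two-strand ladder model
#'
#' Collects and validates the parameters of the simplified coarse-grained
#' dsDNA model: harmonic backbone bonds, Kratky-Porod bending on each strand
#' (with a softer constant on the single-stranded lead), breakable Morse base
#' pairing, WCA excluded volume, and a screened Debye-Hueckel repulsion whose
#' decay length corresponds to 1 M monovalent salt by default.
#'
#' Defaults place one bead per nucleotide per strand at `bond_r0 = 0.5` nm
#' rise with `bend_kappa` tuned so the duplex persistence length is about
#' 50 nm (each strand contributes roughly `bend_kappa * bond_r0 / kT`).
#' The pairing depth is set so the unzipping threshold separates a low-force
#' regime (knot effects negligible) from a high-force regime (strong
#' topological friction) at the model's scale; see `calibrate_forces()`.
#'
#' @param bond_k backbone bond stiffness, pN/nm.
#' @param bond_r0 backbone bond rest length (rise per nucleotide), nm.
#' @param bend_kappa Kratky-Porod bending constant on duplex strands, pN nm.
#' @param bend_kappa_ss bending constant on the single-stranded lead, pN nm.
#' @param pair_depth depth of the Morse base-pairing well, pN nm.
#' @param pair_r0 rest separation of a base pair (inter-strand), nm; with
#'   `ev_sigma` = 1 nm this gives the duplex its B-DNA-like 2 nm diameter.
#' @param pair_a Morse inverse width, 1/nm.
#' @param pair_break_cutoff separation beyond which a pair is flagged broken
#'   and stops contributing, nm; must exceed `pair_r0` (default 1.5 pair_r0).
#' @param pair_perp strength of the pairing orientation term
#'   `pair_perp * (u.t)^2` penalizing alignment of the pair vector u with
#'   the local strand tangent t, pN nm.  Base pairs are lateral to the
#'   backbone; without this term a ladder duplex could thread the narrow
#'   pore in single file without unzipping.
#' @param pair_reform logical; may broken pairs re-form when the beads
#'   re-approach below `pair_r0`? Off by default (unzipping is effectively
#'   irreversible at the studied forces).
#' @param ev_sigma WCA excluded-volume diameter, nm.
#' @param ev_epsilon WCA energy scale, pN nm.
#' @param debye_length Debye screening length, nm (about 0.3 nm at 1 M NaCl).
#' @param debye_prefactor electrostatic prefactor, pN nm^2.
#' @param temperature thermal energy kT, pN nm.
#' @param mass bead mass (defines the time unit).
#' @return An object of class `"forcefield_params"` (a validated named list,
#'   including the derived `dh_cutoff = 2.5 * debye_length`).
#' @examples
#' ff <- forcefield_params()
#' ff$pair_break_cutoff > ff$pair_r0
#' @export
forcefield_params <- function(bond_k = 800, bond_r0 = 0.5,
                              bend_kappa = 200, bend_kappa_ss = 8,
                              pair_depth = 30, pair_r0 = 1, pair_a = 3,
                              pair_break_cutoff = 1.5 * pair_r0,
                              pair_perp = 60, pair_reform = FALSE,
                              ev_sigma = 1, ev_epsilon = 4.1,
                              debye_length = 0.3, debye_prefactor = 1,
                              temperature = 4.1, mass = 1) {
  p <- list(bond_k = bond_k, bond_r0 = bond_r0,
            bend_kappa = bend_kappa, bend_kappa_ss = bend_kappa_ss,
            pair_depth = pair_depth, pair_r0 = pair_r0, pair_a = pair_a,
            pair_break_cutoff = pair_break_cutoff, pair_perp = pair_perp,
            pair_reform = isTRUE(pair_reform),
            ev_sigma = ev_sigma, ev_epsilon = ev_epsilon,
            debye_length = debye_length, debye_prefactor = debye_prefactor,
            dh_cutoff = 2.5 * debye_length,
            temperature = temperature, mass = mass)
  num <- p[setdiff(names(p), "pair_reform")]
  bad <- names(num)[!vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                              is.finite(x), logical(1))]
  if (length(bad))
    stop("forcefield parameter not a finite scalar: ", paste(bad, collapse = ", "))
  pos <- setdiff(names(num), c("temperature", "debye_prefactor", "pair_perp"))
  neg <- pos[vapply(num[pos], function(x) x <= 0, logical(1))]
  if (length(neg))
    stop("forcefield parameter must be positive: ", paste(neg, collapse = ", "))
  if (p$temperature < 0) stop("temperature must be >= 0")
  if (p$debye_prefactor < 0) stop("debye_prefactor must be >= 0")
  if (p$pair_break_cutoff <= p$pair_r0)
    stop("pair_break_cutoff must exceed pair_r0")
  structure(p, class = "forcefield_params")
}

#' @export
print.forcefield_params <- function(x, ...) {
  cat("<forcefield_params>\n")
  cat(sprintf("  backbone: k = %g pN/nm, r0 = %g nm\n", x$bond_k, x$bond_r0))
  cat(sprintf("  bending:  kappa = %g (duplex), %g (ss lead) pN nm\n",
              x$bend_kappa, x$bend_kappa_ss))
  cat(sprintf("  pairing:  Morse depth %g pN nm, r0 = %g nm, break at %g nm%s\n",
              x$pair_depth, x$pair_r0, x$pair_break_cutoff,
              if (x$pair_reform) " (re-formation on)" else ""))
  cat(sprintf("  WCA sigma = %g nm, eps = %g; DH lambda = %g nm (cut %g)\n",
              x$ev_sigma, x$ev_epsilon, x$debye_length, x$dh_cutoff))
  cat(sprintf("  kT = %g pN nm, mass = %g\n", x$temperature, x$mass))
  invisible(x)
}

# stiffest curvature among declared terms, used by the timestep heuristic
kp_stiffness <- function(ff, pore = NULL) {
  morse <- 2 * ff$pair_depth * ff$pair_a^2
  wca <- 60 * ff$ev_epsilon / ff$ev_sigma^2 # curvature scale near the cutoff
  k <- max(ff$bond_k, morse, wca)
  if (!is.null(pore)) k <- max(k, pore$wall_k)
  k
}
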