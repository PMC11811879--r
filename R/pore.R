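#' Slab-embedded cylindrical pore
#'
#' Geometry of the confining slab with an embedded cylindrical pore along the
#' +z axis.  The cis face sits at `slab_z0` (default 0) and the trans face at
#' `slab_z0 + slab_thickness`.  The wall potential is a smoothed quadratic
#' ramp with range `steric_range / 2 + bead_contact` on bead centres (the
#' bead surface sees the wall at `steric_range / 2`), so the net open pore
#' diameter is `nominal_diameter - steric_range` -- about 1 nm for the
#' narrow default, which admits a single DNA strand (1 nm wide, with a mild
#' squeeze) and blocks a duplex, forcing translocating duplexes to unzip.
#'
#' @param nominal_diameter pore diameter in nm, or one of `"narrow"`
#'   (1.87 nm, single strand passes: unzipping mode) / `"wide"` (4.25 nm,
#'   a duplex passes but a knot does not).
#' @param slab_thickness pore length (slab thickness), nm.
#' @param steric_range steric repulsion range of the slab material, nm.
#' @param slab_z0 z coordinate of the cis face, nm.
#' @param wall_k stiffness of the quadratic wall ramp, pN/nm.
#' @param bead_contact bead radius added to the wall interaction range, nm,
#'   so the wall repels the bead surface rather than its centre.
#' @return object of class `"slab_pore"`.
#' @examples
#' slab_pore("narrow")
#' @export
slab_pore <- function(nominal_diameter = c("narrow", "wide"),
                      slab_thickness = 8.52, steric_range = 0.95,
                      slab_z0 = 0, wall_k = 2000, bead_contact = 0.5) {
  if (is.character(nominal_diameter)) {
    nominal_diameter <- switch(match.arg(nominal_diameter),
                               narrow = 1.87, wide = 4.25)
  }
  if (slab_thickness <= 0) stop("slab_thickness must be positive")
  if (steric_range <= 0) stop("steric_range must be positive")
  if (nominal_diameter <= steric_range)
    stop("nominal_diameter must exceed steric_range (net diameter would close)")
  structure(list(nominal_diameter = nominal_diameter,
                 slab_thickness = slab_thickness,
                 steric_range = steric_range,
                 slab_z0 = slab_z0, wall_k = wall_k,
                 bead_contact = bead_contact,
                 axis = c(0, 0, 1)),
            class = "slab_pore")
}

#' @export
print.slab_pore <- function(x, ...) {
  cat(sprintf("<slab_pore> diameter %.2f nm (net %.2f), slab %.2f nm, cis face z = %g\n",
              x$nominal_diameter, x$nominal_diameter - x$steric_range,
              x$slab_thickness, x$slab_z0))
  invisible(x)
}

# is this pore in single-strand (unzipping) mode?
is_narrow <- function(pore) pore$nominal_diameter < 2.5

pos_of <- function(chain) if (is.matrix(chain)) chain else chain$pos

#' Confinement forces from the slab and pore walls
#'
#' Zero beyond `steric_range/2` from the slab material; inside the ramp the
#' force is normal to the nearest slab or pore surface; beads on the pore
#' axis feel zero radial force by convention.  Finite everywhere (the ramp
#' continues linearly inside the material).
#'
#' @param chain a `duplex_chain` or a bare n x 3 coordinate matrix.
#' @param pore a `slab_pore`.
#' @return list with `forces` and `energy`.
#' @export
confinement_forces <- function(chain, pore) {
  cpp_confinement_forces(pos_of(chain), pore$slab_z0, pore$slab_thickness,
                         pore$nominal_diameter / 2,
                         pore$steric_range / 2 + pore$bead_contact,
                         pore$wall_k)
}

#' Beads currently inside the pore
#'
#' Indices (ordered) of beads whose axial coordinate lies within the slab and
#' whose radial distance from the axis is below the nominal pore radius.
#' These are the beads across which the driving force is split.
#'
#' @inheritParams confinement_forces
#' @return integer vector of bead indices (possibly empty).
#' @export
in_pore_indices <- function(chain, pore) {
  pos <- pos_of(chain)
  z <- pos[, 3]
  rho2 <- pos[, 1]^2 + pos[, 2]^2
  which(z >= pore$slab_z0 & z <= pore$slab_z0 + pore$slab_thickness &
          rho2 < (pore$nominal_diameter / 2)^2)
}

#' Equal split of the driving force over in-pore beads
#'
#' Each listed bead receives `total_force / length(indices)` along the pore
#' axis, so the applied total is constant while the pore occupancy
#' fluctuates.  With no bead in the pore, no force is applied.
#'
#' @param total_force total longitudinal driving force, pN (non-negative).
#' @param indices bead indices inside the pore.
#' @param n_beads total number of beads (rows of the returned matrix).
#' @return n_beads x 3 matrix of per-bead applied forces.
#' @export
distribute_driving_force <- function(total_force, indices, n_beads) {
  if (total_force < 0) stop("total_force must be non-negative")
  f <- matrix(0, n_beads, 3)
  if (length(indices) > 0 && total_force > 0)
    f[indices, 3] <- total_force / length(indices)
  f
}

#' Number of translocated nucleotides
#'
#' Counts strand-A (including ss-lead) beads whose axial coordinate is past
#' the cis face, i.e. nucleotides that have entered or passed the pore and
#' are thus unzipped from the cis duplex.  With the standard 40-base threaded
#' lead the count starts at 40.
#'
#' @inheritParams confinement_forces
#' @return integer Q, in `[0, number of strand-A beads]`.
#' @export
count_translocated <- function(chain, pore) {
  if (is.matrix(chain)) stop("count_translocated needs a duplex_chain (strand labels)")
  a <- chain$strand %in% c("lead", "A")
  sum(chain$pos[a, 3] > pore$slab_z0)
}
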