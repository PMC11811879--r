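#' Duplex chain container
#'
#' A `duplex_chain` holds the bead coordinates and bonded topology of one
#' dsDNA filament in the ladder representation: strand A carries the
#' single-stranded lead (the segment pre-threaded through the pore) followed
#' by the duplex nucleotides; strand B is the complementary strand, paired
#' bead-by-bead with the duplex part of strand A through a breakable pairing
#' map.  Bead order is: lead (1..n_lead), strand-A duplex (n_lead+1 ..
#' n_lead+n_duplex), strand-B duplex (rest), with strand-B bead j paired to
#' strand-A duplex bead j.
#'
#' @param positions numeric matrix (n x 3), bead coordinates in nm.
#' @param strand character vector of per-bead labels: `"lead"`, `"A"`, `"B"`.
#' @param velocities optional numeric matrix (n x 3); zero if omitted.
#' @param n_bp length in base pairs of the main equilibrated chain (metadata;
#'   the duplex may additionally contain a knotted lead segment).
#' @param pair_state optional logical vector, one per base pair; `TRUE` =
#'   intact.  All intact if omitted.
#' @param meta optional list of free-form metadata.
#' @return An object of class `"duplex_chain"` with components `pos`, `vel`,
#'   `strand`, `bonds` (2-column matrix of backbone bonds), `angles`
#'   (3-column matrix with logical attribute `ss` marking lead-centred
#'   angles), `pair_a`, `pair_b`, `pair_state`, `n_lead`, `n_duplex`, `n_bp`.
#' @export
duplex_chain <- function(positions, strand, velocities = NULL, n_bp = NULL,
                         pair_state = NULL, meta = list()) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  strand <- as.character(strand)
  if (length(strand) != n) stop("strand must have one label per bead")
  if (!all(strand %in% c("lead", "A", "B"))) stop("strand labels must be lead/A/B")
  n_lead <- sum(strand == "lead")
  nA <- sum(strand == "A")
  nB <- sum(strand == "B")
  if (nB != nA) stop("strand B must have one bead per strand-A duplex bead")
  if (n_lead > 0 && !all(strand[seq_len(n_lead)] == "lead"))
    stop("lead beads must come first")
  if (!all(strand[n_lead + seq_len(nA)] == "A"))
    stop("strand-A duplex beads must follow the lead")
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)

  nd <- nA
  # backbone: one path lead+A, one path B
  iA <- seq_len(n_lead + nd)
  iB <- n_lead + nd + seq_len(nd)
  bonds <- rbind(cbind(head(iA, -1), tail(iA, -1)),
                 if (nd > 1) cbind(head(iB, -1), tail(iB, -1)))
  angles <- rbind(
    if (length(iA) > 2) cbind(head(iA, -2), iA[-c(1, length(iA))], tail(iA, -2)),
    if (nd > 2) cbind(head(iB, -2), iB[-c(1, length(iB))], tail(iB, -2)))
  if (is.null(angles)) angles <- matrix(integer(0), 0, 3)
  # an angle bends softly if its centre bead is on the ss lead or at the junction
  ss <- n_lead > 0 & angles[, 2] <= (n_lead + 1L)
  if (is.null(pair_state)) pair_state <- rep(TRUE, nd)
  obj <- structure(list(
    pos = positions, vel = velocities, strand = strand,
    bonds = bonds, angles = angles, angle_ss = ss,
    pair_a = n_lead + seq_len(nd), pair_b = iB,
    pair_state = as.logical(pair_state),
    n_lead = n_lead, n_duplex = nd,
    n_bp = if (is.null(n_bp)) nd else n_bp,
    meta = meta), class = "duplex_chain")
  validate_chain(obj)
  obj
}

#' Validate a duplex chain
#'
#' Checks the structural invariants: finite coordinates, backbone bonds
#' forming two simple paths (lead+strand A, strand B), and a symmetric
#' one-to-one pairing map between the strands.
#'
#' @param chain a `duplex_chain`.
#' @param hard_min optional minimum allowed bead-bead distance; when given,
#'   the closest non-bonded approach is checked against it.
#' @return The chain, invisibly; errors describe the first violation.
#' @export
validate_chain <- function(chain, hard_min = NULL) {
  pos <- chain$pos
  bad <- which(!apply(is.finite(pos), 1, all))
  if (length(bad))
    stop("non-finite coordinates at bead ", bad[1])
  n <- nrow(pos)
  if (length(chain$pair_a) != length(chain$pair_b) ||
      length(chain$pair_a) != length(chain$pair_state))
    stop("pairing map and state lengths disagree")
  if (any(chain$strand[chain$pair_a] != "A") ||
      any(chain$strand[chain$pair_b] != "B"))
    stop("pairing map inconsistent with strand labels")
  if (anyDuplicated(chain$pair_a) || anyDuplicated(chain$pair_b))
    stop("pairing map is not one-to-one")
  # two simple paths: every bead degree <= 2, edge count = n - 2 components
  deg <- tabulate(c(chain$bonds), nbins = n)
  if (any(deg > 2)) stop("backbone bonds do not form simple paths")
  ncomp <- if (chain$n_duplex > 0) 2L else 1L
  if (nrow(chain$bonds) != n - ncomp)
    stop("backbone bonds must form exactly ", ncomp, " path(s)")
  if (!is.null(hard_min)) {
    d <- min_nonbonded_distance(chain)
    if (d < hard_min)
      stop(sprintf("bead overlap: min non-bonded distance %.3f < %.3f", d, hard_min))
  }
  invisible(chain)
}

# non-bonded exclusion pairs: the bonded ladder scaffold -- backbone (1-2)
# and next-nearest (1-3) neighbours along each path, pairing partners, and
# the cross-strand nearest neighbours A_i - B_{i+-1} (held at fixed geometry
# by the bond + pairing network, like 1-3 contacts)
nb_exclusions <- function(chain) {
  iA <- seq_len(chain$n_lead + chain$n_duplex)
  iB <- chain$n_lead + chain$n_duplex + seq_len(chain$n_duplex)
  ex13 <- rbind(
    if (length(iA) > 2) cbind(head(iA, -2), tail(iA, -2)),
    if (length(iB) > 2) cbind(head(iB, -2), tail(iB, -2)))
  nd <- chain$n_duplex
  cross <- if (nd > 1) rbind(cbind(chain$pair_a[-nd], chain$pair_b[-1]),
                             cbind(chain$pair_a[-1], chain$pair_b[-nd]))
  rbind(chain$bonds, ex13, cross, cbind(chain$pair_a, chain$pair_b))
}

# closest approach over non-bonded bead pairs (brute force; setup-time check)
min_nonbonded_distance <- function(chain) {
  pos <- chain$pos
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  ex <- nb_exclusions(chain)
  d[ex] <- Inf
  d[ex[, 2:1, drop = FALSE]] <- Inf
  diag(d) <- Inf
  min(d)
}

#' @export
print.duplex_chain <- function(x, ...) {
  cat(sprintf("<duplex_chain> %d beads: %d ss-lead + 2 x %d duplex (n_bp = %d)\n",
              nrow(x$pos), x$n_lead, x$n_duplex, x$n_bp))
  cat(sprintf("  intact pairs: %d / %d\n", sum(x$pair_state), length(x$pair_state)))
  if (!is.null(x$meta$knot_type))
    cat(sprintf("  knot type: %s\n", x$meta$knot_type))
  invisible(x)
}

# full strand-A path (ss lead + duplex strand A): the polyline on which knot
# detection and boundary tracking run, so reported bounds are nucleotide
# indices directly comparable with the translocated count
strand_a_path <- function(chain) {
  chain$pos[chain$strand %in% c("lead", "A"), , drop = FALSE]
}

# duplex centreline of the still-paired region (midpoints of pairs from the
# first to the last intact pair); used by the cis-side geometry checks.
# Returns the matrix with attribute "offset": nucleotide index of row 1 - 1.
cis_centerline <- function(chain) {
  intact <- which(chain$pair_state)
  if (length(intact) < 3) return(NULL)
  rng <- seq(min(intact), max(intact))
  a <- chain$pos[chain$pair_a[rng], , drop = FALSE]
  b <- chain$pos[chain$pair_b[rng], , drop = FALSE]
  cl <- (a + b) / 2
  attr(cl, "offset") <- chain$n_lead + min(intact) - 1L
  cl
}
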