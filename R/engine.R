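#' Run protocol for Langevin dynamics
#'
#' Describes one simulation run: either driven translocation (a constant
#' total force split equally over the in-pore nucleotides) or the pinned
#' reference protocol (no driving force, one in-pore nucleotide held fixed).
#'
#' @param mode `"driven"` or `"pinned"`.
#' @param total_force total driving force in pN (driven mode).
#' @param pinned_bead bead index to pin (pinned mode).
#' @param timestep integration timestep in model time tau.
#' @param gamma Langevin friction, 1/tau.
#' @param duration number of steps.
#' @param seed integer seed; fully determines the noise stream.
#' @param snapshot_stride steps between stored frames.
#' @param stall_window steps without progress of Q after which a driven run
#'   is flagged stalled and stopped (0 disables the detector).
#' @param terminate_on_complete stop once every strand-A bead has entered the
#'   pore (full translocation).
#' @return object of class `"run_protocol"`.
#' @export
run_protocol <- function(mode = c("driven", "pinned"), total_force = 0,
                         pinned_bead = NA_integer_, timestep = 0.004,
                         gamma = 1, duration = 10000, seed = 1,
                         snapshot_stride = 500, stall_window = 0,
                         terminate_on_complete = TRUE) {
  mode <- match.arg(mode)
  if (mode == "driven" && total_force < 0) stop("total_force must be >= 0")
  if (timestep <= 0 || duration < 1) stop("bad timestep/duration")
  structure(list(mode = mode, total_force = total_force,
                 pinned_bead = pinned_bead, timestep = timestep, gamma = gamma,
                 duration = as.integer(duration), seed = seed,
                 snapshot_stride = as.integer(snapshot_stride),
                 stall_window = as.integer(stall_window),
                 terminate_on_complete = isTRUE(terminate_on_complete)),
            class = "run_protocol")
}

# startup stability heuristic: dt must resolve the stiffest declared term
check_timestep <- function(protocol, ff, pore = NULL) {
  k <- kp_stiffness(ff, pore)
  dt_max <- 0.25 * sqrt(ff$mass / k)
  if (protocol$timestep > dt_max)
    stop(sprintf("timestep %g exceeds stability bound %.4g for stiffness %.3g",
                 protocol$timestep, dt_max, k))
  invisible(TRUE)
}

kp_run <- function(chain, ff, pore, protocol, drive, pinned) {
  check_timestep(protocol, ff, pore)
  validate_chain(chain)
  strandA <- chain$strand %in% c("lead", "A")
  res <- cpp_run_langevin(
    chain$pos, chain$vel, chain$bonds - 1L, chain$angles - 1L,
    as.numeric(ifelse(chain$angle_ss, ff$bend_kappa_ss, ff$bend_kappa)),
    chain$pair_a - 1L, chain$pair_b - 1L, chain$pair_state,
    unclass(ff),
    c(if (is.null(pore)) list(enabled = FALSE) else
      c(list(enabled = TRUE), unclass(pore))),
    list(nsteps = protocol$duration, timestep = protocol$timestep,
         gamma = protocol$gamma, total_force = drive,
         pinned = if (is.na(pinned)) -1L else as.integer(pinned) - 1L,
         snapshot_stride = protocol$snapshot_stride,
         stall_window = protocol$stall_window,
         terminate_on_complete = protocol$terminate_on_complete,
         seed = protocol$seed),
    strandA)
  if (identical(res$status, "diverged"))
    stop(sprintf("dynamics diverged at step %d (bead %d); last frame retained",
                 res$bad_step, res$bad_bead + 1L))
  res
}

# package a C++ run result as a trajectory object
as_trajectory <- function(res, chain, ff, pore, protocol) {
  out_chain <- chain
  out_chain$pos <- res$pos
  out_chain$vel <- res$vel
  out_chain$pair_state <- as.logical(res$pair_state)
  structure(list(
    frames = res$frames, pair_frames = lapply(res$pair_frames, as.logical),
    time = res$time, step = res$step, Q = res$Q, energy = res$energy,
    n_in_pore = res$n_in_pore, force_per_bead = res$force_per_bead,
    status = res$status, chain = out_chain, chain0 = chain,
    forcefield = ff, pore = pore, protocol = protocol),
    class = "kp_trajectory")
}

#' @export
print.kp_trajectory <- function(x, ...) {
  cat(sprintf("<kp_trajectory> %d frames, %d beads, status '%s'\n",
              length(x$frames), nrow(x$chain$pos), x$status))
  if (!is.null(x$pore))
    cat(sprintf("  Q: %d -> %d\n", x$Q[1], tail(x$Q, 1)))
  invisible(x)
}

#' Advance a chain by Langevin dynamics
#'
#' One or more BAOAB steps at temperature kT with friction `gamma`.  The
#' noise stream is fully determined by the protocol seed; a pinned bead (if
#' any) does not move.
#'
#' @param chain a `duplex_chain`.
#' @param forcefield a `forcefield_params`.
#' @param pore a `slab_pore`, or `NULL` for free-space dynamics.
#' @param protocol a `run_protocol`.
#' @param steps number of steps (default 1).
#' @return the updated `duplex_chain`.
#' @export
langevin_step <- function(chain, forcefield, pore = NULL, protocol, steps = 1) {
  p <- protocol
  p$duration <- as.integer(steps)
  p$snapshot_stride <- max(1L, as.integer(steps))
  p$terminate_on_complete <- FALSE
  drive <- if (p$mode == "driven") p$total_force else 0
  pinned <- if (p$mode == "pinned") p$pinned_bead else NA_integer_
  res <- kp_run(chain, forcefield, pore, p, drive, pinned)
  chain$pos <- res$pos
  chain$vel <- res$vel
  chain$pair_state <- as.logical(res$pair_state)
  chain
}

#' Driven translocation run
#'
#' Evolves an initial threaded state under the equal-split driving protocol
#' until full translocation, a stall, or the step budget.  In narrow-pore
#' mode a knot can never pass the pore; detection of still-paired strand-B
#' material past the trans face therefore aborts with a topology-violation
#' error (it would signal a geometry bug).
#'
#' @inheritParams langevin_step
#' @return a `kp_trajectory`; use [unzip_trace()] to extract the Q(t) series.
#' @export
run_translocation <- function(chain, forcefield, pore, protocol) {
  if (protocol$mode != "driven") stop("protocol mode must be 'driven'")
  if (length(in_pore_indices(chain, pore)) == 0)
    stop("initial state is not threaded through the pore")
  res <- kp_run(chain, forcefield, pore, protocol, protocol$total_force,
                NA_integer_)
  traj <- as_trajectory(res, chain, forcefield, pore, protocol)
  if (is_narrow(pore)) {
    ztrans <- pore$slab_z0 + pore$slab_thickness
    iB <- which(chain$strand == "B")
    for (k in seq_along(traj$frames)) {
      paired <- traj$pair_frames[[k]]
      beyond <- traj$frames[[k]][chain$pair_b[paired], 3] > ztrans
      if (any(beyond))
        stop("topology violation: paired strand-B bead past the trans face ",
             "in narrow mode (frame ", k, ")")
    }
  }
  traj
}

#' Pinned reference run
#'
#' No driving force; one in-pore nucleotide is held fixed, isolating the
#' intrinsic evolution of the knotted region over a time span comparable to a
#' driven run.
#'
#' @inheritParams langevin_step
#' @return a `kp_trajectory`.
#' @export
run_pinned <- function(chain, forcefield, pore, protocol) {
  if (protocol$mode != "pinned") stop("protocol mode must be 'pinned'")
  p <- protocol$pinned_bead
  if (is.na(p) || !(p %in% in_pore_indices(chain, pore)))
    stop("pinned_bead must be a bead inside the pore")
  res <- kp_run(chain, forcefield, pore, protocol, 0, p)
  as_trajectory(res, chain, forcefield, pore, protocol)
}
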