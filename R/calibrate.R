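#' Locate the low/high force regimes of the model
#'
#' The simplified ladder model need not place its unzipping regimes at the
#' same numerical forces as a full-resolution DNA model, so the
#' phenomenological regimes (low force: knots irrelevant; high force: strong
#' topological friction) are located by scanning the total driving force on
#' small systems.  For each force the scan runs driven unzipping of
#' unknotted and trefoil-led chains over several seeds and reports
#' completion fractions and median completion times.
#'
#' @param forces total driving forces to scan, pN.
#' @param n_bp reduced chain length for the scan.
#' @param seeds seeds per condition.
#' @param duration step budget per run.
#' @param recipe_seed study seed for the initial states.
#' @param forcefield,pore model components (defaults).
#' @return data.frame with one row per (force, topology): completion
#'   fraction, median completion time (NA if none), median velocity to the
#'   mark Q = 40 + n_bp/2.
#' @export
calibrate_forces <- function(forces = c(10, 20, 40, 60, 80), n_bp = 50,
                             seeds = 1:3, duration = 250000,
                             recipe_seed = 1,
                             forcefield = forcefield_params(),
                             pore = slab_pore("narrow")) {
  rows <- list()
  for (topo in c("0_1", "3_1")) {
    rec <- setup_recipe(n_bp = n_bp, knot_type = topo, seed = recipe_seed)
    states <- lapply(seq_along(seeds) - 1, function(cc)
      prepare_initial_state(rec, forcefield, pore, chain_counter = cc))
    for (f in forces) {
      tms <- vapply(seq_along(seeds), function(i) {
        prot <- run_protocol("driven", total_force = f, duration = duration,
                             seed = kp_seed(recipe_seed, "calib", i * 1000 + f),
                             snapshot_stride = 2000,
                             stall_window = as.integer(duration / 2))
        traj <- run_translocation(states[[i]], forcefield, pore, prot)
        if (traj$status == "completed") tail(traj$time, 1) else NA_real_
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        force = f, topology = topo,
        completed = mean(!is.na(tms)),
        median_time = stats::median(tms, na.rm = TRUE))
    }
  }
  do.call(rbind, rows)
}
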