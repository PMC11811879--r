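#' Extract the unzipping trace from a trajectory
#'
#' Time series of the translocated-nucleotide count Q(t) together with the
#' pore-entrance bead index (equivalently Q), the in-pore occupancy and the
#' applied per-bead force audit.
#'
#' @param traj a `kp_trajectory` from [run_translocation()] or
#'   [run_pinned()].
#' @return object of class `"unzip_trace"`: a data.frame with columns
#'   `time`, `step`, `Q`, `b_pore`, `n_in_pore`, `force_per_bead`, `energy`,
#'   and attributes `status` and `metadata` (force, topology, seed).
#' @export
unzip_trace <- function(traj) {
  df <- data.frame(time = traj$time, step = traj$step, Q = traj$Q,
                   b_pore = traj$Q, n_in_pore = traj$n_in_pore,
                   force_per_bead = traj$force_per_bead, energy = traj$energy)
  structure(df, status = traj$status,
            metadata = list(force = traj$protocol$total_force,
                            mode = traj$protocol$mode,
                            topology = traj$chain$meta$knot_type,
                            seed = traj$protocol$seed),
            class = c("unzip_trace", "data.frame"))
}

# strand-A path of one stored frame (detection polyline)
frame_apath <- function(traj, k) {
  traj$frames[[k]][traj$chain0$strand %in% c("lead", "A"), , drop = FALSE]
}

# cis duplex centreline of one stored frame
frame_centerline <- function(traj, k) {
  ch <- traj$chain0
  ch$pos <- traj$frames[[k]]
  ch$pair_state <- traj$pair_frames[[k]]
  cis_centerline(ch)
}

#' Knot kymograph: boundary indices of the knotted region over time
#'
#' Runs the bottom-up shortest-arc search on the strand-A path (ss lead plus
#' duplex strand A) of each analysed frame, reporting the nucleotide indices
#' (k1, k2) of the
#' knot ends -- and (k3, k4) for the second prime component of a composite
#' -- together with the pore-entrance index b.  Frames where the target is
#' not found are recorded as gaps; loss of the topology in a narrow-pore
#' driven run is flagged as an anomaly (possible only by end escape).
#'
#' @param traj a `kp_trajectory`.
#' @param target knot type to track (default: the chain's constructed type).
#' @param analysis_stride analyse every `analysis_stride`-th stored frame.
#' @param stride coarse search stride passed to [shortest_knotted_arc()].
#' @return data.frame with columns `time`, `b_pore`, `k1`, `k2`, `k3`, `k4`
#'   (NA where absent), `found`, `anomaly`.
#' @export
knot_kymograph <- function(traj, target = NULL, analysis_stride = 1,
                           stride = 4) {
  if (is.null(target)) target <- traj$chain$meta$knot_type
  if (is.null(target) || target == "0_1")
    stop("no knotted lead to track (target is the unknot)")
  composite <- target == "3_1#3_1"
  idx <- seq(1, length(traj$frames), by = analysis_stride)
  narrow_driven <- !is.null(traj$pore) && is_narrow(traj$pore) &&
    traj$protocol$mode == "driven"
  rows <- lapply(idx, function(k) {
    cl <- frame_apath(traj, k)
    out <- data.frame(time = traj$time[k], b_pore = traj$Q[k],
                      k1 = NA_integer_, k2 = NA_integer_,
                      k3 = NA_integer_, k4 = NA_integer_,
                      found = FALSE, anomaly = FALSE)
    if (is.null(cl) || nrow(cl) < 10) return(out)
    off <- 0L
    if (composite) {
      comps <- decompose_composite(cl, stride = stride)
      if (length(comps) >= 1) {
        out$k1 <- comps[[1]]$k1 + off; out$k2 <- comps[[1]]$k2 + off
        out$found <- TRUE
      }
      if (length(comps) >= 2) {
        out$k3 <- comps[[2]]$k1 + off; out$k4 <- comps[[2]]$k2 + off
      }
    } else {
      arc <- shortest_knotted_arc(cl, target, stride = stride)
      if (arc$found) {
        out$k1 <- arc$k1 + off; out$k2 <- arc$k2 + off
        out$found <- TRUE
      }
    }
    if (!out$found && narrow_driven) out$anomaly <- TRUE
    out
  })
  do.call(rbind, rows)
}

#' Knot length series from a kymograph
#'
#' Inclusive length convention L = k2 - k1 + 1 per component.
#'
#' @param kymo data.frame from [knot_kymograph()].
#' @return data.frame with `time`, `L1` and (for composites) `L2`.
#' @export
knot_length_series <- function(kymo) {
  data.frame(time = kymo$time,
             L1 = kymo$k2 - kymo$k1 + 1L,
             L2 = kymo$k4 - kymo$k3 + 1L)
}

#' First-passage time of the translocated count to a mark
#'
#' Linearly interpolated between stored frames.  Returns `NA` (with
#' attribute `reached = FALSE`) when the trace never attains the mark.
#'
#' @param trace an `unzip_trace` (or data.frame with `time` and `Q`).
#' @param mark translocated-nucleotide threshold.
#' @return time of first passage (numeric), `NA` if not reached.
#' @export
time_to_mark <- function(trace, mark) {
  q <- trace$Q; tt <- trace$time
  hit <- which(q >= mark)[1]
  if (is.na(hit)) return(structure(NA_real_, reached = FALSE))
  if (hit == 1) return(structure(tt[1], reached = TRUE))
  q0 <- q[hit - 1]; q1 <- q[hit]
  f <- if (q1 > q0) (mark - q0) / (q1 - q0) else 0
  structure(tt[hit - 1] + f * (tt[hit] - tt[hit - 1]), reached = TRUE)
}

#' Detect the two-regime structure of an unzipping trace
#'
#' Best continuous two-piece linear fit of Q versus t over candidate
#' breakpoints, compared against a single line by an F-test; when the test
#' is non-significant a single regime is declared.
#'
#' @param trace an `unzip_trace` with at least 20 frames.
#' @param alpha significance level of the F-test (default 0.01).
#' @return list with `single_regime` (logical), `breakpoint_time`,
#'   `breakpoint_Q`, slopes `v1`, `v2`, `F` and `p_value`.
#' @export
detect_velocity_regimes <- function(trace, alpha = 0.01) {
  tt <- trace$time; q <- trace$Q
  n <- length(tt)
  if (n < 20) stop("need at least 20 frames to detect regimes")
  fit1 <- lm(q ~ tt)
  rss1 <- sum(residuals(fit1)^2)
  cand <- tt[seq(4, n - 3)]
  best <- NULL
  for (tb in cand) {
    hinge <- pmax(tt - tb, 0)
    fit2 <- lm(q ~ tt + hinge)
    rss2 <- sum(residuals(fit2)^2)
    if (is.null(best) || rss2 < best$rss) best <- list(tb = tb, rss = rss2, fit = fit2)
  }
  df2 <- n - 3
  Fstat <- max(0, (rss1 - best$rss)) / max(best$rss / df2, 1e-300)
  # the breakpoint is selected as the best of many candidates, so the naive
  # F p-value is optimistic; a Bonferroni correction over the candidate set
  # restores a conservative test
  p <- min(1, pf(Fstat, 1, df2, lower.tail = FALSE) * length(cand))
  co <- coef(best$fit)
  v1 <- co[["tt"]]
  v2 <- v1 + co[["hinge"]]
  bq <- co[[1]] + v1 * best$tb
  if (p >= alpha) {
    list(single_regime = TRUE, breakpoint_time = NA_real_,
         breakpoint_Q = NA_real_, v1 = coef(fit1)[["tt"]],
         v2 = coef(fit1)[["tt"]], F = Fstat, p_value = p)
  } else {
    list(single_regime = FALSE, breakpoint_time = best$tb, breakpoint_Q = bq,
         v1 = v1, v2 = v2, F = Fstat, p_value = p)
  }
}

#' Heterogeneity ratio of a replicate set
#'
#' Ratio of the slowest to the fastest first-passage time to `mark` across
#' replicate traces.  Traces that never reach the mark are dropped from the
#' ratio and flagged.
#'
#' @param traces list of `unzip_trace` objects (at least 2 reaching `mark`).
#' @param mark translocated-nucleotide threshold.
#' @return ratio (>= 1), with attributes `times` and `all_reached`.
#' @export
heterogeneity_ratio <- function(traces, mark) {
  tm <- vapply(traces, function(tr) as.numeric(time_to_mark(tr, mark)),
               numeric(1))
  ok <- !is.na(tm)
  if (sum(ok) < 2) stop("need at least two traces reaching the mark")
  structure(max(tm[ok]) / min(tm[ok]), times = tm, all_reached = all(ok))
}

#' Wrapping turns of the unzipped cis strand around the duplex stem
#'
#' Signed winding number of the newly unzipped strand-B beads (broken
#' pairs, cis side) about the stem axis -- the duplex segment between the
#' pore mouth and the knot start k1 -- accumulated as angle increments in
#' planes normal to the stem.  Undefined (NA) when the stem is shorter than
#' 3 beads.
#'
#' @param traj a `kp_trajectory`.
#' @param kymo matching kymograph (for k1); `NULL` tracks the chain's type.
#' @return data.frame with `time` and `turns` (NA where undefined).
#' @export
wrapping_turns <- function(traj, kymo = NULL) {
  if (is.null(kymo)) kymo <- knot_kymograph(traj)
  ch <- traj$chain0
  z0 <- traj$pore$slab_z0
  rows <- lapply(seq_len(nrow(kymo)), function(r) {
    k <- which.min(abs(traj$time - kymo$time[r]))
    out <- data.frame(time = kymo$time[r], turns = NA_real_)
    if (!kymo$found[r]) return(out)
    pos <- traj$frames[[k]]
    paired <- traj$pair_frames[[k]]
    intact <- which(paired)
    if (length(intact) < 3) return(out)
    # stem: duplex between the pore mouth (first intact pair) and k1
    k1_local <- kymo$k1[r] - ch$n_lead
    stem_idx <- intact[intact <= k1_local]
    if (length(stem_idx) < 3) return(out)
    a <- pos[ch$pair_a[stem_idx], , drop = FALSE]
    b <- pos[ch$pair_b[stem_idx], , drop = FALSE]
    stem <- (a + b) / 2
    axis <- stem[nrow(stem), ] - stem[1, ]
    nx <- sqrt(sum(axis^2))
    if (nx < 1e-9) return(out)
    axis <- axis / nx
    # unzipped cis strand-B beads, ordered along the strand
    loose <- which(!paired)
    loose <- loose[pos[ch$pair_b[loose], 3] < z0]
    if (length(loose) < 3) { out$turns <- 0; return(out) }
    pb <- pos[ch$pair_b[sort(loose)], , drop = FALSE]
    rel <- sweep(pb, 2, stem[1, ])
    ax_coord <- rel %*% axis
    span <- as.numeric(sweep(stem, 2, stem[1, ]) %*% axis)
    inside <- ax_coord >= min(span) & ax_coord <= max(span)
    if (sum(inside) < 3) { out$turns <- 0; return(out) }
    perp <- rel[inside, , drop = FALSE] - outer(ax_coord[inside, 1], axis)
    ref1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref1 - sum(ref1 * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    ang <- atan2(perp %*% e2, perp %*% e1)
    dth <- diff(ang)
    dth <- ((dth + pi) %% (2 * pi)) - pi
    out$turns <- sum(dth) / (2 * pi)
    out
  })
  do.call(rbind, rows)
}
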