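#' Write a trajectory in the extended-XYZ dialect
#'
#' One block per frame: a bead-count line, a comment line with `key=value`
#' metadata (time, step, Q, in-pore occupancy, per-bead applied force,
#' status), then one record per bead: strand tag, x, y, z, pairing state
#' (`1` intact, `0` broken, `-` for beads without a pairing partner).
#' Coordinates are printed with enough digits to round-trip to 1e-9 nm.
#'
#' @param traj a `kp_trajectory`, or a list of frames as returned by
#'   [read_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(traj, "kp_trajectory")) {
    ch <- traj$chain0
    nd <- ch$n_duplex
    pair_of <- integer(nrow(ch$pos))
    pair_of[ch$pair_a] <- seq_len(nd)
    pair_of[ch$pair_b] <- seq_len(nd)
    for (k in seq_along(traj$frames)) {
      pos <- traj$frames[[k]]
      st <- traj$pair_frames[[k]]
      pstate <- ifelse(pair_of > 0, ifelse(st[pmax(pair_of, 1)], "1", "0"), "-")
      writeLines(as.character(nrow(pos)), con)
      writeLines(sprintf("time=%.12g step=%d Q=%d n_in=%d f_per=%.12g status=%s",
                         traj$time[k], traj$step[k], traj$Q[k],
                         traj$n_in_pore[k], traj$force_per_bead[k],
                         traj$status), con)
      writeLines(sprintf("%s %.12g %.12g %.12g %s", toupper(ch$strand),
                         pos[, 1], pos[, 2], pos[, 3], pstate), con)
    }
  } else {
    for (fr in traj) {
      writeLines(as.character(nrow(fr$pos)), con)
      meta <- fr$meta
      writeLines(paste(sprintf("%s=%s", names(meta),
                               vapply(meta, function(v)
                                 if (is.numeric(v)) sprintf("%.12g", v)
                                 else as.character(v), "")),
                       collapse = " "), con)
      ps <- if (is.null(fr$pair_state)) rep("-", nrow(fr$pos)) else fr$pair_state
      writeLines(sprintf("%s %.12g %.12g %.12g %s", fr$strand,
                         fr$pos[, 1], fr$pos[, 2], fr$pos[, 3], ps), con)
    }
  }
  invisible(path)
}

parse_xyz_meta <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- paste(p[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[[`, "", 1)
  vals
}

#' Read an extended-XYZ trajectory
#'
#' Reads frame blocks written by [write_trajectory()].  With a `callback`,
#' frames are processed one at a time as they are parsed and never
#' accumulated, so arbitrarily long files are streamed in constant memory;
#' otherwise all frames are returned as a list.
#'
#' @param path input file.
#' @param callback optional `function(frame, index)`; its return values are
#'   discarded.
#' @return list of frames (each `list(pos, strand, pair_state, meta)`), or
#'   (with a callback) the number of frames processed, invisibly.
#' @export
read_trajectory <- function(path, callback = NULL) {
  con <- file(path, "r")
  on.exit(close(con))
  frames <- if (is.null(callback)) list() else NULL
  k <- 0
  repeat {
    hd <- readLines(con, n = 1)
    if (length(hd) == 0) break
    n <- suppressWarnings(as.integer(hd))
    if (is.na(n)) stop("malformed frame header at frame ", k + 1, ": ", hd)
    meta <- parse_xyz_meta(readLines(con, n = 1))
    lines <- readLines(con, n = n)
    if (length(lines) < n)
      stop("truncated frame ", k + 1, ": expected ", n, " bead records")
    toks <- strsplit(lines, " ", fixed = TRUE)
    bad <- which(lengths(toks) != 5)
    if (length(bad))
      stop("malformed bead record in frame ", k + 1, ", line ", bad[1])
    mt <- matrix(unlist(toks), ncol = 5, byrow = TRUE)
    fr <- list(pos = cbind(as.numeric(mt[, 2]), as.numeric(mt[, 3]),
                           as.numeric(mt[, 4])),
               strand = mt[, 1], pair_state = mt[, 5], meta = meta)
    k <- k + 1
    if (is.null(callback)) frames[[k]] <- fr else callback(fr, k)
  }
  if (is.null(callback)) frames else invisible(k)
}

#' Study configuration
#'
#' One YAML document holding every tunable of a run: recipe, force field,
#' pore, protocol and analysis sections plus output paths.  Written next to
#' every run's outputs so any result can be reproduced from its directory.
#'
#' @param recipe,forcefield,pore named lists or the corresponding objects.
#' @param protocol named list of protocol fields.
#' @param analysis named list (stride, mark, alpha, ...).
#' @param output named list of output paths.
#' @return object of class `"study_config"` (a named list of sections).
#' @export
study_config <- function(recipe = setup_recipe(), forcefield = forcefield_params(),
                         pore = slab_pore("narrow"),
                         protocol = list(mode = "driven", total_force = 60,
                                         timestep = 0.0025, gamma = 1,
                                         duration = 200000, seed = 1,
                                         snapshot_stride = 1000,
                                         stall_window = 0),
                         analysis = list(stride = 1, mark = 90, alpha = 0.01),
                         output = list(dir = ".")) {
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  structure(list(recipe = drop_null(unclass(recipe)),
                 forcefield = drop_null(unclass(forcefield)),
                 pore = drop_null(unclass(pore)),
                 protocol = drop_null(protocol),
                 analysis = drop_null(analysis),
                 output = drop_null(output)),
            class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path file path.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(s)
    lapply(s, function(v) if (is.matrix(v)) NULL else v)), path,
    precision = 15)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("recipe", "forcefield", "pore", "protocol")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config missing section(s): ", paste(miss, collapse = ", "))
  structure(cfg, class = "study_config")
}

# rebuild typed objects from a parsed config
config_recipe <- function(cfg) do.call(setup_recipe, cfg$recipe[names(cfg$recipe)
  %in% names(formals(setup_recipe))])
config_forcefield <- function(cfg) do.call(forcefield_params,
  cfg$forcefield[names(cfg$forcefield) %in% names(formals(forcefield_params))])
config_pore <- function(cfg) do.call(slab_pore,
  cfg$pore[names(cfg$pore) %in% names(formals(slab_pore))])
config_protocol <- function(cfg) do.call(run_protocol,
  cfg$protocol[names(cfg$protocol) %in% names(formals(run_protocol))])
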