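# Monte Carlo sampling of equilibrated semi-flexible chains (duplex
# centrelines): crankshaft + pivot moves, Metropolis on the Kratky-Porod
# bending energy, hard-core self-avoidance.

# discrete WLC: <cos theta> = coth(k) - 1/k with k = kappa/kT, and
# lp = -b / log(<cos theta>); invert for the target persistence length
kappa_for_lp <- function(lp, bond) {
  target <- exp(-bond / lp)
  f <- function(k) (1 / tanh(k) - 1 / k) - target
  stats::uniroot(f, c(0.5, 5000))$root
}

#' Sample an equilibrated semi-flexible chain
#'
#' Monte Carlo (crankshaft + pivot) sampling of a self-avoiding discrete
#' worm-like chain of `n_bp` segments with the recipe's target persistence
#' length, emulating equilibrated dsDNA centrelines.  Equilibration is
#' monitored through the integrated autocorrelation time of the end-to-end
#' distance; sampling continues in blocks until the run spans at least 20
#' autocorrelation times (within a budget).  Samples that happen to be
#' knotted are discarded and redrawn (the count is recorded); at the studied
#' contour lengths spontaneous knotting is rare.
#'
#' @param recipe a [setup_recipe()] (fields `n_bp`, `bond`,
#'   `persistence_length`, `hard_core`, `mc_sweeps`, `seed`).
#' @param counter stream counter, so replicate conformations draw
#'   independent seeds from the same study seed.
#' @return n_bp x 3 centreline matrix with attributes `lp_target`,
#'   `resampled` (number of knotted samples discarded) and `sweeps`.
#' @export
sample_semiflexible_chain <- function(recipe, counter = 0) {
  b <- recipe$bond
  kap <- kappa_for_lp(recipe$persistence_length, b)
  hard_excl <- ceiling(recipe$hard_core / b) + 1
  base_sweeps <- if (is.null(recipe$mc_sweeps)) max(200L, recipe$n_bp) else recipe$mc_sweeps
  resampled <- 0
  for (try in 0:19) {
    seed <- kp_seed(recipe$seed, "wlc", counter * 100 + try)
    res <- cpp_wlc_mc(recipe$n_bp, b, kap, recipe$hard_core, hard_excl,
                      base_sweeps, seed, 1L, NULL)
    sweeps <- base_sweeps
    for (block in 1:4) { # extend until equilibrated by the Ree criterion
      tau <- ree_autocorr_time(res$ree)
      if (sweeps >= 20 * tau) break
      more <- cpp_wlc_mc(recipe$n_bp, b, kap, recipe$hard_core, hard_excl,
                         base_sweeps, kp_seed(seed, "ext", block), 1L, res$pos)
      res$pos <- more$pos
      res$ree <- c(res$ree, more$ree)
      sweeps <- sweeps + base_sweeps
    }
    if (classify_knot(res$pos) == "0_1") {
      out <- res$pos
      attr(out, "lp_target") <- recipe$persistence_length
      attr(out, "resampled") <- resampled
      attr(out, "sweeps") <- sweeps
      return(out)
    }
    resampled <- resampled + 1
  }
  stop("could not draw an unknotted equilibrated conformation in 20 attempts")
}

# integrated autocorrelation time (sweeps) of a scalar series
ree_autocorr_time <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) < 1e-12) return(1)
  a <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(a < 0.05)[1]
  if (is.na(pos)) pos <- length(a)
  max(1, 1 + 2 * sum(a[seq_len(pos)]))
}

#' Fit the persistence length of a sampled chain ensemble
#'
#' Exponential fit of the bond-vector correlation decay
#' \eqn{\langle t_i . t_{i+s} \rangle = e^{-s b / l_p}} over an ensemble of
#' centrelines; used to verify that the sampler and the bending constant
#' reproduce the target persistence length.
#'
#' @param chains list of centreline matrices (or a single matrix).
#' @param bond bead spacing, nm.
#' @param max_lag largest contour lag (in beads) used in the fit.
#' @return fitted persistence length in nm.
#' @export
fit_persistence_length <- function(chains, bond, max_lag = 40) {
  if (is.matrix(chains)) chains <- list(chains)
  lags <- seq_len(max_lag)
  corr <- vapply(lags, function(s) {
    vals <- unlist(lapply(chains, function(x) {
      tg <- diff(x)
      tg <- tg / sqrt(rowSums(tg^2))
      m <- nrow(tg)
      if (m <= s) return(NULL)
      rowSums(tg[1:(m - s), , drop = FALSE] * tg[(1 + s):m, , drop = FALSE])
    }))
    mean(vals)
  }, numeric(1))
  keep <- corr > 0.05
  if (sum(keep) < 3) stop("correlation decays too fast for a fit")
  fit <- stats::lm(log(corr[keep]) ~ 0 + lags[keep])
  -bond / coef(fit)[[1]]
}

# worm-like-chain closed form for the mean-square end-to-end distance
wlc_r2 <- function(L, lp) 2 * lp * L - 2 * lp^2 * (1 - exp(-L / lp))
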