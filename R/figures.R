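#' Standard study figures
#'
#' Writes the three panel types of the study as PDF files: translocation
#' traces Q(t) grouped by force, a knot kymograph (k1/k2 and the
#' pore-entrance index b), and knot-length series L(t) by topology.  Figures
#' are deterministic functions of the input tables.
#'
#' @param traces optional data.frame with columns `time`, `Q`, `force`,
#'   `replicate`.
#' @param kymo optional kymograph data.frame ([knot_kymograph()] output).
#' @param lengths optional data.frame with `time`, `L`, `topology`,
#'   `replicate`.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
make_figures <- function(traces = NULL, kymo = NULL, lengths = NULL,
                         dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  if (!is.null(traces)) {
    f <- file.path(dir, "traces.pdf")
    grDevices::pdf(f, width = 6, height = 4)
    if (nrow(traces) == 0) {
      plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "time [tau]",
           ylab = "translocated nucleotides Q")
    } else {
      forces <- sort(unique(traces$force))
      cols <- grDevices::hcl.colors(max(3, length(forces)), "Dark 3")
      plot(NA, xlim = range(traces$time), ylim = range(traces$Q),
           xlab = "time [tau]", ylab = "translocated nucleotides Q")
      for (i in seq_along(forces)) {
        sub <- traces[traces$force == forces[i], ]
        for (r in unique(sub$replicate)) {
          s <- sub[sub$replicate == r, ]
          graphics::lines(s$time, s$Q, col = cols[i])
        }
      }
      graphics::legend("bottomright", legend = sprintf("%g pN", forces),
                       col = cols[seq_along(forces)], lty = 1, bty = "n")
    }
    grDevices::dev.off()
    written <- c(written, f)
  }

  if (!is.null(kymo)) {
    f <- file.path(dir, "kymograph.pdf")
    grDevices::pdf(f, width = 6, height = 4)
    if (nrow(kymo) == 0) {
      plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "time [tau]",
           ylab = "nucleotide index")
    } else {
      ylim <- range(c(kymo$k1, kymo$k2, kymo$k3, kymo$k4, kymo$b_pore),
                    na.rm = TRUE)
      plot(NA, xlim = range(kymo$time), ylim = ylim, xlab = "time [tau]",
           ylab = "nucleotide index")
      graphics::lines(kymo$time, kymo$b_pore, col = "grey40", lty = 2)
      graphics::lines(kymo$time, kymo$k1, col = "firebrick")
      graphics::lines(kymo$time, kymo$k2, col = "firebrick", lty = 3)
      if (any(!is.na(kymo$k3))) {
        graphics::lines(kymo$time, kymo$k3, col = "steelblue")
        graphics::lines(kymo$time, kymo$k4, col = "steelblue", lty = 3)
      }
      graphics::legend("topleft", legend = c("b (pore)", "k1", "k2"),
                       col = c("grey40", "firebrick", "firebrick"),
                       lty = c(2, 1, 3), bty = "n")
    }
    grDevices::dev.off()
    written <- c(written, f)
  }

  if (!is.null(lengths)) {
    f <- file.path(dir, "knot_length.pdf")
    grDevices::pdf(f, width = 6, height = 4)
    if (nrow(lengths) == 0) {
      plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "time [tau]",
           ylab = "knot length L [bp]")
    } else {
      tops <- unique(lengths$topology)
      cols <- grDevices::hcl.colors(max(3, length(tops)), "Dark 3")
      plot(NA, xlim = range(lengths$time), ylim = range(lengths$L, na.rm = TRUE),
           xlab = "time [tau]", ylab = "knot length L [bp]")
      for (i in seq_along(tops)) {
        sub <- lengths[lengths$topology == tops[i], ]
        for (r in unique(sub$replicate)) {
          s <- sub[sub$replicate == r, ]
          graphics::lines(s$time, s$L, col = cols[i])
        }
      }
      graphics::legend("topleft", legend = tops, col = cols[seq_along(tops)],
                       lty = 1, bty = "n")
    }
    grDevices::dev.off()
    written <- c(written, f)
  }

  invisible(written)
}
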