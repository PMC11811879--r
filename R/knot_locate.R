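#' Shortest knotted arc of an open chain
#'
#' Bottom-up search for the shortest sub-arc whose minimally interfering
#' closure carries the sought knot type while the closure of the complement
#' (the chain with the arc replaced by a straight jump) is unknotted.  Arcs
#' are enumerated by increasing length on a coarse stride and the winning
#' bounds are then refined by unit steps; ties break toward the pore
#' (low-index) end.  Shrinking either refined bound loses the knot.
#'
#' @param open_chain n x 3 coordinate matrix (or an object with a
#'   `$centerline`).
#' @param target_label knot type sought (`"3_1"`, `"4_1"`, `"3_1#3_1"`).
#' @param stride coarse enumeration stride in beads.
#' @param min_len smallest arc length tried.
#' @return list with `found` (logical); when found also `k1`, `k2` (1-based
#'   inclusive bead bounds) and `label`.
#' @export
shortest_knotted_arc <- function(open_chain, target_label, stride = 4,
                                 min_len = 8) {
  x <- as_polyline(open_chain)
  n <- nrow(x)
  not_found <- list(found = FALSE, label = target_label)
  if (n < min_len) return(not_found)

  arc_ok <- function(k1, k2) {
    classify_knot(x[k1:k2, , drop = FALSE]) == target_label &&
      complement_unknot(x, k1, k2)
  }

  hit <- NULL
  for (len in unique(c(seq(min_len, n, by = stride), n))) {
    starts <- unique(c(seq(1, n - len + 1, by = stride), n - len + 1))
    for (k1 in starts) {
      k2 <- k1 + len - 1
      if (classify_knot(x[k1:k2, , drop = FALSE]) == target_label &&
          complement_unknot(x, k1, k2)) {
        hit <- c(k1, k2)
        break
      }
    }
    if (!is.null(hit)) break
  }
  if (is.null(hit)) return(not_found)

  k1 <- hit[1]; k2 <- hit[2]
  # refine: pull each bound inward by unit steps while the arc still works
  repeat {
    moved <- FALSE
    if (k2 - k1 > 3 && arc_ok(k1 + 1, k2)) { k1 <- k1 + 1; moved <- TRUE }
    if (k2 - k1 > 3 && arc_ok(k1, k2 - 1)) { k2 <- k2 - 1; moved <- TRUE }
    if (!moved) break
  }
  # ties toward the pore end: slide the window down while it still works
  while (k1 > 1 && arc_ok(k1 - 1, k2 - 1)) { k1 <- k1 - 1; k2 <- k2 - 1 }
  list(found = TRUE, k1 = k1, k2 = k2, label = target_label)
}

as_polyline <- function(x) {
  if (is.list(x) && !is.null(x$centerline)) x <- x$centerline
  as.matrix(x)
}

# closure of the chain with arc (k1,k2) replaced by a straight jump
complement_unknot <- function(x, k1, k2) {
  n <- nrow(x)
  comp <- rbind(x[seq_len(k1), , drop = FALSE],
                x[seq(k2, n), , drop = FALSE])
  if (nrow(comp) < 5) return(TRUE)
  classify_knot(comp) == "0_1"
}

#' Decompose a chain into prime knotted components
#'
#' For a composite (granny) chain, returns the two disjoint arcs that each
#' close to a trefoil, ordered by proximity to the pore (low-index) end; for
#' a prime knot, the single shortest knotted arc; for an unknot, an empty
#' list.  Prime components are identified by a bottom-up search in which the
#' complement of a candidate first component must itself carry the remaining
#' knot.
#'
#' @inheritParams shortest_knotted_arc
#' @return list of components, each `list(k1, k2, label)`, ordered by `k1`.
#' @export
decompose_composite <- function(open_chain, stride = 4, min_len = 8) {
  x <- as_polyline(open_chain)
  whole <- classify_knot(x)
  if (whole == "0_1") return(list())
  if (whole %in% c("3_1", "4_1")) {
    arc <- shortest_knotted_arc(x, whole, stride, min_len)
    if (!arc$found) return(list())
    return(list(list(k1 = arc$k1, k2 = arc$k2, label = whole)))
  }
  if (whole != "3_1#3_1") return(list())
  n <- nrow(x)
  # first (pore-proximal) trefoil: shortest arc classifying 3_1 whose
  # complement still carries the second trefoil
  first <- NULL
  for (len in seq(min_len, n, by = stride)) {
    for (k1 in seq(1, n - len + 1, by = stride)) {
      k2 <- k1 + len - 1
      if (classify_knot(x[k1:k2, , drop = FALSE]) != "3_1") next
      comp <- rbind(x[seq_len(k1), , drop = FALSE],
                    x[seq(k2, n), , drop = FALSE])
      if (classify_knot(comp) == "3_1") { first <- c(k1, k2); break }
    }
    if (!is.null(first)) break
  }
  if (is.null(first)) return(list())
  # second trefoil lives in the remainder beyond the first component
  rest <- x[seq(first[2], n), , drop = FALSE]
  second <- shortest_knotted_arc(rest, "3_1", stride, min_len)
  comps <- list(list(k1 = first[1], k2 = first[2], label = "3_1"))
  if (second$found)
    comps <- c(comps, list(list(k1 = second$k1 + first[2] - 1,
                                k2 = second$k2 + first[2] - 1,
                                label = "3_1")))
  comps[order(vapply(comps, `[[`, numeric(1), "k1"))]
}

#' Minimal crossing number of a supported knot type
#'
#' Nominal knot complexity: the minimum number of crossings over all
#' non-degenerate projections, i.e. 0, 3, 4 and 6 for the unknot, trefoil,
#' figure-eight and granny knot.
#'
#' @param knot_label one of `"0_1"`, `"3_1"`, `"4_1"`, `"3_1#3_1"`.
#' @return integer crossing number.
#' @export
crossing_number_of_type <- function(knot_label) {
  tab <- c("0_1" = 0L, "3_1" = 3L, "4_1" = 4L, "3_1#3_1" = 6L)
  if (!knot_label %in% names(tab))
    stop("unsupported knot label: ", knot_label)
  tab[[knot_label]]
}
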