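#' Parametric knotted curves
#'
#' Standard parametrizations used to construct tight knotted leads: the
#' (2,3) torus curve for the trefoil and the standard figure-eight curve.
#'
#' @param type `"3_1"` or `"4_1"`.
#' @param n number of vertices.
#' @param open drop a small parameter gap so the curve is an open arc with
#'   adjacent endpoints (the form used to splice a knot into an open chain)?
#' @return n x 3 coordinate matrix (unit-ish scale; rescale as needed).
#' @export
parametric_knot <- function(type = c("3_1", "4_1"), n = 200, open = FALSE) {
  type <- match.arg(type)
  span <- if (open) 2 * pi * 0.96 else 2 * pi
  t0 <- if (open) 2 * pi * 0.02 else 0
  tt <- t0 + seq(0, span, length.out = n + if (open) 0 else 1)
  if (!open) tt <- tt[-(n + 1)]
  if (type == "3_1") {
    cbind((2 + cos(3 * tt)) * cos(2 * tt),
          (2 + cos(3 * tt)) * sin(2 * tt),
          sin(3 * tt))
  } else {
    cbind((2 + cos(2 * tt)) * cos(3 * tt),
          (2 + cos(2 * tt)) * sin(3 * tt),
          sin(4 * tt))
  }
}

# resample a polyline at (approximately) equal arc-length spacing h
resample_polyline <- function(x, h) {
  seg <- sqrt(rowSums(diff(x)^2))
  s <- c(0, cumsum(seg))
  stot <- s[length(s)]
  m <- max(2, round(stot / h) + 1)
  si <- seq(0, stot, length.out = m)
  cbind(approx(s, x[, 1], xout = si)$y,
        approx(s, x[, 2], xout = si)$y,
        approx(s, x[, 3], xout = si)$y)
}

# scale a polyline so its total contour length is L
scale_contour <- function(x, L) {
  stot <- sum(sqrt(rowSums(diff(x)^2)))
  x * (L / stot)
}

#' Construct a tight knotted lead segment
#'
#' Builds the centreline of a pre-tightened knotted duplex segment of the
#' requested type, sampled at bead resolution with a knotted core of about
#' `tight_core_target_bp` base pairs.  The granny knot is built as the
#' connected sum of two like-handed trefoils (each of core size
#' `tight_core_target_bp`, joined by a short straight bridge).  The
#' construction is verified by classification; a mismatch is a hard failure.
#' An unknot request returns `NULL` (nothing is added to the chain).
#'
#' @param knot_type `"0_1"`, `"3_1"`, `"4_1"` or `"3_1#3_1"`.
#' @param tight_core_target_bp target core length in base pairs (beads).
#' @param bond bead spacing along the centreline, nm.
#' @return object of class `"knot_segment"`: list with `centerline` (m x 3
#'   matrix, arc starting at row 1), `type`, `bond`; or `NULL` for `"0_1"`.
#' @export
build_tight_knot <- function(knot_type = c("3_1", "4_1", "3_1#3_1", "0_1"),
                             tight_core_target_bp = 50, bond = 0.5) {
  knot_type <- match.arg(knot_type)
  if (knot_type == "0_1") return(NULL)
  core <- function(type) {
    # the shortest knotted arc of a parametric curve is shorter than the
    # curve itself (its ends can be trimmed), so calibrate the sampling until
    # the *measured* core matches the target
    n_s <- tight_core_target_bp
    for (it in 1:3) {
      x <- parametric_knot(type, n = n_s, open = TRUE)
      x <- scale_contour(x, n_s * bond)
      arc <- shortest_knotted_arc(x, type, stride = 2)
      if (!arc$found) stop("parametric ", type, " curve lost its knot")
      len <- arc$k2 - arc$k1 + 1
      if (abs(len - tight_core_target_bp) <= 3) break
      n_s <- max(12, min(400, round(n_s * tight_core_target_bp / len)))
    }
    x
  }
  if (knot_type %in% c("3_1", "4_1")) {
    cl <- core(knot_type)
  } else {
    a <- core("3_1")
    # align both trefoils along the chord between their endpoints and chain
    # them with a short straight bridge: a connected sum of like-handed knots
    a <- orient_by_chord(a)
    b <- a # identical copy: same handedness by construction
    gap <- 4 * bond
    off <- a[nrow(a), ] + c(0, 0, -gap)
    b <- sweep(b, 2, b[1, ]) # start at origin
    b <- sweep(b, 2, off, `+`)
    bridge <- rbind(a[nrow(a), ] + c(0, 0, -gap / 3),
                    a[nrow(a), ] + c(0, 0, -2 * gap / 3))
    cl <- rbind(a, bridge, b)
  }
  cl <- resample_polyline(cl, bond)
  got <- classify_knot(cl)
  if (got != knot_type)
    stop(sprintf("tight-knot construction failed: built %s, classified %s",
                 knot_type, got))
  structure(list(centerline = cl, type = knot_type, bond = bond),
            class = "knot_segment")
}

# rotate/translate an open curve so it starts at the origin with its
# end-to-end chord along -z (entry tangent roughly -z)
orient_by_chord <- function(x) {
  x <- sweep(x, 2, x[1, ])
  chord <- x[nrow(x), ]
  nc <- sqrt(sum(chord^2))
  if (nc < 1e-9) return(x)
  u <- chord / nc
  tgt <- c(0, 0, -1)
  ax <- c(u[2] * tgt[3] - u[3] * tgt[2],
          u[3] * tgt[1] - u[1] * tgt[3],
          u[1] * tgt[2] - u[2] * tgt[1])
  na <- sqrt(sum(ax^2))
  if (na < 1e-9) {
    if (sum(u * tgt) > 0) return(x)
    return(x %*% diag(c(1, -1, -1)))
  }
  th <- acos(max(-1, min(1, sum(u * tgt))))
  x %*% t(rot_about(ax / na, th))
}

# parallel-transport frame: offset strands A and B at +/- half_sep from the
# centreline without introducing frame flips
duplex_strands_from_centerline <- function(cl, half_sep) {
  m <- nrow(cl)
  tg <- rbind(cl[2, ] - cl[1, ], (cl[3:m, , drop = FALSE] - cl[1:(m - 2), , drop = FALSE]) / 2,
              cl[m, ] - cl[m - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  nrm <- matrix(0, m, 3)
  # initial normal: any unit vector perpendicular to the first tangent
  t1 <- tg[1, ]
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * t1) * t1
  nrm[1, ] <- v / sqrt(sum(v^2))
  for (i in 2:m) {
    v <- nrm[i - 1, ] - sum(nrm[i - 1, ] * tg[i, ]) * tg[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) v <- nrm[i - 1, ] else v <- v / nv
    nrm[i, ] <- v
  }
  list(A = cl + half_sep * nrm, B = cl - half_sep * nrm)
}
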