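#' KMT simplification of a polyline
#'
#' Topology-preserving reduction: a vertex is removed when the triangle
#' spanned by it and its two neighbours is crossed by no other segment of the
#' curve, iterated to a fixed point.  Shrinks a chain to a handful of
#' vertices before crossing enumeration, which keeps the Alexander
#' determinant computation cheap.
#'
#' @param polyline n x 3 coordinate matrix (at least 3 vertices).
#' @param closed treat the polyline as a closed ring?
#' @return the reduced coordinate matrix.
#' @export
kmt_simplify <- function(polyline, closed = FALSE) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 3) stop("need at least 3 vertices")
  cpp_kmt(polyline, closed)
}

# deterministic quasi-uniform directions on the sphere (Fibonacci lattice)
fib_sphere <- function(m) {
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# approximate distance from interior point p to the convex hull of pts,
# via the support function h(u) = max_j u.x_j sampled over fixed directions;
# also returns the direction of nearest exit
hull_exit <- function(pts, p, dirs) {
  gaps <- dirs %*% p
  sup <- apply(dirs %*% t(pts), 1, max)
  d <- sup - gaps
  k <- which.min(d)
  list(dist = max(d[k], 0), dir = dirs[k, ])
}

# rotation matrix about unit axis u by angle th (Rodrigues)
rot_about <- function(u, th) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Minimally interfering closure of an open chain
#'
#' Knots are rigorously defined only for closed curves, so an open chain is
#' closed by the auxiliary arc adding the least entanglement: if the sum of
#' the two endpoints' distances to the convex hull is smaller than their
#' mutual distance, each endpoint exits the hull along its nearest direction
#' out to a far radius and the two exit points are joined by an external arc;
#' otherwise the endpoints are bridged directly.  Degenerate (collinear)
#' input falls back to direct bridging.
#'
#' @param polyline n x 3 coordinate matrix (at least 3 vertices).
#' @return a closed polyline (closure edge implied between last and first
#'   row), with attribute `"closure"` equal to `"outward"` or `"bridge"`.
#' @export
minimally_interfering_closure <- function(polyline) {
  x <- as.matrix(polyline)
  if (nrow(x) < 3) stop("need at least 3 vertices")
  n <- nrow(x)
  e1 <- x[1, ]; e2 <- x[n, ]
  ctr <- colMeans(x)
  rad <- sqrt(max(rowSums(sweep(x, 2, ctr)^2)))
  span <- svd(sweep(x, 2, ctr), nu = 0, nv = 0)$d
  degenerate <- rad < 1e-9 || span[min(3, length(span))] / max(span[1], 1e-300) < 1e-9
  if (!degenerate) {
    dirs <- fib_sphere(312)
    h1 <- hull_exit(x, e1, dirs)
    h2 <- hull_exit(x, e2, dirs)
    d12 <- sqrt(sum((e1 - e2)^2))
    if (h1$dist + h2$dist < d12) {
      rout <- 10 * rad
      q1 <- e1 + h1$dir * (h1$dist + rout)
      q2 <- e2 + h2$dir * (h2$dist + rout)
      # join the two exit points by an arc on a far sphere around the centre
      u1 <- q1 - ctr; u2 <- q2 - ctr
      r1 <- sqrt(sum(u1^2)); r2 <- sqrt(sum(u2^2))
      ang <- acos(max(-1, min(1, sum(u1 * u2) / (r1 * r2))))
      nseg <- max(2, ceiling(ang / (pi / 6)))
      ts <- seq(0, 1, length.out = nseg + 1)[-c(1, nseg + 1)]
      arc <- t(vapply(ts, function(t) {
        v <- (1 - t) * u1 / r1 + t * u2 / r2
        nv <- sqrt(sum(v^2))
        if (nv < 1e-9) { # antipodal: detour via an orthogonal direction
          w <- c(u1[2], -u1[1], 0)
          if (sum(w^2) < 1e-12) w <- c(0, u1[3], -u1[2])
          v <- w; nv <- sqrt(sum(v^2))
        }
        ctr + v / nv * ((1 - t) * r1 + t * r2)
      }, numeric(3)))
      out <- rbind(x, q2, arc[rev(seq_len(nrow(arc))), , drop = FALSE], q1)
      attr(out, "closure") <- "outward"
      return(out)
    }
  }
  out <- x
  attr(out, "closure") <- "bridge"
  out
}

# enumerate crossings of a closed polyline projected on xy (after rotation).
# Returns NULL on a degenerate projection, else a list of under/over events.
kp_crossings <- function(x) {
  m <- nrow(x)
  eps <- 1e-9
  p <- x
  q <- x[c(2:m, 1), , drop = FALSE]
  d <- q - p
  under_pos <- c(); over_pos <- c(); sgn <- c()
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      # skip adjacent edges (sharing a vertex)
      if (j == i + 1 || (i == 1 && j == m)) next
      den <- d[i, 1] * d[j, 2] - d[i, 2] * d[j, 1]
      scale <- max(abs(d[i, 1:2]), abs(d[j, 1:2]))
      if (abs(den) < 1e-12 * scale^2) {
        # parallel in projection: degenerate only if they actually overlap
        next
      }
      rx <- p[j, 1] - p[i, 1]; ry <- p[j, 2] - p[i, 2]
      t <- (rx * d[j, 2] - ry * d[j, 1]) / den
      u <- (rx * d[i, 2] - ry * d[i, 1]) / den
      if (t <= -eps || t >= 1 + eps || u <= -eps || u >= 1 + eps) next
      if (t < eps || t > 1 - eps || u < eps || u > 1 - eps)
        return(NULL) # crossing at/near a vertex: redraw projection
      zi <- p[i, 3] + t * d[i, 3]
      zj <- p[j, 3] + u * d[j, 3]
      if (abs(zi - zj) < 1e-9) return(NULL)
      if (zi < zj) { # edge i passes under
        under_pos <- c(under_pos, i - 1 + t)
        over_pos <- c(over_pos, j - 1 + u)
        s <- sign(d[j, 1] * d[i, 2] - d[j, 2] * d[i, 1]) # cross(over, under)
      } else {
        under_pos <- c(under_pos, j - 1 + u)
        over_pos <- c(over_pos, i - 1 + t)
        s <- sign(d[i, 1] * d[j, 2] - d[i, 2] * d[j, 1])
      }
      sgn <- c(sgn, s)
    }
  }
  list(under = under_pos, over = over_pos, sign = sgn)
}

# Alexander matrix |det| at the given t from the crossing/generator diagram
kp_alexander_det <- function(cr, tval) {
  K <- length(cr$under)
  if (K < 3) return(1)
  ord <- order(cr$under)
  upos <- cr$under[ord]
  opos <- cr$over[ord]
  sgn <- cr$sign[ord]
  gen_of <- function(pos) {
    cnt <- sum(upos < pos)
    (cnt %% K) + 1
  }
  A <- matrix(0, K, K)
  for (k in 1:K) {
    k1 <- (k %% K) + 1
    i <- gen_of(opos[k])
    if (i == k || i == k1) {
      A[k, k] <- A[k, k] - 1
      A[k, k1] <- A[k, k1] + 1
    } else if (sgn[k] > 0) {
      A[k, k] <- 1; A[k, k1] <- -tval; A[k, i] <- tval - 1
    } else {
      A[k, k] <- -tval; A[k, k1] <- 1; A[k, i] <- tval - 1
    }
  }
  abs(det(A[-K, -K, drop = FALSE]))
}

#' Alexander determinants of a closed curve
#'
#' Projects the (KMT-simplified) ring onto a plane, enumerates crossings
#' with over/under assignment from depth, builds the Alexander matrix and
#' evaluates the absolute determinant at t = -1 and t = -2.  Degenerate
#' projections are discarded and redrawn from a fixed deterministic sequence
#' of rotations, so the result does not depend on a random stream.  The
#' value at t = -2 is defined up to a power of two by the diagram; the
#' reported value is reduced to its odd part, which is the invariant
#' |Delta(-2)| for all supported knot types.
#'
#' @param closed_polyline closed curve as an n x 3 matrix (closure edge
#'   implied between last and first vertex).
#' @param max_retry number of projection redraws before giving up.
#' @return integer vector `c(det1, det2)` = (|Delta(-1)|, odd part of
#'   |Delta(-2)|).
#' @export
alexander_determinants <- function(closed_polyline, max_retry = 40) {
  x <- kmt_simplify(as.matrix(closed_polyline), closed = TRUE)
  if (nrow(x) <= 3) return(c(1L, 1L))
  golden <- pi * (3 - sqrt(5))
  axes <- fib_sphere(64)
  for (k in seq_len(max_retry)) {
    R <- rot_about(axes[(k - 1) %% 64 + 1, ], golden * k + 0.1)
    cr <- kp_crossings(x %*% R)
    if (is.null(cr)) next
    d1 <- round(kp_alexander_det(cr, -1))
    d2 <- round(kp_alexander_det(cr, -2))
    while (d2 > 0 && d2 %% 2 == 0) d2 <- d2 / 2
    return(c(as.integer(d1), as.integer(d2)))
  }
  stop("no usable projection found after ", max_retry, " redraws")
}

# determinant pair -> label lookup for the supported knot set
kp_knot_table <- function() {
  list("0_1" = c(1L, 1L), "3_1" = c(3L, 7L), "4_1" = c(5L, 11L),
       "3_1#3_1" = c(9L, 49L))
}

#' Classify the knot type of a polyline
#'
#' Open inputs are closed with [minimally_interfering_closure()] first; the
#' Alexander determinant pair at t = -1, -2 is then looked up over the
#' supported set (unknot, trefoil, figure-eight, granny).  An unmatched pair
#' yields `"unknown"`.  Chirality is not resolved (Alexander determinants
#' are achiral).
#'
#' @param polyline n x 3 coordinate matrix.
#' @param closed is the input already a closed ring?
#' @return character label: `"0_1"`, `"3_1"`, `"4_1"`, `"3_1#3_1"`, or
#'   `"unknown"`.
#' @export
classify_knot <- function(polyline, closed = FALSE) {
  x <- as.matrix(polyline)
  if (nrow(x) < 5) return("0_1")
  if (!closed) x <- minimally_interfering_closure(x)
  dets <- alexander_determinants(x)
  tab <- kp_knot_table()
  for (lab in names(tab))
    if (all(dets == tab[[lab]])) return(lab)
  "unknown"
}
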