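# shared builders for small test systems

# straight ladder duplex along -z with an optional ss lead on the axis;
# exact rest geometry (bonds at r0, pairs at pair_r0, all angles straight)
straight_ladder <- function(nd = 8, n_lead = 0, ff = forcefield_params()) {
  b <- ff$bond_r0
  h <- ff$pair_r0 / 2
  zs <- -(seq_len(nd) - 1) * b - b / 2
  A <- cbind(0, 0, zs)
  B <- cbind(ff$pair_r0, 0, zs)
  lead <- if (n_lead > 0) cbind(0, 0, b / 2 + (n_lead - seq_len(n_lead)) * b)
  duplex_chain(rbind(lead, A, B),
               c(rep("lead", n_lead), rep("A", nd), rep("B", nd)))
}

# small curved duplex with jitter: generic configuration for gradient tests
toy_duplex <- function(nd = 6, n_lead = 4, jitter = 0.05, seed = 42,
                       ff = forcefield_params()) {
  set.seed(seed)
  cl <- cbind(0.3 * sin(seq_len(nd)), 0.3 * cos(seq_len(nd)), -seq_len(nd) * ff$bond_r0)
  st <- knotpore:::duplex_strands_from_centerline(cl, ff$pair_r0 / 2)
  lead <- cbind(0, 0, rev(seq_len(n_lead)) * ff$bond_r0)
  pos <- rbind(lead, st$A, st$B) + jitter * matrix(rnorm(3 * (n_lead + 2 * nd)),
                                                   ncol = 3)
  duplex_chain(pos, c(rep("lead", n_lead), rep("A", nd), rep("B", nd)))
}

# central-difference gradient of a scalar energy function of the chain
num_grad <- function(fun, chain, h = 1e-6) {
  g <- matrix(0, nrow(chain$pos), 3)
  for (i in seq_len(nrow(chain$pos))) {
    for (d in 1:3) {
      cp <- chain; cp$pos[i, d] <- cp$pos[i, d] + h
      cm <- chain; cm$pos[i, d] <- cm$pos[i, d] - h
      g[i, d] <- -(fun(cp) - fun(cm)) / (2 * h)
    }
  }
  g
}

# open knotted segment spliced between two straight arms (bond spacing 0.5);
# returns the polyline and the planted core bounds measured on the segment
planted_knot_chain <- function(n_before = 100, n_after = 450, type = "3_1") {
  ks <- build_tight_knot(type)
  seg <- knotpore:::orient_by_chord(ks$centerline)
  arc <- shortest_knotted_arc(seg, type, stride = 2)
  b <- 0.5
  before <- cbind(0, 0, (n_before:1) * b)
  seg <- sweep(seg, 2, c(0, 0, -b), `+`)
  exit <- seg[nrow(seg), ]
  after <- cbind(0, 0, -(seq_len(n_after)) * b)
  after <- sweep(after, 2, exit, `+`)
  list(chain = rbind(before, seg, after),
       k1 = n_before + arc$k1, k2 = n_before + arc$k2)
}

# do two 3D segment sets intersect anywhere (brute force, for closure tests)
segments_cross <- function(P, Q, tol = 1e-9) {
  # P, Q: lists of 2x3 matrices
  for (s1 in P) for (s2 in Q) {
    d1 <- s1[2, ] - s1[1, ]; d2 <- s2[2, ] - s2[1, ]
    r <- s2[1, ] - s1[1, ]
    cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
            d1[3] * d2[1] - d1[1] * d2[3],
            d1[1] * d2[2] - d1[2] * d2[1])
    den <- sum(cr^2)
    if (den < tol) next
    t <- sum((r[1] * (d2[2] * cr[3] - d2[3] * cr[2]) +
              r[2] * (d2[3] * cr[1] - d2[1] * cr[3]) +
              r[3] * (d2[1] * cr[2] - d2[2] * cr[1]))) / den
    u <- sum((r[1] * (d1[2] * cr[3] - d1[3] * cr[2]) +
              r[2] * (d1[3] * cr[1] - d1[1] * cr[3]) +
              r[3] * (d1[1] * cr[2] - d1[2] * cr[1]))) / den
    if (t > 1e-6 && t < 1 - 1e-6 && u > 1e-6 && u < 1 - 1e-6) {
      p1 <- s1[1, ] + t * d1; p2 <- s2[1, ] + u * d2
      if (sqrt(sum((p1 - p2)^2)) < 0.05) return(TRUE)
    }
  }
  FALSE
}
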