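# Implicit (signed-distance) description of the airway lumen: a lofted
# union of flat-ended cylinders around the centerline segments.  Creases at
# bifurcations are rounded by a smooth-union correction whose blend width is
# calibrated so that the maximum added material equals the depth of a true
# circular fillet: the carinal ridge between the two daughters gets the
# carinal radius r, the outer wall transition parent->daughter gets the
# outer curvature radius R.  Terminal ends (the inlet and the outlet tips)
# are cut flat by cap half-planes, optionally after extending the terminal
# axes (the extension supplies ghost-cell layers for boundary conditions).

# Signed distance from points (n x 3) to the flat-ended cylinder around
# segment row `s`, with the free (root / terminal) ends optionally extended
# along the axis.  Flat ends make the union of parent and daughter tubes a
# lofted junction: the daughters overlap each other just past the node, so
# the flow divider (carina) forms where their walls separate, without any
# spurious junction bulge.
.capsule_dist <- function(pts, s, extend = 0) {
  a <- c(s$ax, s$ay, s$az); b <- c(s$bx, s$by, s$bz); d <- c(s$dx, s$dy, s$dz)
  if (extend > 0) {
    if (s$parent == 0L) a <- a - extend * d
    if (s$terminal)     b <- b + extend * d
  }
  ab <- b - a
  L <- sqrt(sum(ab * ab))
  px <- pts[, 1] - a[1]; py <- pts[, 2] - a[2]; pz <- pts[, 3] - a[3]
  t <- (px * ab[1] + py * ab[2] + pz * ab[3]) / L
  qx <- px - (t / L) * ab[1]; qy <- py - (t / L) * ab[2]
  qz <- pz - (t / L) * ab[3]
  dr <- sqrt(qx * qx + qy * qy + qz * qz) - s$radius
  da <- abs(t - L / 2) - L / 2
  pmin(pmax(dr, da), 0) +
    sqrt(pmax(dr, 0)^2 + pmax(da, 0)^2)
}

# Smoothing pairs at every junction: (i, j, blend width k).
.smooth_pairs <- function(tree) {
  s <- tree$segments
  theta <- tree$bifurcation_angle * pi / 180
  pairs <- list()
  for (p in s$id[!s$terminal]) {
    kids <- s$id[s$parent == p]
    if (length(kids) != 2L) next
    r_car <- s$carinal_r[p]; R_out <- s$outer_R[p]
    if (!is.na(r_car) && theta > 0) {
      depth <- r_car * (1 / sin(theta / 2) - 1)
      pairs[[length(pairs) + 1L]] <- c(kids[1], kids[2], 4 * depth)
    }
    if (!is.na(R_out) && theta > 0) {
      depth <- R_out * (1 / sin(pi / 2 - theta / 4) - 1)
      for (k in kids)
        pairs[[length(pairs) + 1L]] <- c(p, k, 4 * depth)
    }
  }
  pairs
}

# Signed distance of the (smoothed, optionally cap-cut) lumen at `pts`.
# Returns a list: phi, nearest (segment id of nearest capsule), and when
# caps = TRUE the per-point cap membership (0 = none, else cap row index)
# with the signed depth beyond that cap plane.
.airway_phi <- function(pts, tree, extend = 0, caps = TRUE, smooth = TRUE,
                        chunk = 300000L) {
  stopifnot(is.matrix(pts), ncol(pts) == 3)
  n <- nrow(pts)
  out_phi <- numeric(n); out_near <- integer(n)
  out_cap <- integer(n); out_depth <- numeric(n)
  segs <- tree$segments
  pair_list <- if (smooth) .smooth_pairs(tree) else list()
  capdf <- tree$caps
  i0 <- 1L
  while (i0 <= n) {
    i1 <- min(i0 + chunk - 1L, n)
    P <- pts[i0:i1, , drop = FALSE]
    D <- matrix(0, nrow(P), nrow(segs))
    for (j in seq_len(nrow(segs)))
      D[, j] <- .capsule_dist(P, segs[j, ], extend = extend)
    near <- max.col(-D, ties.method = "first")
    phi <- D[cbind(seq_len(nrow(P)), near)]
    for (pr in pair_list) {
      k <- pr[3]
      if (k <= 0) next
      h <- pmax(k - abs(D[, pr[1]] - D[, pr[2]]), 0)
      # localize to the crease: fade the correction out away from the two
      # surfaces so that distant loci equidistant from both tubes (e.g. the
      # symmetry plane) are untouched
      gate <- pmax(1 - pmin(D[, pr[1]], D[, pr[2]]) / (3 * k), 0)^2
      phi <- phi - gate * h * h / (4 * k)
    }
    capid <- integer(nrow(P)); depth <- numeric(nrow(P))
    if (caps) {
      for (ci in seq_len(nrow(capdf))) {
        cp <- capdf[ci, ]
        # nanometre inset breaks exact ties when a lattice point falls on
        # the cap plane (the point then counts as inside the lumen)
        sdist <- (P[, 1] - cp$cx) * cp$nx + (P[, 2] - cp$cy) * cp$ny +
                 (P[, 3] - cp$cz) * cp$nz - 1e-9
        seg_col <- which(segs$id == cp$segment)
        rem <- pmin(sdist, -D[, seg_col])
        upd <- rem > phi
        phi[upd] <- rem[upd]
        beyond <- sdist > 0 & D[, seg_col] < 0
        capid[beyond] <- ci
        depth[beyond] <- sdist[beyond]
      }
    }
    out_phi[i0:i1] <- phi
    out_near[i0:i1] <- segs$id[near]
    out_cap[i0:i1] <- capid
    out_depth[i0:i1] <- depth
    i0 <- i1 + 1L
  }
  list(phi = out_phi, nearest = out_near, cap = out_cap, cap_depth = out_depth)
}

# Distance to the tube wall only (no cap cut), used for near-wall
# sub-cell corrections in the solver and for WSS recovery.
.wall_phi <- function(pts, tree, extend = 0) {
  .airway_phi(pts, tree, extend = extend, caps = FALSE)$phi
}

# Outward wall normal from central differences of the wall distance field.
.wall_normal <- function(pts, tree, eps) {
  n <- nrow(pts)
  g <- matrix(0, n, 3)
  for (ax in 1:3) {
    e <- matrix(0, n, 3); e[, ax] <- eps
    g[, ax] <- (.wall_phi(pts + e, tree, extend = eps * 4) -
                .wall_phi(pts - e, tree, extend = eps * 4)) / (2 * eps)
  }
  nrm <- sqrt(rowSums(g * g))
  nrm[nrm < 1e-12] <- 1
  g / nrm
}

# Bounding box of the tree lumen with margin (metres).
.tree_bbox <- function(tree, margin) {
  s <- tree$segments
  rmax <- max(s$radius)
  lo <- c(min(c(s$ax, s$bx)), min(c(s$ay, s$by)), min(c(s$az, s$bz))) -
    rmax - margin
  hi <- c(max(c(s$ax, s$bx)), max(c(s$ay, s$by)), max(c(s$az, s$bz))) +
    rmax + margin
  rbind(lo, hi)
}
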