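# Planar centerline skeleton of a symmetric dichotomously branching airway
# tree.  All coordinates are SI metres; the tree lies in the z = 0 plane with
# the root segment along +x.  The "right" daughter at every bifurcation is
# the one deviating towards negative y.

.rot_z <- function(v, angle_deg) {
  a <- angle_deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2], v[3])
}

# Build a tree from per-level dimension rows (SI metres).  `levels` is a
# data.frame with columns generation, L, D, R, r (R/r NA on the last level).
.tree_from_levels <- function(levels, bifurcation_angle, name = "tree") {
  nlev <- nrow(levels)
  segs <- list()
  # breadth-first construction; each entry: start point, direction, level
  queue <- list(list(start = c(0, 0, 0), dir = c(1, 0, 0), level = 1L,
                     parent = 0L, side = "root"))
  id <- 0L
  while (length(queue) > 0L) {
    item <- queue[[1L]]; queue <- queue[-1L]
    id <- id + 1L
    lv <- levels[item$level, ]
    b <- item$start + lv$L * item$dir
    segs[[id]] <- list(
      id = id, parent = item$parent, level = item$level,
      generation = lv$generation, a = item$start, b = b, dir = item$dir,
      L = lv$L, radius = lv$D / 2,
      outer_R = if (is.na(lv$R)) NA_real_ else lv$R,
      carinal_r = if (is.na(lv$r)) NA_real_ else lv$r,
      side = item$side,
      terminal = item$level == nlev
    )
    if (item$level < nlev) {
      half <- bifurcation_angle / 2
      # right daughter first (negative-y deviation), then left
      queue <- c(queue, list(
        list(start = b, dir = .rot_z(item$dir, -half), level = item$level + 1L,
             parent = id, side = "right"),
        list(start = b, dir = .rot_z(item$dir, +half), level = item$level + 1L,
             parent = id, side = "left")
      ))
    }
  }
  seg_df <- do.call(rbind, lapply(segs, function(s) data.frame(
    id = s$id, parent = s$parent, generation = s$generation,
    ax = s$a[1], ay = s$a[2], az = s$a[3],
    bx = s$b[1], by = s$b[2], bz = s$b[3],
    dx = s$dir[1], dy = s$dir[2], dz = s$dir[3],
    L = s$L, radius = s$radius, outer_R = s$outer_R, carinal_r = s$carinal_r,
    side = s$side, terminal = s$terminal
  )))
  # cap patches: inlet at the root start, one outlet per terminal tip,
  # ordered by segment id (left-to-right stable ordering)
  term <- seg_df[seg_df$terminal, ]
  caps <- rbind(
    data.frame(patch = "inlet", segment = seg_df$id[seg_df$parent == 0L],
               cx = 0, cy = 0, cz = 0,
               nx = -seg_df$dx[1], ny = -seg_df$dy[1], nz = -seg_df$dz[1],
               radius = seg_df$radius[1]),
    data.frame(patch = sprintf("outlet_%d", seq_len(nrow(term))),
               segment = term$id,
               cx = term$bx, cy = term$by, cz = term$bz,
               nx = term$dx, ny = term$dy, nz = term$dz,
               radius = term$radius)
  )
  structure(list(segments = seg_df, caps = caps,
                 bifurcation_angle = bifurcation_angle, name = name),
            class = "centerline_tree")
}

#' Centerline tree of a four-generation airway model
#'
#' Builds the planar (z = 0) centerline skeleton of the symmetric G6--G9
#' tree: a single root segment along +x followed by three levels of
#' bifurcations in which the two daughters deviate by plus/minus half the
#' bifurcation angle from the parent direction.  Table dimensions (mm) are
#' converted to metres here.
#'
#' @param profile An [build_profile()] / [interpolate_profile()] result.
#' @return An object of class `centerline_tree` with elements `segments`
#'   (data frame, one row per segment: endpoints `a`/`b`, unit direction,
#'   length, radius, bifurcation rounding radii, side label, terminal flag;
#'   all lengths in metres), `caps` (inlet and outlet cap planes) and
#'   `bifurcation_angle` (degrees).
#' @examples
#' tr <- build_centerline_tree(build_profile("infant"))
#' nrow(tr$segments) # 15
#' @export
build_centerline_tree <- function(profile) {
  stopifnot(inherits(profile, "age_profile"))
  levels <- data.frame(
    generation = profile$dims$generation,
    L = profile$dims$L * 1e-3, D = profile$dims$D * 1e-3,
    R = profile$dims$R * 1e-3, r = profile$dims$r * 1e-3
  )
  .tree_from_levels(levels, profile$bifurcation_angle, name = profile$name)
}

# Single straight tube as a degenerate one-segment tree (SI metres).
.straight_tube_tree <- function(L, D) {
  .tree_from_levels(
    data.frame(generation = 0L, L = L, D = D, R = NA_real_, r = NA_real_),
    bifurcation_angle = 0, name = "straight_tube"
  )
}

# Parent plus two daughters (SI metres); rounding radii on the parent.
.single_bifurcation_tree <- function(L_parent, D_parent, L_child, D_child,
                                     angle = 70, outer_R = NA, carinal_r = NA) {
  .tree_from_levels(
    data.frame(generation = 0:1,
               L = c(L_parent, L_child), D = c(D_parent, D_child),
               R = c(outer_R, NA), r = c(carinal_r, NA)),
    bifurcation_angle = angle, name = "single_bifurcation"
  )
}

#' @export
print.centerline_tree <- function(x, ...) {
  s <- x$segments
  cat(sprintf(
    "Centerline tree '%s': %d segments, %d outlets, bifurcation angle %g deg\n",
    x$name, nrow(s), sum(s$terminal), x$bifurcation_angle))
  path_len <- 0; id <- s$id[s$parent == 0L][1]
  while (length(id) == 1L && !is.na(id)) {
    path_len <- path_len + s$L[s$id == id]
    id <- s$id[s$parent == id & s$side == "right"][1]
  }
  cat(sprintf("Generations %s; root-to-tip axial path length %.3g mm\n",
              paste(range(s$generation), collapse = "-"), path_len * 1e3))
  invisible(x)
}

#' Probe geometry for a tree
#'
#' One mid-segment cross-section per segment (plane through the segment
#' midpoint, normal to its axis, with the local radius) plus five equispaced
#' interior points on the axis of the right (negative-y) branch one level
#' below the root -- for the G6--G9 models this is the right seventh
#' generation, the conventional flow path for mesh-independence probing.
#' For a single straight tube the probe line lies on the tube axis itself.
#'
#' @param tree A [build_centerline_tree()] result.
#' @param n_path_points Number of axis probe points (default 5).
#' @return An object of class `probe_set`: list with `mid_sections`
#'   (data frame: segment, center, normal, radius) and `path_points`
#'   (matrix n x 3, metres).
#' @export
make_probe_set <- function(tree, n_path_points = 5L) {
  stopifnot(inherits(tree, "centerline_tree"))
  s <- tree$segments
  mid <- data.frame(
    segment = s$id, generation = s$generation,
    cx = (s$ax + s$bx) / 2, cy = (s$ay + s$by) / 2, cz = (s$az + s$bz) / 2,
    nx = s$dx, ny = s$dy, nz = s$dz, radius = s$radius
  )
  cand <- s[s$side == "right", ]
  path_seg <- if (nrow(cand) > 0L) cand[1L, ] else s[1L, ]
  tfrac <- seq_len(n_path_points) / (n_path_points + 1)
  pts <- cbind(path_seg$ax + tfrac * (path_seg$bx - path_seg$ax),
               path_seg$ay + tfrac * (path_seg$by - path_seg$ay),
               path_seg$az + tfrac * (path_seg$bz - path_seg$az))
  colnames(pts) <- c("x", "y", "z")
  structure(list(mid_sections = mid, path_points = pts,
                 path_segment = path_seg$id),
            class = "probe_set")
}
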