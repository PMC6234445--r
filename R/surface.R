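# Triangulated, patch-labeled boundary surface of the airway lumen,
# extracted from the implicit model on a uniform lattice.

#' Watertight labeled airway surface
#'
#' Extracts the closed triangulated boundary of the airway lumen by marching
#' tetrahedra on the signed-distance field of the tree: circular tubes away
#' from bifurcations, fillet-rounded carinal ridges (radius `r`) and outer
#' wall transitions (radius `R`), flat end caps perpendicular to the local
#' centerline.  Triangles are labeled `inlet`, `outlet_k` or `wall`.
#'
#' @param tree A [build_centerline_tree()] result (or an internal fixture
#'   tree).
#' @param resolution Target surface edge length as a fraction of the smallest
#'   tube diameter (default 0.1, i.e. `D_min / 10`).
#' @return An object of class `airway_surface`: `vertices` (n x 3, metres),
#'   `triangles` (m x 3 vertex indices), `patch` (length-m character),
#'   `tree` (the generating model), `spacing` (lattice step, m).
#' @export
build_surface <- function(tree, resolution = 0.1) {
  stopifnot(inherits(tree, "centerline_tree"), resolution > 0)
  dmin <- 2 * min(tree$segments$radius)
  h <- resolution * dmin
  pairs <- .smooth_pairs(tree)
  kmax <- if (length(pairs)) max(vapply(pairs, `[`, 0, 3)) else 0
  bb <- .tree_bbox(tree, margin = 3 * h + kmax / 2)
  n <- pmax(ceiling((bb[2, ] - bb[1, ]) / h) + 1L, 2L)
  origin <- bb[1, ]
  xs <- origin[1] + (seq_len(n[1]) - 1) * h
  ys <- origin[2] + (seq_len(n[2]) - 1) * h
  zs <- origin[3] + (seq_len(n[3]) - 1) * h
  pts <- cbind(rep(xs, times = n[2] * n[3]),
               rep(rep(ys, each = n[1]), times = n[3]),
               rep(zs, each = n[1] * n[2]))
  phi <- .airway_phi(pts, tree)$phi
  mc <- .cpp_marching_tets(phi, as.integer(n), origin, h)
  V <- mc$vertices; Tr <- mc$triangles
  if (nrow(Tr) == 0L)
    stop("surface extraction produced no triangles; resolution too coarse")

  v1 <- V[Tr[, 1], , drop = FALSE]
  v2 <- V[Tr[, 2], , drop = FALSE]
  v3 <- V[Tr[, 3], , drop = FALSE]
  cent <- (v1 + v2 + v3) / 3
  tn <- cbind((v2[, 2] - v1[, 2]) * (v3[, 3] - v1[, 3]) -
              (v2[, 3] - v1[, 3]) * (v3[, 2] - v1[, 2]),
              (v2[, 3] - v1[, 3]) * (v3[, 1] - v1[, 1]) -
              (v2[, 1] - v1[, 1]) * (v3[, 3] - v1[, 3]),
              (v2[, 1] - v1[, 1]) * (v3[, 2] - v1[, 2]) -
              (v2[, 2] - v1[, 2]) * (v3[, 1] - v1[, 1]))
  tl <- sqrt(rowSums(tn^2)); tl[tl == 0] <- 1
  tn <- tn / tl
  patch <- rep("wall", nrow(Tr))
  capdf <- tree$caps
  for (ci in seq_len(nrow(capdf))) {
    cp <- capdf[ci, ]
    sdist <- (cent[, 1] - cp$cx) * cp$nx + (cent[, 2] - cp$cy) * cp$ny +
             (cent[, 3] - cp$cz) * cp$nz
    dx <- cent[, 1] - cp$cx; dy <- cent[, 2] - cp$cy; dz <- cent[, 3] - cp$cz
    ax <- dx * cp$nx + dy * cp$ny + dz * cp$nz
    rad <- sqrt(pmax(dx^2 + dy^2 + dz^2 - ax^2, 0))
    align <- tn[, 1] * cp$nx + tn[, 2] * cp$ny + tn[, 3] * cp$nz
    on_cap <- abs(sdist) < 0.9 * h & rad <= cp$radius + h & align > 0.3
    patch[on_cap] <- cp$patch
  }
  surf <- structure(
    list(vertices = V, triangles = Tr, patch = patch, tree = tree,
         spacing = h, resolution = resolution),
    class = "airway_surface")
  chk <- check_surface(surf)
  if (!chk$closed_manifold)
    stop("extracted surface is not a closed manifold; refine the resolution")
  if (!setequal(unique(patch), c("wall", capdf$patch)))
    stop("cap patch labeling incomplete; refine the resolution")
  surf
}

#' Surface integrity and size checks
#'
#' @param surface An [build_surface()] result.
#' @return List with `closed_manifold` (every undirected edge shared by
#'   exactly two triangles, consistently oriented), `volume` (signed enclosed
#'   volume, m^3; positive for outward orientation), `area` (total, m^2) and
#'   `patch_areas` (named, m^2).
#' @export
check_surface <- function(surface) {
  V <- surface$vertices; Tr <- surface$triangles
  e <- rbind(Tr[, c(1, 2)], Tr[, c(2, 3)], Tr[, c(3, 1)])
  undirected <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(undirected)
  manifold <- all(cnt == 2L)
  # consistent orientation: each directed edge appears exactly once
  directed <- paste(e[, 1], e[, 2])
  oriented <- manifold && !anyDuplicated(directed)
  a <- V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 2], , drop = FALSE]
  cc <- V[Tr[, 3], , drop = FALSE]
  cross <- cbind((b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) -
                 (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
                 (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) -
                 (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
                 (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
                 (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
  areas <- 0.5 * sqrt(rowSums(cross^2))
  vol <- sum(rowSums(a * cross)) / 6
  # cap areas projected onto their cap planes (the physically meaningful
  # inflow/outflow areas; rim chamfer triangles contribute their projection)
  proj <- setNames(numeric(0), character(0))
  if (!is.null(surface$tree)) {
    capdf <- surface$tree$caps
    nrm <- cross / (2 * pmax(areas, 1e-300))
    for (ci in seq_len(nrow(capdf))) {
      cp <- capdf[ci, ]
      sel <- surface$patch == cp$patch
      proj[cp$patch] <- sum(areas[sel] *
        abs(nrm[sel, 1] * cp$nx + nrm[sel, 2] * cp$ny + nrm[sel, 3] * cp$nz))
    }
  }
  list(closed_manifold = manifold && oriented,
       volume = vol, area = sum(areas),
       patch_areas = tapply(areas, surface$patch, sum),
       cap_areas_projected = proj)
}

#' @export
print.airway_surface <- function(x, ...) {
  chk <- check_surface(x)
  cat(sprintf(
    "Airway surface '%s': %d vertices, %d triangles, %d patches\n",
    x$tree$name, nrow(x$vertices), nrow(x$triangles),
    length(unique(x$patch))))
  cat(sprintf("Enclosed volume %.4g mm^3, area %.4g mm^2, closed manifold: %s\n",
              chk$volume * 1e9, chk$area * 1e6, chk$closed_manifold))
  invisible(x)
}

#' Export a surface to STL or VTK polydata
#'
#' STL is written binary (float32 coordinates); `vtk` writes legacy ASCII
#' VTK polydata with the patch label as integer cell data (readable by
#' standard VTK tooling).  A JSON sidecar `<path>.json` records the
#' generating model name, bifurcation angle and resolution.
#'
#' @param surface An [build_surface()] result.
#' @param path Output file path.
#' @param format `"stl"` or `"vtk"`.
#' @return `path`, invisibly.
#' @export
export_surface <- function(surface, path, format = c("stl", "vtk")) {
  format <- match.arg(format)
  V <- surface$vertices; Tr <- surface$triangles
  if (format == "stl") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(Tr)), con, size = 4, endian = "little")
    a <- V[Tr[, 1], , drop = FALSE]
    b <- V[Tr[, 2], , drop = FALSE]
    cc <- V[Tr[, 3], , drop = FALSE]
    nrm <- cbind((b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) -
                 (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
                 (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) -
                 (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
                 (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
                 (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    for (i in seq_len(nrow(Tr))) {
      writeBin(as.numeric(c(nrm[i, ], a[i, ], b[i, ], cc[i, ])), con,
               size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    lines <- c("# vtk DataFile Version 3.0", "airway surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(V)),
               apply(V, 1, function(r) paste(formatC(r, format = "g",
                                                     digits = 17),
                                             collapse = " ")),
               sprintf("POLYGONS %d %d", nrow(Tr), 4L * nrow(Tr)),
               apply(Tr - 1L, 1, function(r) paste(c(3L, r), collapse = " ")),
               sprintf("CELL_DATA %d", nrow(Tr)),
               "SCALARS patch int 1", "LOOKUP_TABLE default",
               as.character(match(surface$patch,
                                  c("wall", surface$tree$caps$patch)) - 1L))
    writeLines(lines, path)
  }
  meta <- list(model = surface$tree$name,
               bifurcation_angle = surface$tree$bifurcation_angle,
               resolution = surface$resolution, spacing = surface$spacing,
               format = format)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Re-import an exported surface
#'
#' @param path File written by [export_surface()].
#' @param format `"stl"` or `"vtk"`.
#' @return List with `vertices` and `triangles` (and `patch` for vtk).
#' @export
import_surface <- function(path, format = c("stl", "vtk")) {
  format <- match.arg(format)
  if (format == "stl") {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, raw(), 80)
    nt <- readBin(con, integer(), 1, size = 4, endian = "little")
    V <- matrix(0, 3 * nt, 3)
    Tr <- matrix(seq_len(3 * nt), nt, 3, byrow = TRUE)
    for (i in seq_len(nt)) {
      rec <- readBin(con, numeric(), 12, size = 4, endian = "little")
      readBin(con, raw(), 2)
      V[3 * i - 2, ] <- rec[4:6]
      V[3 * i - 1, ] <- rec[7:9]
      V[3 * i, ] <- rec[10:12]
    }
    list(vertices = V, triangles = Tr)
  } else {
    txt <- readLines(path)
    toks <- function(lines) {
      x <- unlist(strsplit(trimws(lines), "\\s+"))
      x[nzchar(x)]
    }
    ip <- grep("^POINTS", txt)
    np <- as.integer(strsplit(txt[ip], " ")[[1]][2])
    V <- matrix(as.numeric(toks(txt[(ip + 1):(ip + np)])), np, 3, byrow = TRUE)
    it <- grep("^POLYGONS", txt)
    ntri <- as.integer(strsplit(txt[it], " ")[[1]][2])
    Tm <- matrix(as.integer(toks(txt[(it + 1):(it + ntri)])),
                 ntri, 4, byrow = TRUE)
    il <- grep("^LOOKUP_TABLE", txt)
    lab <- NULL
    if (length(il) == 1L && length(txt) >= il + ntri)
      lab <- as.integer(txt[(il + 1):(il + ntri)])
    list(vertices = V, triangles = Tm[, 2:4, drop = FALSE] + 1L, patch = lab)
  }
}
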