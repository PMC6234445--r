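# Export of meshes, solutions and derived fields in formats readable by
# standard VTK / Gmsh tooling (legacy ASCII VTK; MSH 2.2).

#' Export a volume mesh
#'
#' `vtk` writes a legacy ASCII VTK unstructured grid of the fluid-cell
#' tetrahedra; `msh` writes Gmsh MSH 2.2 (nodes + 4-node tetrahedra).
#'
#' @param mesh A [generate_volume_mesh()] result.
#' @param path Output file.
#' @param format `"vtk"` or `"msh"`.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, format = c("vtk", "msh")) {
  format <- match.arg(format)
  tet <- mesh_tetrahedra(mesh)
  V <- tet$vertices; Tt <- tet$tetrahedra
  if (format == "vtk") {
    lines <- c("# vtk DataFile Version 3.0", "airway volume mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(V)),
               apply(V, 1, paste, collapse = " "),
               sprintf("CELLS %d %d", nrow(Tt), 5L * nrow(Tt)),
               apply(Tt - 1L, 1, function(r) paste(c(4L, r), collapse = " ")),
               sprintf("CELL_TYPES %d", nrow(Tt)),
               rep("10", nrow(Tt)))
    writeLines(lines, path)
  } else {
    lines <- c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", as.character(nrow(V)),
               paste(seq_len(nrow(V)),
                     V[, 1], V[, 2], V[, 3]),
               "$EndNodes",
               "$Elements", as.character(nrow(Tt)),
               paste(seq_len(nrow(Tt)), 4L, 2L, 0L, 1L,
                     Tt[, 1], Tt[, 2], Tt[, 3], Tt[, 4]),
               "$EndElements")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Import a Gmsh MSH 2.2 mesh (nodes and tetrahedra)
#'
#' @param path File written by [export_mesh()] with `format = "msh"`.
#' @return List with `vertices` and `tetrahedra`.
#' @export
import_msh <- function(path) {
  txt <- readLines(path)
  i0 <- match("$Nodes", txt); n <- as.integer(txt[i0 + 1])
  nd <- read.table(text = txt[(i0 + 2):(i0 + 1 + n)])
  i1 <- match("$Elements", txt); m <- as.integer(txt[i1 + 1])
  el <- read.table(text = txt[(i1 + 2):(i1 + 1 + m)])
  list(vertices = unname(as.matrix(nd[, 2:4])),
       tetrahedra = unname(as.matrix(el[, 6:9])))
}

#' Export a flow solution as legacy VTK structured points
#'
#' Writes the cell-centred velocity vector and gauge pressure on the full
#' lattice (zeros outside the fluid) plus the cell classification, readable
#' by standard VTK tooling.
#'
#' @param solution A [solve_steady()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_solution <- function(solution, path) {
  mesh <- solution$mesh
  d <- mesh$dims
  n <- prod(d)
  lines <- c("# vtk DataFile Version 3.0", "steady laminar airflow", "ASCII",
             "DATASET STRUCTURED_POINTS",
             sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
             sprintf("ORIGIN %g %g %g", mesh$origin[1], mesh$origin[2],
                     mesh$origin[3]),
             sprintf("SPACING %g %g %g", mesh$h, mesh$h, mesh$h),
             sprintf("POINT_DATA %d", n),
             "SCALARS pressure double 1", "LOOKUP_TABLE default",
             format(as.numeric(solution$p), trim = TRUE),
             "SCALARS celltype int 1", "LOOKUP_TABLE default",
             format(as.integer(mesh$celltype), trim = TRUE),
             "VECTORS velocity double",
             paste(format(as.numeric(solution$uc), trim = TRUE),
                   format(as.numeric(solution$vc), trim = TRUE),
                   format(as.numeric(solution$wc), trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' Export a wall field (wall shear stress and pressure) as VTK polydata
#'
#' @param wall_field A [wall_shear_stress()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_wall_field <- function(wall_field, path) {
  n <- nrow(wall_field)
  lines <- c("# vtk DataFile Version 3.0", "wall fields", "ASCII",
             "DATASET POLYDATA",
             sprintf("POINTS %d double", n),
             paste(wall_field$x, wall_field$y, wall_field$z),
             sprintf("VERTICES %d %d", n, 2L * n),
             paste(1L, seq_len(n) - 1L),
             sprintf("POINT_DATA %d", n),
             "SCALARS wss double 1", "LOOKUP_TABLE default",
             format(wall_field$wss, trim = TRUE),
             "SCALARS wall_pressure double 1", "LOOKUP_TABLE default",
             format(wall_field$pressure, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Export streamlines as VTK polydata polylines
#'
#' @param streamlines A [trace_streamlines()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_streamlines <- function(streamlines, path) {
  pts <- do.call(rbind, streamlines$lines)
  counts <- vapply(streamlines$lines, nrow, 0L)
  offs <- cumsum(c(0L, counts[-length(counts)]))
  lines <- c("# vtk DataFile Version 3.0", "streamlines", "ASCII",
             "DATASET POLYDATA",
             sprintf("POINTS %d double", nrow(pts)),
             paste(pts[, 1], pts[, 2], pts[, 3]),
             sprintf("LINES %d %d", length(counts), sum(counts) + length(counts)),
             vapply(seq_along(counts), function(i)
               paste(c(counts[i], seq_len(counts[i]) - 1L + offs[i]),
                     collapse = " "), ""))
  writeLines(lines, path)
  invisible(path)
}
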