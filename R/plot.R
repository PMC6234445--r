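# Basic visualization helpers (quick-look figures, not publication plots).

#' Midplane speed contour of a flow solution
#'
#' Filled contour of the velocity magnitude on the z = 0 midplane (the
#' bifurcation plane), walls masked.
#'
#' @param x A [solve_steady()] result.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.flow_solution <- function(x, ...) {
  mesh <- x$mesh
  k0 <- which.min(abs(mesh$origin[3] + (seq_len(mesh$dims[3]) - 1) * mesh$h))
  sl <- x$speed[, , k0]
  ct <- array(mesh$celltype, mesh$dims)[, , k0]
  sl[ct != 0L] <- NA
  xs <- (mesh$origin[1] + (seq_len(mesh$dims[1]) - 1) * mesh$h) * 1e3
  ys <- (mesh$origin[2] + (seq_len(mesh$dims[2]) - 1) * mesh$h) * 1e3
  graphics::image(xs, ys, sl, asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("|v| (m/s), midplane, %s %s",
                                 mesh$tree$name, x$bcs$phase),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Computed-versus-published comparison chart for a study report
#'
#' Grouped bars of the computed maximum velocities against the published
#' values per age and phase.
#'
#' @param x A [run_study()] report.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.study_report <- function(x, ...) {
  df <- as.data.frame(x)
  lab <- paste(substr(df$age, 1, 2), substr(df$phase, 1, 4))
  m <- rbind(computed = df$max_velocity, published = df$reference_max_velocity)
  graphics::barplot(m, beside = TRUE, names.arg = lab, las = 2,
                    ylab = "max |v| (m/s)",
                    legend.text = rownames(m),
                    main = "Maximum velocity by age and phase")
  invisible(x)
}
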