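# Shared, lazily computed fixtures.  Flow solves are the expensive part of
# the suite, so each configuration is solved once and reused across test
# files (test_dir runs files in one process).

.bf_cache <- new.env(parent = emptyenv())

bf_cached <- function(key, expr) {
  if (!exists(key, envir = .bf_cache)) {
    assign(key, force(expr), envir = .bf_cache)
  }
  get(key, envir = .bf_cache)
}

# Straight tube at creeping flow (entrance effects negligible): the
# Poiseuille verification fixture.  Q gives Re ~ 1.3.
tube_fixture <- function(cells_per_d = 12) {
  bf_cached(paste0("tube", cells_per_d), {
    fx <- make_fixture("straight_tube", L = 0.010, D = 0.002, Q = 3e-8)
    surf <- build_surface(fx$tree)
    mesh <- generate_volume_mesh(surf, 0.002 / cells_per_d, n_layers = 3L)
    bc <- bronchoflow:::.bc_flow_at(mesh, "inlet", fx$params$Q %||% 3e-8)
    sol <- solve_steady(mesh, bc)
    list(fixture = fx, surface = surf, mesh = mesh, solution = sol,
         probe_set = make_probe_set(fx$tree), Q = 3e-8)
  })
}

# Developed-region axial pressure gradient of a tube solution, expressed as
# an equivalent full-length drop (the Poiseuille comparison measure: the
# entrance region is excluded).
tube_gradient_drop <- function(tube, L = 0.010) {
  sol <- tube$solution
  mesh <- sol$mesh
  dims <- mesh$dims
  ct <- array(mesh$celltype == 0L, dims)
  pmean <- vapply(seq_len(dims[1]), function(i)
    if (any(ct[i, , ])) mean(sol$p[i, , ][ct[i, , ]]) else NA_real_, 0)
  x <- mesh$origin[1] + (seq_len(dims[1]) - 1) * mesh$h
  w <- which(x > 0.3 * L & x < 0.9 * L & !is.na(pmean))
  -unname(coef(lm(pmean[w] ~ x[w]))[2]) * L
}

# The six-case study at the coarse acceptance resolution, solved once.
study_fixture <- function() {
  bf_cached("study6", run_study(study_config(cells_per_dmin = 6)))
}

# A single coarse infant inspiration case (quick postprocess target).
infant_fixture <- function() {
  bf_cached("infant1", {
    rep <- study_fixture()
    attr(rep, "cases")[["infant_inspiration"]]
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
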