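# Age-specific airway dimensions and breathing parameters (embedded
# morphometric tables for the three reference ages).

# Per-generation airway dimensions, millimetres.  L = segment length,
# D = inner diameter, R = outer-wall transition (curvature) radius at the
# downstream bifurcation, r = carinal ridge rounding radius.  G9 is terminal
# in the four-generation window, so it carries no bifurcation radii.
.airway_dims <- list(
  infant = data.frame(
    generation = 6:9,
    L = c(3.5, 2.9, 2.5, 2.1),
    D = c(1.0, 0.9, 0.7, 0.6),
    R = c(1.8, 1.4, 1.2, NA),
    r = c(0.09, 0.07, 0.06, NA)
  ),
  child = data.frame(
    generation = 6:9,
    L = c(5.6, 4.7, 4.0, 3.3),
    D = c(1.8, 1.5, 1.2, 1.0),
    R = c(3.0, 2.4, 2.0, NA),
    r = c(0.15, 0.12, 0.10, NA)
  ),
  adult = data.frame(
    generation = 6:9,
    L = c(8.8, 7.4, 6.3, 5.3),
    D = c(2.8, 2.3, 1.8, 1.5),
    R = c(4.6, 3.6, 3.0, NA),
    r = c(0.23, 0.18, 0.15, NA)
  )
)

# Normal-breathing parameters per age group: tidal volume (mL), respiratory
# rate (breaths/min) and the inspiration:expiration time ratio.
.breathing_params <- list(
  infant = list(tidal_volume = 39,  respiratory_rate = 36, ie_ratio = c(1, 1.5)),
  child  = list(tidal_volume = 181, respiratory_rate = 20, ie_ratio = c(1, 1.7)),
  adult  = list(tidal_volume = 500, respiratory_rate = 14, ie_ratio = c(1, 1.7))
)

# Reference ages (years) of the three anchor profiles, used for
# age-continuous interpolation.
.anchor_ages <- c(infant = 0.5, child = 5, adult = 25)

.new_age_profile <- function(name, dims, pattern, bifurcation_angle = 70,
                             age_years = NA_real_) {
  stopifnot(nrow(dims) == 4L, all(dims$generation == 6:9))
  if (any(diff(dims$D) >= 0))
    stop("airway diameter must decrease strictly with generation")
  if (any(!is.na(dims$r) & dims$r >= dims$D / 2))
    stop("carinal radius r must be smaller than the airway radius D/2")
  if (any(dims$L <= 0) || any(dims$D <= 0) ||
      any(!is.na(dims$R) & dims$R <= 0) || any(!is.na(dims$r) & dims$r <= 0))
    stop("all airway dimensions must be strictly positive")
  structure(
    list(name = name, dims = dims, bifurcation_angle = bifurcation_angle,
         pattern = pattern, age_years = age_years),
    class = "age_profile"
  )
}

#' Airway model profile for a reference age group
#'
#' Returns the per-generation dimensions (G6--G9), the bifurcation angle and
#' the normal-breathing parameters of one of the three reference age groups.
#' Dimensions are stored in millimetres exactly as tabulated; conversion to
#' SI metres happens when a centerline tree is built.
#'
#' @param name `"infant"` (6 months), `"child"` (5 years) or `"adult"`
#'   (25 years).
#' @return An object of class `age_profile`: a list with elements `name`,
#'   `dims` (data frame with columns `generation`, `L`, `D`, `R`, `r`, in mm;
#'   `R` and `r` are `NA` for the terminal generation G9),
#'   `bifurcation_angle` (degrees, 70), `pattern` (a [breathing_pattern()])
#'   and `age_years`.
#' @examples
#' p <- build_profile("infant")
#' p$dims
#' @seealso [interpolate_profile()] for intermediate ages.
#' @export
build_profile <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.airway_dims))
    stop("unknown age-group name: must be one of ",
         paste(names(.airway_dims), collapse = ", "))
  bp <- .breathing_params[[name]]
  .new_age_profile(
    name, .airway_dims[[name]],
    breathing_pattern(bp$tidal_volume, bp$respiratory_rate, bp$ie_ratio),
    age_years = unname(.anchor_ages[name])
  )
}

#' Interpolated airway profile for an arbitrary age
#'
#' Piecewise-linear per-field interpolation of airway dimensions and
#' breathing parameters between the anchor ages 0.5 y (infant), 5 y (child)
#' and 25 y (adult).  At an anchor age the anchor profile is returned
#' exactly.  Intended as a generator of synthetic intermediate-age models;
#' only the three anchors are backed by tabulated data.
#'
#' @param age_years Age in years, in `[0.5, 25]`.
#' @return An `age_profile` (see [build_profile()]).
#' @examples
#' interpolate_profile(15)$dims$D[1] # G6 diameter at 15 y: 2.3 mm
#' @export
interpolate_profile <- function(age_years) {
  stopifnot(is.numeric(age_years), length(age_years) == 1L, is.finite(age_years))
  if (age_years < 0.5 || age_years > 25)
    stop("age_years must lie in [0.5, 25]")
  anchors <- names(.anchor_ages)
  hit <- anchors[abs(.anchor_ages - age_years) < 1e-12]
  if (length(hit) == 1L) return(build_profile(hit))
  hi <- if (age_years < .anchor_ages["child"]) "child" else "adult"
  lo <- if (hi == "child") "infant" else "child"
  w <- unname((age_years - .anchor_ages[lo]) /
              (.anchor_ages[hi] - .anchor_ages[lo]))
  lerp <- function(a, b) a + w * (b - a)
  dims <- .airway_dims[[lo]]
  dims$L <- lerp(.airway_dims[[lo]]$L, .airway_dims[[hi]]$L)
  dims$D <- lerp(.airway_dims[[lo]]$D, .airway_dims[[hi]]$D)
  dims$R <- lerp(.airway_dims[[lo]]$R, .airway_dims[[hi]]$R)
  dims$r <- lerp(.airway_dims[[lo]]$r, .airway_dims[[hi]]$r)
  blo <- .breathing_params[[lo]]; bhi <- .breathing_params[[hi]]
  pat <- breathing_pattern(
    lerp(blo$tidal_volume, bhi$tidal_volume),
    lerp(blo$respiratory_rate, bhi$respiratory_rate),
    c(1, lerp(blo$ie_ratio[2] / blo$ie_ratio[1], bhi$ie_ratio[2] / bhi$ie_ratio[1]))
  )
  .new_age_profile(sprintf("age_%g", age_years), dims, pat,
                   age_years = age_years)
}

#' @export
print.age_profile <- function(x, ...) {
  cat(sprintf("Airway profile '%s' (G6-G9, bifurcation angle %g deg)\n",
              x$name, x$bifurcation_angle))
  print(x$dims, row.names = FALSE)
  p <- x$pattern
  cat(sprintf("Breathing: VT %g mL, RR %g /min, I:E = 1:%.2g\n",
              p$tidal_volume, p$respiratory_rate, p$ie_ratio[2]))
  invisible(x)
}
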