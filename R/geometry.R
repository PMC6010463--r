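#' Concentric-shell geometry of a spherical microtumor
#'
#' Partitions a sphere of radius `r_outer` into three compartments: a central
#' core (radius `r_core`), an inner shell (`r_core`--`r_inner`) and an outer
#' shell (`r_inner`--`r_outer`), surrounded by an extracellular bath. Shell
#' volumes use the closed form \eqn{\frac{4}{3}\pi (r_2^3 - r_1^3)} and
#' interface areas \eqn{4 \pi r^2}. The defaults (300, 450, 600 um) describe a
#' 600 um radius spheroid with equal-thickness proliferative shells around a
#' nutrient-starved core.
#'
#' The extracellular bath is given a nominal volume (by default the volume of
#' a sphere of radius `r_outer`). Because the extracellular nutrient is
#' clamped at a fixed concentration in the models built on this geometry, the
#' bath volume cancels out of every transport flux and never affects the
#' dynamics; it only fixes the bookkeeping copy number of the clamped pool.
#'
#' @param r_core core radius (um).
#' @param r_inner outer radius of the inner shell (um); must exceed `r_core`.
#' @param r_outer outer radius of the spheroid (um); must exceed `r_inner`.
#' @param v_extracellular nominal bath volume (um^3); defaults to the volume
#'   of a sphere of radius `r_outer`.
#'
#' @return An object of class `mt_geometry`: a list with the three radii,
#'   `shell_volumes` (named `c`, `i`, `o`, in um^3), `interface_areas`
#'   (named `c|i`, `i|o`, `o|e`, in um^2) and `v_extracellular`.
#'
#' @examples
#' g <- build_geometry()
#' g$shell_volumes
#' sum(g$shell_volumes) - 4 / 3 * pi * 600^3  # partition is exact
#' @export
build_geometry <- function(r_core = 300, r_inner = 450, r_outer = 600,
                           v_extracellular = NULL) {
  radii <- c(r_core, r_inner, r_outer)
  if (!is.numeric(radii) || length(radii) != 3L || !all(is.finite(radii)))
    stop("radii must be finite numbers", call. = FALSE)
  if (any(radii <= 0))
    stop("radii must be positive", call. = FALSE)
  if (!(r_core < r_inner && r_inner < r_outer))
    stop("radii must be strictly increasing: r_core < r_inner < r_outer",
         call. = FALSE)
  sphere_vol <- function(r) 4 / 3 * pi * r^3
  shell_volumes <- c(
    c = sphere_vol(r_core),
    i = sphere_vol(r_inner) - sphere_vol(r_core),
    o = sphere_vol(r_outer) - sphere_vol(r_inner)
  )
  interface_areas <- c(
    "c|i" = 4 * pi * r_core^2,
    "i|o" = 4 * pi * r_inner^2,
    "o|e" = 4 * pi * r_outer^2
  )
  if (is.null(v_extracellular)) v_extracellular <- sphere_vol(r_outer)
  if (!is.numeric(v_extracellular) || length(v_extracellular) != 1L ||
      !is.finite(v_extracellular) || v_extracellular <= 0)
    stop("v_extracellular must be a positive number", call. = FALSE)
  structure(
    list(
      r_core = r_core, r_inner = r_inner, r_outer = r_outer,
      shell_volumes = shell_volumes,
      interface_areas = interface_areas,
      v_extracellular = v_extracellular
    ),
    class = "mt_geometry"
  )
}

#' Surface-area-adjusted first-order transport constants
#'
#' Converts a membrane permeability into directional first-order rate
#' constants for molecule exchange across the three compartment interfaces.
#' The convention is `k = permeability * interface_area / source_volume`,
#' applied to copy numbers, so that the flux across an interface is
#' `permeability * area * concentration(source)` and pure diffusion
#' equilibrates concentrations (not copy numbers) between compartments.
#'
#' @param geometry an [`mt_geometry`][build_geometry] object.
#' @param base_permeability permeability (um per time unit); must be >= 0.
#'
#' @return A data frame with one row per directed edge (six rows): columns
#'   `interface`, `from`, `to`, `area`, and the rate constant `k`
#'   (per time unit).
#'
#' @examples
#' scale_transport_rates(build_geometry(), 1)
#' @export
scale_transport_rates <- function(geometry, base_permeability) {
  stopifnot(inherits(geometry, "mt_geometry"))
  if (!is.numeric(base_permeability) || length(base_permeability) != 1L ||
      !is.finite(base_permeability) || base_permeability < 0)
    stop("base_permeability must be a single non-negative number",
         call. = FALSE)
  vols <- c(geometry$shell_volumes, e = unname(geometry$v_extracellular))
  edges <- data.frame(
    interface = c("c|i", "c|i", "i|o", "i|o", "o|e", "o|e"),
    from      = c("c",   "i",   "i",   "o",   "o",   "e"),
    to        = c("i",   "c",   "o",   "i",   "e",   "o"),
    stringsAsFactors = FALSE
  )
  edges$area <- unname(geometry$interface_areas[edges$interface])
  edges$k <- base_permeability * edges$area / unname(vols[edges$from])
  edges
}

#' @export
print.mt_geometry <- function(x, ...) {
  cat("Microtumor geometry (concentric shells)\n")
  cat(sprintf("  radii (um): core %g | inner %g | outer %g\n",
              x$r_core, x$r_inner, x$r_outer))
  cat(sprintf("  shell volumes (um^3): c %.4e, i %.4e, o %.4e\n",
              x$shell_volumes["c"], x$shell_volumes["i"],
              x$shell_volumes["o"]))
  cat(sprintf("  interface areas (um^2): c|i %.4e, i|o %.4e, o|e %.4e\n",
              x$interface_areas["c|i"], x$interface_areas["i|o"],
              x$interface_areas["o|e"]))
  invisible(x)
}
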