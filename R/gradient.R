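# Comparison of compartment profiles within and across model variants.

mt_profile_values <- function(p) {
  if (inherits(p, "mt_profile")) return(p$values)
  if (is.numeric(p) && length(p) == 3L) {
    if (is.null(names(p))) names(p) <- c("o", "i", "c")
    return(p[c("o", "i", "c")])
  }
  stop("expected an mt_profile or a length-3 numeric (o, i, c)",
       call. = FALSE)
}

#' Monotonicity of a compartment profile along the radial axis
#'
#' Classifies a profile as strictly or weakly monotone in the stated
#' direction. `toward_core_decreasing` requires `o > i > c` (the nutrient
#' pattern), `toward_core_increasing` the reverse (the inhibitor pattern).
#' Strict monotonicity additionally requires each step to exceed
#' `tol * max(profile)`.
#'
#' @param profile an [`mt_profile`][normalize_to_outer] or named numeric
#'   `(o, i, c)`.
#' @param direction `"toward_core_decreasing"` or `"toward_core_increasing"`.
#' @param tol relative margin below which a step counts as a tie.
#' @return List with `direction`, `strict`, `weak`, and `margin` (the
#'   smallest step in the stated direction, negative if violated).
#' @export
check_monotone <- function(profile,
                           direction = c("toward_core_decreasing",
                                         "toward_core_increasing"),
                           tol = 1e-9) {
  direction <- match.arg(direction)
  v <- mt_profile_values(profile)
  steps <- if (direction == "toward_core_decreasing")
    c(v[["o"]] - v[["i"]], v[["i"]] - v[["c"]])
  else
    c(v[["i"]] - v[["o"]], v[["c"]] - v[["i"]])
  margin <- min(steps)
  list(direction = direction,
       strict = margin > tol * max(abs(v)),
       weak = margin >= -tol * max(abs(v)),
       margin = margin)
}

#' Elementwise equality of two compartment profiles
#'
#' Compares two outer-normalized profiles, reporting the maximum elementwise
#' relative deviation `|a - b| / max(|a|, |b|)` and whether it is within
#' `rtol`.
#'
#' @param a,b profiles ([`mt_profile`][normalize_to_outer] or named numeric
#'   `(o, i, c)`).
#' @param rtol relative tolerance.
#' @return List with `equal` (logical) and `max_rel_dev`.
#' @export
profile_equality <- function(a, b, rtol = 1e-6) {
  va <- mt_profile_values(a); vb <- mt_profile_values(b)
  denom <- pmax(abs(va), abs(vb))
  dev <- ifelse(denom > 0, abs(va - vb) / denom, 0)
  list(equal = all(dev <= rtol), max_rel_dev = max(dev))
}

#' Compare steady-state profiles of the M1 and M2 model variants
#'
#' Computes outer-normalized profiles of NU, KI67 and PHGDH for both
#' variants, their per-compartment deltas (second minus first argument), and
#' the named qualitative verdicts: preservation of the decreasing nutrient
#' gradient in both variants, comparability of the KI67 profiles within a
#' loose tolerance, and suppression of normalized PHGDH in the M2 inner
#' layer and core, with the core value at most `suppression_factor` times
#' its M1 counterpart. INH is excluded from the deltas because its M1
#' profile (identically zero) has no outer-layer normalization.
#'
#' @param res_m1,res_m2 [`mt_sim`][simulate_model] results for the two
#'   variants; both must have reached steady state.
#' @param ki67_rtol tolerance for the KI67 comparability verdict.
#' @param suppression_factor threshold for the core-suppression verdict
#'   (an operational convention; the underlying claim is directional).
#' @return Object of class `mt_comparison`: list with `profiles` (per
#'   species, per variant), `deltas` (species x compartment matrix) and
#'   `verdicts` (named logicals).
#' @export
compare_variants <- function(res_m1, res_m2, ki67_rtol = 0.1,
                             suppression_factor = 0.5) {
  for (r in list(res_m1, res_m2)) {
    if (!inherits(r, "mt_sim")) stop("inputs must be mt_sim results",
                                     call. = FALSE)
    if (!r$reached_steady_state)
      stop("simulation has not reached steady state", call. = FALSE)
  }
  species <- c("NU", "KI67", "PHGDH")
  profiles <- lapply(stats::setNames(species, species), function(sp)
    list(first = normalize_to_outer(res_m1, sp),
         second = normalize_to_outer(res_m2, sp)))
  deltas <- t(vapply(species, function(sp)
    profiles[[sp]]$second$values - profiles[[sp]]$first$values,
    numeric(3)))
  colnames(deltas) <- c("o", "i", "c")
  ph1 <- profiles$PHGDH$first$values
  ph2 <- profiles$PHGDH$second$values
  verdicts <- c(
    nu_gradient_preserved =
      check_monotone(profiles$NU$first, "toward_core_decreasing")$strict &&
      check_monotone(profiles$NU$second, "toward_core_decreasing")$strict,
    ki67_comparable =
      profile_equality(profiles$KI67$first, profiles$KI67$second,
                       rtol = ki67_rtol)$equal,
    phgdh_inner_suppressed = ph2[["i"]] < ph1[["i"]],
    phgdh_core_suppressed =
      ph2[["c"]] <= suppression_factor * ph1[["c"]]
  )
  structure(list(profiles = profiles, deltas = deltas, verdicts = verdicts,
                 ki67_rtol = ki67_rtol,
                 suppression_factor = suppression_factor),
            class = "mt_comparison")
}

#' @export
print.mt_comparison <- function(x, ...) {
  cat("Variant comparison (deltas = second - first, outer-normalized)\n")
  print(round(x$deltas, 4))
  cat("verdicts:\n")
  for (n in names(x$verdicts))
    cat(sprintf("  %-24s %s\n", n, x$verdicts[[n]]))
  invisible(x)
}

#' Sweep rate constants and collect normalized steady-state profiles
#'
#' Simulates the model over the Cartesian grid of the supplied constant
#' values and returns a long table with one row per grid point, species and
#' compartment. Species whose outer-layer abundance is zero at a grid point
#' (e.g. INH in M1) get `NA` normalized values.
#'
#' @param spec an [`mt_model`][build_model] object.
#' @param grid named list mapping rate-constant ids to value vectors; names
#'   must exist in `spec$rate_constants` and values must be non-negative.
#' @param ... passed on to [simulate_model()].
#' @return Data frame with the grid columns plus `species`, `compartment`,
#'   `normalized`; zero rows for an empty grid.
#' @export
parameter_sweep <- function(spec, grid, ...) {
  validate_model(spec)
  if (!is.list(grid))
    stop("grid must be a named list of value vectors", call. = FALSE)
  species <- c("NU", "KI67", "PHGDH", "INH")
  comps <- c("o", "i", "c")
  empty <- data.frame(species = character(0), compartment = character(0),
                      normalized = numeric(0))
  if (length(grid) == 0L) return(empty)
  unknown <- setdiff(names(grid), names(spec$rate_constants))
  if (length(unknown))
    stop("unknown rate constant(s) in grid: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(vapply(grid, function(v) any(v < 0), logical(1))))
    stop("grid values must be non-negative", call. = FALSE)
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  if (nrow(points) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(points)), function(ip) {
    sp2 <- spec
    sp2$rate_constants[names(points)] <- as.numeric(points[ip, ])
    res <- simulate_model(sp2, ...)
    ss <- res$steady_state
    norm <- unlist(lapply(species, function(s) {
      v <- ss[paste0(s, "_", comps)]
      if (v[1] > 0) as.numeric(v / v[1]) else rep(NA_real_, 3)
    }))
    cbind(points[rep(ip, length(species) * length(comps)), , drop = FALSE],
          data.frame(species = rep(species, each = length(comps)),
                     compartment = rep(comps, times = length(species)),
                     normalized = norm))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
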