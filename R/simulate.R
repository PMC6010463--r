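# Mass-action ODE derivation and steady-state integration.

#' Derive mass-action rate functions from a model specification
#'
#' Converts a model's rule inventory into a stoichiometry matrix and a
#' mass-action rate vector: each rule contributes a flux
#' `k * prod(reactant abundances)`, multiplied, where an inhibitor is
#' attached, by `1 / (1 + ([INH]/K_I)^hill)` with `[INH]` the inhibitor copy
#' number divided by its compartment volume. Catalytic rules list the
#' catalyst on both sides, so its net stoichiometry is zero. First-order
#' decay entries in the model's `decay` slot are appended as additional sink
#' columns. Clamped species get identically zero derivatives.
#'
#' @param spec an [`mt_model`][build_model] object.
#' @return A list of class `mt_rates` with elements `state_ids`,
#'   `stoichiometry` (species x flux matrix), `fluxes(x)` returning the flux
#'   vector at state `x`, and `deriv(t, x, parms)` in the form accepted by
#'   [deSolve::lsoda()].
#' @examples
#' rt <- derive_rates(build_model("M2"))
#' d <- rt$deriv(0, initial_state(build_model("M2")), NULL)[[1]]
#' @export
derive_rates <- function(spec) {
  validate_model(spec)
  ids <- mt_state_ids
  k <- spec$rate_constants
  vols <- c(spec$geometry$shell_volumes,
            e = unname(spec$geometry$v_extracellular))
  n_rule <- length(spec$rules)
  n_decay <- length(spec$decay)
  S <- matrix(0, length(ids), n_rule + n_decay,
              dimnames = list(ids, NULL))
  react_idx <- vector("list", n_rule + n_decay)
  kval <- numeric(n_rule + n_decay)
  inh_idx <- rep(NA_integer_, n_rule)
  inh_ki <- rep(NA_real_, n_rule)
  inh_vol <- rep(NA_real_, n_rule)
  for (j in seq_len(n_rule)) {
    r <- spec$rules[[j]]
    for (s in r$reactants) S[s, j] <- S[s, j] - 1
    for (s in r$products) S[s, j] <- S[s, j] + 1
    react_idx[[j]] <- match(r$reactants, ids)
    kval[j] <- k[[r$k]]
    if (!is.null(r$inhibitor)) {
      inh_idx[j] <- match(r$inhibitor$species, ids)
      inh_ki[j] <- k[[r$inhibitor$k_i]]
      inh_vol[j] <-
        vols[[mt_split_species(r$inhibitor$species)$compartment]]
    }
  }
  for (d in seq_len(n_decay)) {
    j <- n_rule + d
    sp <- names(spec$decay)[d]
    S[sp, j] <- -1
    react_idx[[j]] <- match(sp, ids)
    kval[j] <- k[[spec$decay[[d]]]]
  }
  clamped_idx <- match(spec$clamped, ids)
  hill <- spec$hill
  has_inh <- which(!is.na(inh_idx))
  fluxes <- function(x) {
    x <- pmax(x, 0)
    v <- numeric(length(kval))
    for (j in seq_along(kval)) {
      v[j] <- kval[j] * prod(x[react_idx[[j]]])
    }
    for (j in has_inh) {
      conc <- x[inh_idx[j]] / inh_vol[j]
      if (conc > 0 && inh_ki[j] > 0) {
        v[j] <- v[j] / (1 + (conc / inh_ki[j])^hill)
      } else if (inh_ki[j] == 0 && conc > 0) {
        v[j] <- 0  # infinitely potent inhibitor
      }
    }
    v
  }
  deriv <- function(t, x, parms) {
    dx <- as.vector(S %*% fluxes(x))
    dx[clamped_idx] <- 0
    list(dx)
  }
  structure(
    list(state_ids = ids, stoichiometry = S, fluxes = fluxes, deriv = deriv,
         clamped_idx = clamped_idx),
    class = "mt_rates"
  )
}

#' Default initial state for a model
#'
#' Seed abundances of all microtumor species are zero; the clamped
#' extracellular nutrient pool starts (and stays) at
#' `conc_nu_e * v_extracellular` copy numbers, i.e. at the clamped
#' concentration.
#'
#' @param spec an [`mt_model`][build_model] object.
#' @return Named numeric vector over the 13 state variables.
#' @export
initial_state <- function(spec) {
  x <- stats::setNames(numeric(length(mt_state_ids)), mt_state_ids)
  x["NU_e"] <- spec$rate_constants[["conc_nu_e"]] *
    spec$geometry$v_extracellular
  x
}

#' Integrate a microtumor model to steady state
#'
#' Integrates the mass-action ODE system with the stiff-capable [deSolve]
#' `lsoda` solver from the default all-zero microtumor seed state, sampling
#' the trajectory on a log-spaced time grid, and evaluates the steady-state
#' criterion along the way: the earliest sampled time from which
#' `max_s |dx_s/dt| / max(x_s, floor)` stays below `steady_tol` for every
#' state variable.
#'
#' Small negative excursions from the solver (relative magnitude below
#' `1e-12` of the largest abundance) are clipped to zero with a warning;
#' larger ones are an error.
#'
#' @param spec an [`mt_model`][build_model] object.
#' @param t_end integration horizon in time units (default 600000).
#' @param initial optional named initial state; defaults to
#'   [initial_state()].
#' @param steady_tol steady-state threshold on the relative rate of change,
#'   per time unit (default 1e-8).
#' @param floor abundance floor used in the relative-derivative denominator
#'   (default 1).
#' @param rtol,atol solver tolerances.
#' @param n_out number of sampled output times (log-spaced plus t = 0).
#'
#' @return Object of class `mt_sim`: list with `times`, `trajectories`
#'   (time x species matrix), `steady_state` (named abundances at `t_end`),
#'   `reached_steady_state`, `steady_state_time` (NA if never reached),
#'   `rel_deriv` (criterion statistic per sampled time) and the `spec`.
#'
#' @examples
#' \donttest{
#' res <- simulate_model(build_model("M2"))
#' res$reached_steady_state
#' }
#' @export
simulate_model <- function(spec, t_end = 6e5, initial = NULL,
                           steady_tol = 1e-8, floor = 1,
                           rtol = 1e-8, atol = 1e-10, n_out = 300) {
  validate_model(spec)
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("t_end must be a positive number", call. = FALSE)
  if (steady_tol <= 0 || rtol <= 0 || atol <= 0)
    stop("tolerances must be positive", call. = FALSE)
  rt <- derive_rates(spec)
  x0 <- initial_state(spec)
  if (!is.null(initial)) {
    if (is.null(names(initial)) || !all(names(initial) %in% mt_state_ids))
      stop("initial must be named with known species ids", call. = FALSE)
    x0[names(initial)] <- initial
  }
  if (any(x0 < 0)) stop("initial abundances must be non-negative",
                        call. = FALSE)
  times <- c(0, exp(seq(log(max(t_end * 1e-7, 1e-3)), log(t_end),
                        length.out = n_out - 1L)))
  out <- deSolve::lsoda(y = x0, times = times, func = rt$deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed; last time reached ", max(out[, "time"]),
         call. = FALSE)
  traj <- out[, mt_state_ids, drop = FALSE]
  neg_floor <- 1e-12 * max(1, max(abs(traj)))
  if (any(traj < -neg_floor))
    stop("negative abundances beyond tolerance (min ", min(traj), ")",
         call. = FALSE)
  if (any(traj < 0)) {
    warning("clipping small negative solver excursions to zero")
    traj[traj < 0] <- 0
  }
  rel <- apply(traj, 1, function(x) {
    dx <- rt$deriv(0, x, NULL)[[1]]
    max(abs(dx) / pmax(x, floor))
  })
  ok_from <- rev(cumprod(rev(rel < steady_tol))) > 0
  ss_time <- if (any(ok_from)) times[which(ok_from)[1]] else NA_real_
  structure(
    list(
      times = times, trajectories = traj,
      steady_state = traj[nrow(traj), ],
      reached_steady_state = !is.na(ss_time),
      steady_state_time = ss_time,
      rel_deriv = rel,
      steady_tol = steady_tol, floor = floor,
      spec = spec
    ),
    class = "mt_sim"
  )
}

#' Earliest steady-state entry time of a trajectory
#'
#' Returns the earliest sampled time from which the maximum relative rate of
#' change `|dx/dt| / max(x, floor)` of every state variable stays below
#' `tol`. For an [`mt_sim`][simulate_model] result the derivative is
#' re-evaluated exactly from the model's rate laws; for a plain list with
#' `times` and `trajectories` (matrix with one column per variable) central
#' finite differences are used.
#'
#' @param result an `mt_sim` object or `list(times=, trajectories=)`.
#' @param tol relative-rate threshold per time unit.
#' @param floor abundance floor in the denominator.
#' @return The entry time, or `NA` if the criterion is never satisfied.
#' @export
steady_state_time <- function(result, tol = 1e-8, floor = 1) {
  if (inherits(result, "mt_sim")) {
    rt <- derive_rates(result$spec)
    times <- result$times
    rel <- apply(result$trajectories, 1, function(x) {
      dx <- rt$deriv(0, x, NULL)[[1]]
      max(abs(dx) / pmax(x, floor))
    })
  } else {
    times <- result$times
    traj <- as.matrix(result$trajectories)
    if (length(times) < 2L) stop("need at least 2 time points", call. = FALSE)
    n <- length(times)
    idx <- 2:(n - 1L)
    dd <- (traj[idx + 1L, , drop = FALSE] - traj[idx - 1L, , drop = FALSE]) /
      (times[idx + 1L] - times[idx - 1L])
    rel <- c(NA, apply(abs(dd) / pmax(traj[idx, , drop = FALSE], floor),
                       1, max), NA)
    # endpoints: one-sided differences
    rel[1] <- max(abs(traj[2, ] - traj[1, ]) / (times[2] - times[1]) /
                    pmax(traj[1, ], floor))
    rel[n] <- max(abs(traj[n, ] - traj[n - 1L, ]) /
                    (times[n] - times[n - 1L]) / pmax(traj[n, ], floor))
  }
  ok_from <- rev(cumprod(rev(rel < tol))) > 0
  if (any(ok_from)) times[which(ok_from)[1]] else NA_real_
}

#' Outer-layer-normalized compartment profile of a species
#'
#' Divides the steady-state abundance of a species in the outer, inner and
#' core compartments by its outer-layer value, the normalization used to
#' compare species across compartments.
#'
#' @param result an [`mt_sim`][simulate_model] object.
#' @param species one of `"NU"`, `"KI67"`, `"PHGDH"`, `"INH"`.
#' @return Object of class `mt_profile`: list with `species` and `values`
#'   (named `o`, `i`, `c`; `values["o"]` is 1).
#' @export
normalize_to_outer <- function(result, species = c("NU", "KI67", "PHGDH",
                                                   "INH")) {
  species <- match.arg(species)
  if (!inherits(result, "mt_sim")) stop("result must be an mt_sim",
                                        call. = FALSE)
  ss <- result$steady_state
  v <- ss[paste0(species, "_", c("o", "i", "c"))]
  if (!is.finite(v[1]) || v[1] <= 0)
    stop("profile undefined: outer-layer abundance of ", species,
         " is not positive", call. = FALSE)
  structure(
    list(species = species,
         values = stats::setNames(as.numeric(v / v[1]), c("o", "i", "c"))),
    class = "mt_profile"
  )
}

#' Direct steady-state solution of the linear nutrient subsystem
#'
#' When PHGDH-catalysed nutrient synthesis and inhibitor expression are
#' switched off (`k_syn_nu_* = 0`, `k_exp_inh_c = 0`), the nutrient
#' balance decouples into a linear 3-variable system: diffusion between
#' shells, influx from the clamped extracellular pool, and first-order
#' consumption by KI67 and PHGDH expression. This solves that balance
#' directly with [solve()], independent of the ODE integrator, for use as a
#' cross-check.
#'
#' @param spec an [`mt_model`][build_model] object whose `k_syn_nu_*` (and,
#'   for M2, `k_exp_inh_c`) constants are zero.
#' @return Named vector of steady-state NU copy numbers in `o`, `i`, `c`.
#' @export
steady_state_nu_linear <- function(spec) {
  validate_model(spec)
  k <- spec$rate_constants
  if (any(k[c("k_syn_nu_o", "k_syn_nu_i", "k_syn_nu_c")] != 0))
    stop("linear solution requires k_syn_nu_* = 0", call. = FALSE)
  has_inh <- any(vapply(spec$rules, function(r)
    r$kind == "production" && any(grepl("^INH_", r$products)),
    logical(1))) && k[["k_exp_inh_c"]] > 0
  if (has_inh)
    stop("linear solution requires inhibitor expression off", call. = FALSE)
  nu_e <- k[["conc_nu_e"]] * spec$geometry$v_extracellular
  cons <- function(s) k[[paste0("k_exp_ki67_", s)]] +
    k[[paste0("k_exp_phgdh_", s)]]
  cons_c <- cons("c") +
    if (spec$variant == "M2") k[["k_exp_inh_c"]] else 0
  A <- rbind(
    c(-(k[["k_tr_nu_o_e"]] + k[["k_tr_nu_o_i"]] + cons("o")),
      k[["k_tr_nu_i_o"]], 0),
    c(k[["k_tr_nu_o_i"]],
      -(k[["k_tr_nu_i_o"]] + k[["k_tr_nu_i_c"]] + cons("i")),
      k[["k_tr_nu_c_i"]]),
    c(0, k[["k_tr_nu_i_c"]], -(k[["k_tr_nu_c_i"]] + cons_c))
  )
  b <- c(-k[["k_tr_nu_e_o"]] * nu_e, 0, 0)
  stats::setNames(as.numeric(solve(A, b)),
                  c("NU_o", "NU_i", "NU_c"))
}

#' @export
print.mt_sim <- function(x, ...) {
  cat(sprintf("Microtumor simulation (%s), t_end = %g\n",
              x$spec$variant, max(x$times)))
  cat(sprintf("  steady state reached: %s (entry time %s, tol %g)\n",
              x$reached_steady_state,
              format(x$steady_state_time), x$steady_tol))
  ss <- x$steady_state
  for (sp in c("NU", "KI67", "PHGDH", "INH")) {
    v <- ss[paste0(sp, "_", c("o", "i", "c"))]
    cat(sprintf("  %-5s o/i/c: %.4g / %.4g / %.4g\n", sp, v[1], v[2], v[3]))
  }
  invisible(x)
}

#' @export
print.mt_profile <- function(x, ...) {
  cat(sprintf("%s compartment profile (outer-normalized): o=%.4g i=%.4g c=%.4g\n",
              x$species, x$values["o"], x$values["i"], x$values["c"]))
  invisible(x)
}
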