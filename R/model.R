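# Model construction: species inventory, default rate constants, rule table.

# Canonical state variables. NU lives in all four compartments; KI67, PHGDH
# and INH only inside the microtumor (o, i, c).
mt_state_ids <- c(
  "NU_e", "NU_o", "NU_i", "NU_c",
  "KI67_o", "KI67_i", "KI67_c",
  "PHGDH_o", "PHGDH_i", "PHGDH_c",
  "INH_o", "INH_i", "INH_c"
)

mt_compartments <- c("e", "o", "i", "c")

# Adjacency of compartments along the radial axis (for transport validation).
mt_adjacent <- list(e = "o", o = c("e", "i"), i = c("o", "c"), c = "i")

mt_split_species <- function(id) {
  m <- regmatches(id, regexec("^([A-Za-z0-9]+)_([eoic])$", id))[[1]]
  if (length(m) != 3L) return(NULL)
  list(name = m[2], compartment = m[3])
}

mt_rule <- function(id, kind, reactants, products, k, inhibitor = NULL) {
  structure(
    list(id = id, kind = kind, reactants = reactants, products = products,
         k = k, inhibitor = inhibitor),
    class = "mt_rule"
  )
}

#' Default rate-constant table
#'
#' Returns the packaged defaults for the 31 rate constants of the M2 model:
#' 26 one-per-rule constants (six NU transport, three KI67 expression, three
#' PHGDH expression, three PHGDH-catalysed NU synthesis, three KI67 and three
#' PHGDH degradation, one core INH expression, four INH transport), plus the
#' clamped extracellular NU concentration `conc_nu_e`, the inhibition constant
#' `K_I`, and three INH degradation constants.
#'
#' Transport constants are derived from the geometry by
#' [scale_transport_rates()] (`k = permeability * area / source volume`) with
#' nutrient permeability `perm_nu` and inhibitor permeability `perm_inh`.
#' Units are abstract: abundances are copy numbers, concentrations copy
#' numbers per um^3, time in model time units; no physical calibration is
#' implied. Expression and degradation defaults put consumption on the same
#' scale as inter-shell transport (so a clear nutrient gradient forms), make
#' the PHGDH-driven nutrient replenishment a small correction to the nutrient
#' budget, and place the steady-state core inhibitor concentration well above
#' `K_I` (strong core suppression of PHGDH expression).
#'
#' @param geometry an [`mt_geometry`][build_geometry] object.
#' @param perm_nu nutrient permeability (um per time unit).
#' @param perm_inh inhibitor permeability (um per time unit).
#'
#' @return Named numeric vector of length 31.
#' @examples
#' length(default_rate_constants())
#' @export
default_rate_constants <- function(geometry = build_geometry(),
                                   perm_nu = 1, perm_inh = 0.1) {
  tr_nu <- scale_transport_rates(geometry, perm_nu)
  tr_in <- scale_transport_rates(geometry, perm_inh)
  edge_k <- function(tab, from, to) tab$k[tab$from == from & tab$to == to]
  c(
    # -- 26 rule constants ---------------------------------------------------
    k_tr_nu_e_o = edge_k(tr_nu, "e", "o"),
    k_tr_nu_o_e = edge_k(tr_nu, "o", "e"),
    k_tr_nu_o_i = edge_k(tr_nu, "o", "i"),
    k_tr_nu_i_o = edge_k(tr_nu, "i", "o"),
    k_tr_nu_i_c = edge_k(tr_nu, "i", "c"),
    k_tr_nu_c_i = edge_k(tr_nu, "c", "i"),
    k_exp_ki67_o = 5e-3, k_exp_ki67_i = 5e-3, k_exp_ki67_c = 5e-3,
    k_exp_phgdh_o = 1e-3, k_exp_phgdh_i = 1e-3, k_exp_phgdh_c = 1e-3,
    k_syn_nu_o = 1e-7, k_syn_nu_i = 1e-7, k_syn_nu_c = 1e-7,
    k_deg_ki67_o = 1e-3, k_deg_ki67_i = 1e-3, k_deg_ki67_c = 1e-3,
    k_deg_phgdh_o = 1e-3, k_deg_phgdh_i = 1e-3, k_deg_phgdh_c = 1e-3,
    k_exp_inh_c = 2e-3,
    k_tr_inh_c_i = edge_k(tr_in, "c", "i"),
    k_tr_inh_i_c = edge_k(tr_in, "i", "c"),
    k_tr_inh_i_o = edge_k(tr_in, "i", "o"),
    k_tr_inh_o_i = edge_k(tr_in, "o", "i"),
    # -- 5 non-rule constants ------------------------------------------------
    conc_nu_e = 1,       # clamped extracellular NU concentration (per um^3)
    K_I = 0.02,          # inhibition constant (concentration units)
    k_deg_inh_o = 1e-3, k_deg_inh_i = 1e-3, k_deg_inh_c = 1e-3
  )
}

mt_build_rules <- function(variant) {
  shells <- c("o", "i", "c")
  rules <- list(
    mt_rule("R01", "transport", "NU_e", "NU_o", "k_tr_nu_e_o"),
    mt_rule("R02", "transport", "NU_o", "NU_e", "k_tr_nu_o_e"),
    mt_rule("R03", "transport", "NU_o", "NU_i", "k_tr_nu_o_i"),
    mt_rule("R04", "transport", "NU_i", "NU_o", "k_tr_nu_i_o"),
    mt_rule("R05", "transport", "NU_i", "NU_c", "k_tr_nu_i_c"),
    mt_rule("R06", "transport", "NU_c", "NU_i", "k_tr_nu_c_i")
  )
  n <- 6L
  for (s in shells) {
    n <- n + 1L
    rules[[n]] <- mt_rule(sprintf("R%02d", n), "production",
                          paste0("NU_", s), paste0("KI67_", s),
                          paste0("k_exp_ki67_", s))
  }
  for (s in shells) {
    n <- n + 1L
    rules[[n]] <- mt_rule(sprintf("R%02d", n), "production",
                          paste0("NU_", s), paste0("PHGDH_", s),
                          paste0("k_exp_phgdh_", s),
                          inhibitor = list(species = paste0("INH_", s),
                                           k_i = "K_I"))
  }
  for (s in shells) {
    n <- n + 1L
    rules[[n]] <- mt_rule(sprintf("R%02d", n), "catalytic_production",
                          paste0("PHGDH_", s),
                          c(paste0("PHGDH_", s), paste0("NU_", s)),
                          paste0("k_syn_nu_", s))
  }
  for (s in shells) {
    n <- n + 1L
    rules[[n]] <- mt_rule(sprintf("R%02d", n), "degradation",
                          paste0("KI67_", s), character(0),
                          paste0("k_deg_ki67_", s))
  }
  for (s in shells) {
    n <- n + 1L
    rules[[n]] <- mt_rule(sprintf("R%02d", n), "degradation",
                          paste0("PHGDH_", s), character(0),
                          paste0("k_deg_phgdh_", s))
  }
  rules[[22L]] <- mt_rule("R22", "production", "NU_c", "INH_c", "k_exp_inh_c")
  rules[[23L]] <- mt_rule("R23", "transport", "INH_c", "INH_i", "k_tr_inh_c_i")
  rules[[24L]] <- mt_rule("R24", "transport", "INH_i", "INH_c", "k_tr_inh_i_c")
  rules[[25L]] <- mt_rule("R25", "transport", "INH_i", "INH_o", "k_tr_inh_i_o")
  rules[[26L]] <- mt_rule("R26", "transport", "INH_o", "INH_i", "k_tr_inh_o_i")
  if (variant == "M1") {
    # M1 omits inhibitor expression; inert INH transport/decay terms remain so
    # the rate-constant table is shared across variants.
    rules <- rules[vapply(rules, function(r) r$id != "R22", logical(1))]
  }
  rules
}

#' Build a microtumor reaction model (variant M1 or M2)
#'
#' Assembles the compartmental reaction model: a clamped extracellular
#' nutrient pool, surface-area-adjusted nutrient diffusion through the three
#' shells, nutrient-consuming expression of KI67 and PHGDH in every shell,
#' PHGDH-catalysed nutrient synthesis, first-order degradation, and (in M2)
#' expression of a PHGDH-expression inhibitor in the core that is transported
#' between shells and cleared by first-order decay. PHGDH expression rules
#' carry a hyperbolic inhibition factor `1 / (1 + ([INH]/K_I)^hill)` in the
#' local inhibitor concentration.
#'
#' The default M2 build has exactly 26 reaction rules and 31 rate constants
#' (the 26 rule constants plus the clamped extracellular NU concentration,
#' `K_I`, and three INH decay constants carried in the `decay` slot). M1 is
#' M2 with the single INH expression rule removed; the inert INH transport
#' and decay entries remain, so both variants share one constant table.
#'
#' @param variant `"M1"` (no inhibitor expression) or `"M2"`.
#' @param geometry an [`mt_geometry`][build_geometry] object.
#' @param params optional named numeric vector overriding entries of
#'   [default_rate_constants()]; unknown names or negative values are errors.
#' @param hill Hill coefficient of the inhibition factor (default 1).
#'
#' @return An object of class `mt_model`: list with `variant`, `geometry`,
#'   `rules` (list of rule records), `rate_constants` (named, length 31),
#'   `decay` (named map species -> decay-constant id), `clamped` (species ids
#'   held constant) and `hill`.
#'
#' @examples
#' m2 <- build_model("M2")
#' length(m2$rules)            # 26
#' length(m2$rate_constants)   # 31
#' @export
build_model <- function(variant = c("M2", "M1"), geometry = build_geometry(),
                        params = NULL, hill = 1) {
  variant <- match.arg(variant)
  stopifnot(inherits(geometry, "mt_geometry"))
  constants <- default_rate_constants(geometry)
  if (!is.null(params)) {
    if (is.null(names(params)) || any(!nzchar(names(params))))
      stop("params must be a named numeric vector", call. = FALSE)
    unknown <- setdiff(names(params), names(constants))
    if (length(unknown))
      stop("unknown rate constant(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    constants[names(params)] <- params
  }
  if (!is.numeric(hill) || length(hill) != 1L || !is.finite(hill) || hill <= 0)
    stop("hill must be a single positive number", call. = FALSE)
  spec <- structure(
    list(
      variant = variant,
      geometry = geometry,
      rules = mt_build_rules(variant),
      rate_constants = constants,
      decay = c(INH_o = "k_deg_inh_o", INH_i = "k_deg_inh_i",
                INH_c = "k_deg_inh_c"),
      clamped = "NU_e",
      hill = hill
    ),
    class = "mt_model"
  )
  validate_model(spec)
  spec
}

#' Validate a microtumor model specification
#'
#' Checks structural invariants: known species and compartments, transport
#' only between adjacent compartments, production consuming local NU,
#' catalytic rules conserving the catalyst, inhibition only on PHGDH
#' expression, every referenced rate constant present and non-negative, and
#' the variant rules for INH expression (absent in M1, exactly one core rule
#' in M2).
#'
#' @param spec an `mt_model` object.
#' @return `spec`, invisibly, if valid; otherwise an error.
#' @export
validate_model <- function(spec) {
  if (!inherits(spec, "mt_model")) stop("not an mt_model", call. = FALSE)
  k <- spec$rate_constants
  if (is.null(names(k)) || anyDuplicated(names(k)))
    stop("rate constants must have unique names", call. = FALSE)
  if (!is.numeric(k) || any(!is.finite(k)))
    stop("rate constants must be finite numbers", call. = FALSE)
  if (any(k < 0))
    stop("negative rate constant(s): ",
         paste(names(k)[k < 0], collapse = ", "), call. = FALSE)
  need <- c(vapply(spec$rules, function(r) r$k, character(1)),
            unname(spec$decay), "conc_nu_e",
            unlist(lapply(spec$rules, function(r) r$inhibitor$k_i)))
  missing_k <- setdiff(need, names(k))
  if (length(missing_k))
    stop("rate constant(s) referenced but not defined: ",
         paste(unique(missing_k), collapse = ", "), call. = FALSE)
  for (r in spec$rules) {
    sp <- c(r$reactants, r$products)
    bad <- sp[!sp %in% mt_state_ids]
    if (length(bad))
      stop("rule ", r$id, ": unknown species ", paste(bad, collapse = ", "),
           call. = FALSE)
    comps <- vapply(sp, function(s) mt_split_species(s)$compartment,
                    character(1))
    if (r$kind == "transport") {
      if (length(r$reactants) != 1L || length(r$products) != 1L)
        stop("rule ", r$id, ": transport must move exactly one molecule",
             call. = FALSE)
      from <- comps[[1]]; to <- comps[[2]]
      if (!(to %in% mt_adjacent[[from]]))
        stop("rule ", r$id, ": transport between non-adjacent compartments ",
             from, " and ", to, call. = FALSE)
    } else if (length(unique(comps)) > 1L) {
      stop("rule ", r$id, ": non-transport rule spans compartments",
           call. = FALSE)
    }
    if (r$kind == "production") {
      nm <- vapply(r$reactants, function(s) mt_split_species(s)$name,
                   character(1))
      if (!identical(unname(nm), "NU"))
        stop("rule ", r$id, ": production must consume local NU",
             call. = FALSE)
    }
    if (r$kind == "catalytic_production" &&
        !all(r$reactants %in% r$products))
      stop("rule ", r$id, ": catalyst must be conserved", call. = FALSE)
    if (!is.null(r$inhibitor)) {
      prod_name <- mt_split_species(r$products[[1]])$name
      if (!(r$kind == "production" && prod_name == "PHGDH"))
        stop("rule ", r$id, ": inhibition only allowed on PHGDH production",
             call. = FALSE)
      if (!r$inhibitor$species %in% mt_state_ids)
        stop("rule ", r$id, ": unknown inhibitor species ",
             r$inhibitor$species, call. = FALSE)
    }
  }
  inh_prod <- Filter(function(r)
    length(r$products) && any(grepl("^INH_", r$products)) &&
      r$kind == "production", spec$rules)
  if (spec$variant == "M1" && length(inh_prod) != 0L)
    stop("M1 must not contain an INH production rule", call. = FALSE)
  if (spec$variant == "M2") {
    if (length(inh_prod) != 1L ||
        !identical(inh_prod[[1]]$products, "INH_c"))
      stop("M2 must contain exactly one INH production rule, in the core",
           call. = FALSE)
  }
  if (!all(spec$clamped %in% mt_state_ids))
    stop("unknown clamped species", call. = FALSE)
  invisible(spec)
}

#' @export
print.mt_model <- function(x, ...) {
  cat(sprintf("Microtumor compartment model, variant %s\n", x$variant))
  cat(sprintf("  %d reaction rules, %d rate constants\n",
              length(x$rules), length(x$rate_constants)))
  kinds <- table(vapply(x$rules, function(r) r$kind, character(1)))
  cat("  rules by kind: ",
      paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  clamped: %s (concentration %g)\n",
              paste(x$clamped, collapse = ", "),
              x$rate_constants[["conc_nu_e"]]))
  invisible(x)
}
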