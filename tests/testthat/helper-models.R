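# Shared fixtures: cached default simulations (several test files compare
# against the same steady states) and a hypercube sampler.

mt_cache <- new.env(parent = emptyenv())

default_sim <- function(variant) {
  key <- paste0("sim_", variant)
  if (is.null(mt_cache[[key]]))
    mt_cache[[key]] <- simulate_model(build_model(variant))
  mt_cache[[key]]
}

# Log-uniform multiplicative draw in [1/span, span] over the model's free
# parameters. Compartment copies of a parameter share one multiplier (they
# are a single parameter expressed per shell) and the transport constants
# are scaled jointly per species, equivalent to drawing the permeability,
# which preserves the surface-area adjustment.
mt_parameter_groups <- list(
  perm_nu = c("k_tr_nu_e_o", "k_tr_nu_o_e", "k_tr_nu_o_i",
              "k_tr_nu_i_o", "k_tr_nu_i_c", "k_tr_nu_c_i"),
  perm_inh = c("k_tr_inh_c_i", "k_tr_inh_i_c", "k_tr_inh_i_o",
               "k_tr_inh_o_i"),
  k_exp_ki67 = c("k_exp_ki67_o", "k_exp_ki67_i", "k_exp_ki67_c"),
  k_exp_phgdh = c("k_exp_phgdh_o", "k_exp_phgdh_i", "k_exp_phgdh_c"),
  k_syn_nu = c("k_syn_nu_o", "k_syn_nu_i", "k_syn_nu_c"),
  k_deg_ki67 = c("k_deg_ki67_o", "k_deg_ki67_i", "k_deg_ki67_c"),
  k_deg_phgdh = c("k_deg_phgdh_o", "k_deg_phgdh_i", "k_deg_phgdh_c"),
  k_deg_inh = c("k_deg_inh_o", "k_deg_inh_i", "k_deg_inh_c"),
  k_exp_inh = "k_exp_inh_c",
  conc_nu_e = "conc_nu_e",
  K_I = "K_I"
)

draw_constants <- function(defaults, span = 10) {
  out <- defaults
  for (ids in mt_parameter_groups) {
    mult <- 10^stats::runif(1, -log10(span), log10(span))
    out[ids] <- defaults[ids] * mult
  }
  out
}
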