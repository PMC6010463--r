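test_that("rate derivation implements mass action with conserved catalysts", {
  m <- build_model("M2")
  rt <- derive_rates(m)
  x <- initial_state(m)
  x[] <- 0
  x["NU_o"] <- 100
  dx <- setNames(rt$deriv(0, x, NULL)[[1]], rt$state_ids)
  k <- m$rate_constants
  # NU_o -> KI67_o contributes k * [NU_o] to KI67_o
  expect_equal(unname(dx["KI67_o"]), unname(k["k_exp_ki67_o"] * 100))
  # catalytic rule: PHGDH unchanged, NU gains k * [PHGDH]
  x2 <- x; x2[] <- 0; x2["PHGDH_c"] <- 50
  dx2 <- setNames(rt$deriv(0, x2, NULL)[[1]], rt$state_ids)
  expect_equal(unname(dx2["NU_c"]), unname(k["k_syn_nu_c"] * 50))
  expect_equal(unname(dx2["PHGDH_c"]),
               -unname(k["k_deg_phgdh_c"] * 50))
  # clamped species never moves
  expect_equal(unname(dx["NU_e"]), 0)
})

test_that("inhibition at [INH] = K_I exactly halves PHGDH production", {
  m <- build_model("M2")
  k <- m$rate_constants
  vol_o <- m$geometry$shell_volumes[["o"]]
  rt <- derive_rates(m)
  x <- initial_state(m); x[] <- 0
  x["NU_o"] <- 1000
  base <- setNames(rt$deriv(0, x, NULL)[[1]], rt$state_ids)["PHGDH_o"]
  x["INH_o"] <- k[["K_I"]] * vol_o  # concentration exactly K_I
  half <- setNames(rt$deriv(0, x, NULL)[[1]], rt$state_ids)["PHGDH_o"]
  expect_equal(unname(half), unname(base) / 2)
})

test_that("all-zero rates give an identically zero, immediately steady run", {
  zero <- setNames(rep(0, 31), names(default_rate_constants()))
  m <- build_model("M2", params = zero)
  res <- simulate_model(m, t_end = 100)
  expect_true(all(res$trajectories == 0))
  expect_true(res$reached_steady_state)
  expect_equal(res$steady_state_time, 0)
})

test_that("two-compartment pure diffusion relaxes to the analytic solution", {
  # keep only NU transport between inner and core (equal permeability),
  # kill everything else including exchange with outer/extracellular
  p <- default_rate_constants()
  p[] <- 0
  g <- build_geometry()
  p["k_tr_nu_i_c"] <- 0.01
  p["k_tr_nu_c_i"] <- 0.01  # equal volumes not needed; equal ks chosen
  m <- build_model("M2", params = p)
  x0 <- c(NU_i = 2, NU_c = 0)
  res <- simulate_model(m, t_end = 2000, initial = x0, atol = 1e-12)
  # closed form: u(t) = 1 + e^{-2kt}, v(t) = 1 - e^{-2kt}
  u <- res$trajectories[, "NU_i"]
  v <- res$trajectories[, "NU_c"]
  expect_equal(u, 1 + exp(-0.02 * res$times), tolerance = 1e-6)
  expect_equal(v, 1 - exp(-0.02 * res$times), tolerance = 1e-6)
  # copy number conserved at every sampled step
  expect_equal(unname(u + v), rep(2, length(u)), tolerance = 1e-8)
})

test_that("with production and degradation off, total NU is conserved", {
  p <- default_rate_constants()
  p[grep("k_exp|k_syn|k_deg", names(p))] <- 0
  p["k_tr_nu_e_o"] <- 0  # close the system off from the clamped bath
  p["k_tr_nu_o_e"] <- 0
  m <- build_model("M2", params = p)
  x0 <- c(NU_o = 5e6, NU_i = 1e6, NU_c = 3e6)
  res <- simulate_model(m, t_end = 1e5, initial = x0)
  total <- rowSums(res$trajectories[, c("NU_o", "NU_i", "NU_c")])
  expect_equal(total, rep(9e6, length(total)), tolerance = 1e-7)
})

test_that("trajectories stay non-negative across random parameter draws", {
  set.seed(421)
  defaults <- default_rate_constants()
  for (rep in 1:10) {
    p <- draw_constants(defaults, span = 10)
    res <- simulate_model(build_model("M2", params = p))
    expect_true(all(res$trajectories >= 0))
  }
})

test_that("steady-state entry time matches the analytic value for e^-t", {
  times <- seq(0, 40, by = 0.01)
  traj <- matrix(exp(-times), ncol = 1)
  t_ss <- steady_state_time(list(times = times, trajectories = traj),
                            tol = 1e-8, floor = 1)
  expect_equal(t_ss, log(1e8), tolerance = 3e-3)
  # constant trajectory: steady from the start
  flat <- matrix(1, nrow = 5, ncol = 2)
  expect_equal(steady_state_time(list(times = 0:4, trajectories = flat)), 0)
  # sustained oscillation never settles
  osc <- matrix(2 + sin(seq(0, 200, by = 0.1)), ncol = 1)
  expect_true(is.na(steady_state_time(
    list(times = seq(0, 200, by = 0.1), trajectories = osc))))
})

test_that("integrator steady state matches the direct linear solution", {
  p <- c(k_syn_nu_o = 0, k_syn_nu_i = 0, k_syn_nu_c = 0, k_exp_inh_c = 0)
  m <- build_model("M2", params = p)
  direct <- steady_state_nu_linear(m)
  res <- simulate_model(m)
  expect_equal(res$steady_state[c("NU_o", "NU_i", "NU_c")], direct,
               tolerance = 1e-6)
  # guard rails: the linear solution refuses nonlinear models
  expect_error(steady_state_nu_linear(build_model("M2")), "k_syn")
})

test_that("normalization to the outer layer behaves and fails as specified", {
  res <- default_sim("M2")
  pr <- normalize_to_outer(res, "NU")
  expect_equal(unname(pr$values["o"]), 1)
  expect_true(all(pr$values >= 0))
  ss <- res$steady_state
  expect_equal(unname(pr$values["i"]), unname(ss["NU_i"] / ss["NU_o"]))
  # M1 INH is identically zero: profile undefined
  expect_error(normalize_to_outer(default_sim("M1"), "INH"), "undefined")
})

test_that("clamped extracellular nutrient is constant over the trajectory", {
  res <- default_sim("M2")
  nu_e <- res$trajectories[, "NU_e"]
  expect_equal(unname(nu_e), rep(nu_e[1], length(nu_e)))
  expect_equal(unname(nu_e[1]),
               res$spec$rate_constants[["conc_nu_e"]] *
                 res$spec$geometry$v_extracellular)
})
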