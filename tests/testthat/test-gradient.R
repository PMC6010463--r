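test_that("monotonicity classification separates strict, weak and none", {
  dec <- check_monotone(c(o = 1, i = 0.4, c = 0.1), "toward_core_decreasing")
  expect_true(dec$strict)
  flat <- check_monotone(c(o = 1, i = 1, c = 1), "toward_core_decreasing")
  expect_false(flat$strict)
  expect_true(flat$weak)
  inc <- check_monotone(c(o = 1, i = 2, c = 5), "toward_core_increasing")
  expect_true(inc$strict)
  broken <- check_monotone(c(o = 1, i = 2, c = 0.5),
                           "toward_core_decreasing")
  expect_false(broken$weak)
  expect_lt(broken$margin, 0)
})

test_that("default M1 shows the nutrient gradient and exact correlation", {
  res <- default_sim("M1")
  expect_true(check_monotone(normalize_to_outer(res, "NU"),
                             "toward_core_decreasing")$strict)
  eq <- profile_equality(normalize_to_outer(res, "KI67"),
                         normalize_to_outer(res, "PHGDH"), rtol = 1e-6)
  expect_true(eq$equal)
})

test_that("default M2 shows an opposing inhibitor gradient", {
  res <- default_sim("M2")
  expect_true(check_monotone(normalize_to_outer(res, "NU"),
                             "toward_core_decreasing")$strict)
  expect_true(check_monotone(normalize_to_outer(res, "INH"),
                             "toward_core_increasing")$strict)
  # PHGDH no longer tracks KI67: suppressed in inner layer and core
  ki <- normalize_to_outer(res, "KI67")$values
  ph <- normalize_to_outer(res, "PHGDH")$values
  eq <- profile_equality(ki, ph, rtol = 1e-6)
  expect_false(eq$equal)
  expect_lt(ph[["i"]], ki[["i"]])
  expect_lt(ph[["c"]], ki[["c"]])
})

test_that("profile equality reports exact agreement and deviations", {
  a <- c(o = 1, i = 0.5, c = 0.2)
  expect_equal(profile_equality(a, a)$max_rel_dev, 0)
  b <- c(o = 1, i = 0.55, c = 0.2)
  eq <- profile_equality(a, b, rtol = 1e-6)
  expect_false(eq$equal)
  expect_equal(eq$max_rel_dev, 0.05 / 0.55)
})

test_that("variant comparison delivers the expected verdicts and deltas", {
  cmp <- compare_variants(default_sim("M1"), default_sim("M2"))
  expect_true(all(cmp$verdicts))
  expect_lt(cmp$deltas["PHGDH", "c"], 0)
  expect_lt(cmp$deltas["PHGDH", "i"], 0)
  # comparing a result with itself: zero deltas, trivially true verdicts
  self <- compare_variants(default_sim("M2"), default_sim("M2"),
                           suppression_factor = 1)
  expect_true(all(abs(self$deltas) == 0))
  # swapping arguments negates the deltas
  swapped <- compare_variants(default_sim("M2"), default_sim("M1"),
                              suppression_factor = 1)
  expect_equal(swapped$deltas, -cmp$deltas)
})

test_that("M2 with inhibitor production off reduces to M1", {
  res_m1 <- default_sim("M1")
  res_m2off <- simulate_model(build_model("M2",
                                          params = c(k_exp_inh_c = 0)))
  for (sp in c("NU", "KI67", "PHGDH")) {
    eq <- profile_equality(normalize_to_outer(res_m1, sp),
                           normalize_to_outer(res_m2off, sp), rtol = 1e-6)
    expect_true(eq$equal, label = paste(sp, "profile equality"))
  }
  cmp <- compare_variants(res_m1, res_m2off, suppression_factor = 1)
  expect_true(all(abs(cmp$deltas) < 1e-6))
})

test_that("parameter sweep enumerates the grid and tracks suppression", {
  m2 <- build_model("M2")
  grid <- list(k_exp_inh_c = c(0.5e-3, 1e-3, 2e-3, 4e-3, 8e-3))
  tab <- parameter_sweep(m2, grid)
  expect_equal(nrow(tab), 5 * 4 * 3)
  expect_setequal(unique(tab$species), c("NU", "KI67", "PHGDH", "INH"))
  # stronger inhibitor production monotonically deepens core suppression
  ph_c <- tab$normalized[tab$species == "PHGDH" & tab$compartment == "c"]
  expect_equal(ph_c, sort(ph_c, decreasing = TRUE))
  expect_true(all(diff(ph_c) < 0))
  # plumbing corners
  expect_equal(nrow(parameter_sweep(m2, list())), 0)
  expect_error(parameter_sweep(m2, list(k_nope = 1)), "unknown")
  expect_error(parameter_sweep(m2, list(k_exp_inh_c = -1)), "non-negative")
})

test_that("qualitative verdicts persist over a +/-10x parameter hypercube", {
  set.seed(2203)
  defaults <- default_rate_constants()
  for (rep in 1:8) {
    p <- draw_constants(defaults, span = 10)
    r1 <- simulate_model(build_model("M1", params = p))
    r2 <- simulate_model(build_model("M2", params = p))
    eq <- profile_equality(normalize_to_outer(r1, "KI67"),
                           normalize_to_outer(r1, "PHGDH"), rtol = 1e-6)
    expect_true(eq$equal, label = sprintf("draw %d M1 equality", rep))
    ki <- normalize_to_outer(r2, "KI67")$values
    ph <- normalize_to_outer(r2, "PHGDH")$values
    expect_lt(ph[["i"]], ki[["i"]])
    expect_lt(ph[["c"]], ki[["c"]])
  }
})
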