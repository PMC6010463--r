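test_that("linescans on a uniform image are flat at the pixel value", {
  img <- array(42, dim = c(101, 101, 2))
  ls <- radial_linescans(img, n_lines = 5, n_bins = 10)
  expect_true(all(ls$profile$ch1 == 42))
  expect_true(all(ls$profile$ch2 == 42))
  expect_error(radial_linescans(img, center = c(500, 50)), "inside")
})

test_that("linescans recover the step profile of a zero-noise ring image", {
  tr <- ring_truth(noise_sd = c(0, 0), background = 0)
  g <- generate_microtumor_image(tr)
  n_bins <- 22
  ls <- radial_linescans(g$image, tr$center, tr$radius, n_lines = 9,
                         n_bins = n_bins)
  bin_frac <- (ls$profile$bin - 0.5) / n_bins
  # plateau bins (more than one bin away from a boundary) hit ring means
  for (ch in rownames(tr$channel_means)) {
    vals <- ls$profile[[ch]]
    means <- tr$channel_means[ch, ]
    expected <- ifelse(bin_frac < tr$boundaries[1], means["c"],
                       ifelse(bin_frac < tr$boundaries[2], means["i"],
                              means["o"]))
    interior <- abs(bin_frac - tr$boundaries[1]) > 1.5 / n_bins &
      abs(bin_frac - tr$boundaries[2]) > 1.5 / n_bins
    expect_equal(vals[interior], unname(expected[interior]))
  }
})

test_that("9 rays agree with 360 rays on a rotationally symmetric image", {
  tr <- ring_truth(noise_sd = c(0, 0))
  g <- generate_microtumor_image(tr)
  n_bins <- 20
  a <- radial_linescans(g$image, tr$center, tr$radius, n_lines = 9,
                        n_bins = n_bins)
  b <- radial_linescans(g$image, tr$center, tr$radius, n_lines = 360,
                        n_bins = n_bins)
  # away from the ring boundaries every sample of every ray sits in the
  # same ring, so the averages agree exactly; bins straddling a boundary
  # differ only by their sub-bin sample split and stay bracketed by the
  # adjacent ring means
  bin_frac <- (a$profile$bin - 0.5) / n_bins
  interior <- abs(bin_frac - tr$boundaries[1]) > 1.5 / n_bins &
    abs(bin_frac - tr$boundaries[2]) > 1.5 / n_bins &
    bin_frac < 1 - 1.5 / n_bins   # rim pixels can round to background
  for (ch in c("ki67", "phgdh")) {
    expect_equal(a$profile[[ch]][interior], b$profile[[ch]][interior])
    rings <- c(tr$channel_means[ch, ], tr$background)
    expect_true(all(a$profile[[ch]] >= min(rings) &
                      a$profile[[ch]] <= max(rings)))
  }
})

test_that("compartment means recover zero-noise ring truths exactly", {
  tr <- ring_truth(channel_means = rbind(a = c(o = 40, i = 20, c = 10)),
                   noise_sd = 0)
  g <- generate_microtumor_image(tr)
  cm <- compartment_means(g$image, tr$center, tr$radius, tr$boundaries)
  expect_equal(unname(cm$means[1, ]), c(40, 20, 10))
  zero <- compartment_means(array(0, dim = c(65, 65, 1)), c(33, 33), 20)
  expect_equal(unname(zero$means[1, ]), c(0, 0, 0))
  expect_error(compartment_means(g$image, tr$center, radius = 1e4),
               "bounds")
})

test_that("noisy compartment means stay within the standard-error bound", {
  tr <- ring_truth(seed = 31)  # default Gaussian noise, sd 300
  g <- generate_microtumor_image(tr)
  cm <- compartment_means(g$image, tr$center, tr$radius, tr$boundaries)
  for (ch in 1:2) {
    err <- abs(cm$means[ch, ] - tr$channel_means[ch, ])
    bound <- 4 * tr$noise_sd[ch] / sqrt(cm$pixel_counts)
    # rounding to the integer grid adds at most 0.5
    expect_true(all(err <= bound + 0.5))
  }
})

test_that("quantification is intensity-scale equivariant", {
  tr <- ring_truth(seed = 8)
  img <- generate_microtumor_image(tr)$image
  cm1 <- compartment_means(img, tr$center, tr$radius)
  cm3 <- compartment_means(3 * img, tr$center, tr$radius)
  expect_equal(cm3$means, 3 * cm1$means)
  ls1 <- radial_linescans(img, tr$center, tr$radius)
  ls3 <- radial_linescans(3 * img, tr$center, tr$radius)
  expect_equal(ls3$profile$ki67, 3 * ls1$profile$ki67)
  ct <- cell_truth(n_cells = 50, p_on = c(1, 1), rho = 0.5, seed = 9)
  fld <- generate_monolayer_field(ct)
  pc1 <- per_cell_intensities(fld$image, fld$masks)
  pc3 <- per_cell_intensities(3 * fld$image, fld$masks)
  expect_equal(pc3$correlation$r, pc1$correlation$r)
  expect_equal(pc3$cells$intensity_cyto, 3 * pc1$cells$intensity_cyto)
})

test_that("a 90-degree rotation leaves compartment means bit-identical", {
  tr <- ring_truth(seed = 12)
  img <- generate_microtumor_image(tr)$image
  rot <- img
  for (ch in 1:2) rot[, , ch] <- t(img[, , ch])[, dim(img)[1]:1]
  cm <- compartment_means(img, tr$center, tr$radius)
  cm_rot <- compartment_means(rot, tr$center, tr$radius)
  expect_identical(cm$means, cm_rot$means)
  ls <- radial_linescans(img, tr$center, tr$radius, n_lines = 36)
  ls_rot <- radial_linescans(rot, tr$center, tr$radius, n_lines = 36)
  expect_lt(max(abs(ls$profile$ki67 - ls_rot$profile$ki67)),
            0.05 * diff(range(tr$channel_means)))
})

test_that("per-cell intensities recover zero-noise truth exactly", {
  ct <- cell_truth(n_cells = 40, p_on = c(0.5, 0.5), noise_sd = 0, seed = 2)
  fld <- generate_monolayer_field(ct)
  pc <- per_cell_intensities(fld$image, fld$masks)
  expect_equal(pc$cells$intensity_nuclear, fld$cells$intensity_nuclear)
  expect_equal(pc$cells$intensity_cyto, fld$cells$intensity_cyto)
})

test_that("correlated fields land in the Fisher-z interval around rho", {
  ct <- cell_truth(n_cells = 500, p_on = c(1, 1), rho = 0.8, seed = 41)
  fld <- generate_monolayer_field(ct)
  pc <- per_cell_intensities(fld$image, fld$masks, conf_level = 0.99)
  half <- qnorm(0.995) / sqrt(500 - 3)
  interval <- tanh(atanh(0.8) + c(-half, half))
  expect_gte(pc$correlation$r, interval[1])
  expect_lte(pc$correlation$r, interval[2])
})

test_that("fewer than three cells flags the correlation undefined", {
  ct <- cell_truth(n_cells = 2, seed = 1)
  fld <- generate_monolayer_field(ct)
  pc <- per_cell_intensities(fld$image, fld$masks)
  expect_false(pc$correlation$defined)
  expect_true(is.na(pc$correlation$r))
})

test_that("model/image concordance flags agreement and disagreement", {
  # concordant: image ordered like a suppressed-PHGDH model profile
  tr <- ring_truth(channel_means = rbind(phgdh = c(o = 40, i = 10, c = 4)),
                   noise_sd = 0)
  cm <- compartment_means(generate_microtumor_image(tr)$image,
                          tr$center, tr$radius)
  chk <- model_vs_image_check(c(o = 1, i = 0.16, c = 0.01), cm)
  expect_true(chk$concordant)
  expect_length(chk$flagged, 0)
  # discordant: image inverts the inner/core order
  tr2 <- ring_truth(channel_means = rbind(phgdh = c(o = 40, i = 5, c = 15)),
                    noise_sd = 0)
  cm2 <- compartment_means(generate_microtumor_image(tr2)$image,
                           tr2$center, tr2$radius)
  chk2 <- model_vs_image_check(c(o = 1, i = 0.22, c = 0.05), cm2)
  expect_false(chk2$concordant)
  expect_setequal(chk2$flagged, c("i", "c"))
  # identical triplets are trivially concordant
  chk3 <- model_vs_image_check(chk$image_normalized, cm)
  expect_true(chk3$concordant)
  # undefined normalization is an explicit error
  dark <- compartment_means(array(0, dim = c(65, 65, 1)), c(33, 33), 20)
  expect_error(model_vs_image_check(c(o = 1, i = 1, c = 1), dark),
               "undefined")
})
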