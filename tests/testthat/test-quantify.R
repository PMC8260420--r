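test_that("voxel water content matches the published hand-checkable cases", {
  k <- water_constants()
  expect_equal(round_half_away(
    water_content(voxel_composition(0.46, 0.50, 0.04), k)$percent, 1), 72.3)
  expect_equal(round_half_away(
    water_content(voxel_composition(0.91, 0.09, 0.00), k)$percent, 1), 76.8)
  expect_equal(round_half_away(
    water_content(voxel_composition(0.11, 0.67, 0.22), k)$percent, 1), 73.5)
  pure_gm <- water_content(voxel_composition(1, 0, 0), k)
  expect_identical(pure_gm$percent, 78)
  expect_identical(pure_gm$mol_per_L, 42.9)
})

test_that("every packaged voxel water content is reproduced exactly at one decimal", {
  voxels <- study_voxels()
  wc <- round_half_away(
    water_content_from_pct(voxels$gm_pct, voxels$wm_pct,
                           voxels$csf_pct)$percent, 1)
  expect_equal(wc, voxels$wc_pct)
  expect_equal(nrow(voxels), 24L)  # 2 cycles x 4 regions x 3 subjects
})

test_that("water content increases strictly with CSF at a fixed GM:WM ratio", {
  wc <- sapply(seq(0, 0.5, by = 0.05), function(csf) {
    rest <- 1 - csf
    water_content(voxel_composition(0.6 * rest, 0.4 * rest, csf))$percent
  })
  expect_true(all(diff(wc) > 0))
})

test_that("composition invariants are enforced", {
  expect_error(voxel_composition(0.5, 0.4, 0.2), "sum to 1")
  expect_error(voxel_composition(0.5, 0.5, 0, voxel_ml = -1), "voxel_ml")
  expect_error(voxel_composition(1.2, -0.2, 0), "\\[0, 1\\]")
})

test_that("the internal water reference formula reproduces its arithmetic and the zero case", {
  pure_gm <- voxel_composition(1, 0, 0)
  expect_equal(water_reference_conc(1e-3, 1, n_met = 3, pure_gm), 28.6,
               tolerance = 1e-12)
  expect_equal(water_reference_conc(0, 1, n_met = 3, pure_gm), 0)
  expect_error(water_reference_conc(1, 0, 3, pure_gm), "water_area")
})

test_that("the noiseless quantification chain recovers ground truth and is homogeneous of degree 1", {
  comps <- list(COMP_OCC,
                voxel_composition(0.87, 0.13, 0, region = "putamen"),
                voxel_composition(0.11, 0.67, 0.22, region = "frontal_cortex"))
  for (comp in comps) {
    sim <- simulate_voxel_case(0.5, comp, BASIS)
    fit <- lcfit(sim$spectrum, BASIS, noise_sd = 0)
    q <- quantify_voxel(fit, water_area(sim$water_ref), comp)
    expect_lt(abs(q$norm_conc_gL - 0.5) / 0.5, 1e-3 / 100)
    expect_equal(q$wc_percent, water_content(comp)$percent)

    sim2 <- simulate_voxel_case(1.0, comp, BASIS)
    fit2 <- lcfit(sim2$spectrum, BASIS, noise_sd = 0)
    q2 <- quantify_voxel(fit2, water_area(sim2$water_ref), comp)
    expect_equal(q2$norm_conc_gL, 2 * q$norm_conc_gL, tolerance = 1e-9)
  }
})

test_that("water normalization divides by the water fraction and inverts exactly", {
  expect_equal(normalize_to_water(0.42, 100), 0.42)
  expect_equal(normalize_to_water(0.50, 73.5), 0.6803, tolerance = 1e-4)
  expect_equal(denormalize_from_water(0.68, 73.5), 0.4998, tolerance = 1e-12)
  expect_equal(denormalize_from_water(0, 73.5), 0)
  for (x in c(0, 0.2, 0.68, 1.3)) {
    for (wc in c(65, 73.5, 97, 100)) {
      expect_equal(denormalize_from_water(normalize_to_water(x, wc), wc), x,
                   tolerance = 1e-12)
      expect_gte(normalize_to_water(x, wc), x)  # never decreases for wc <= 100
    }
  }
  expect_error(normalize_to_water(0.5, 0), "wc_percent")
  expect_error(denormalize_from_water(0.5, -3), "wc_percent")
})

test_that("mass-unit conversion uses the ethanol molar mass and inverts", {
  expect_equal(mmol_to_gL(0), 0)
  expect_equal(round_half_away(mmol_to_gL(14.76), 3), 0.680)
  for (x in c(0.01, 3, 14.76, 80))
    expect_equal(gL_to_mmol(mmol_to_gL(x)), x, tolerance = 1e-12)
  expect_error(mmol_to_gL(-1), ">= 0")
})

test_that("quantify_voxel carries the CRLB and labels from the fit", {
  sim <- simulate_voxel_case(0.62, COMP_OCC, BASIS,
                             noise_sd = default_noise_sd(), seed = 9)
  fit <- lcfit(sim$spectrum, BASIS)
  q <- quantify_voxel(fit, water_area(sim$water_ref), COMP_OCC)
  expect_equal(q$crlb_percent, unname(fit$crlb_percent["Eth"]))
  expect_equal(q$region, "occipital_cortex")
  expect_error(quantify_voxel(fit, water_area(sim$water_ref), COMP_OCC,
                              metabolite = "Lac"), "not in fit")
})
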