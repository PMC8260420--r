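test_that("serum and blood ethanol concentrations interconvert under the study-implied factor", {
  expect_equal(round_half_away(blood_from_serum(0.99), 1), 0.8)
  expect_equal(blood_from_serum(0), 0)
  for (x in c(0.1, 0.99, 2.4))
    expect_equal(serum_from_blood(blood_from_serum(x)), x, tolerance = 1e-12)
  expect_error(blood_from_serum(-0.1), ">= 0")
})

test_that("the Widmark dose is the classical product, corrected for the resorption deficit", {
  pk <- pk_params(body_mass_kg = 62, r_factor = 0.7, target_bac_gkg = 0.8,
                  resorption_deficit = 0)
  expect_equal(widmark_dose_grams(pk), 34.72, tolerance = 1e-12)
  pk$resorption_deficit <- 0.3
  expect_equal(widmark_dose_grams(pk), 49.6, tolerance = 1e-12)
  pk2 <- pk_params(body_mass_kg = 124, r_factor = 0.7, target_bac_gkg = 0.8,
                   resorption_deficit = 0)
  expect_equal(widmark_dose_grams(pk2),
               2 * 34.72, tolerance = 1e-12)
  # exact invertibility: recover the target BAC from the dose
  pk3 <- pk_params(body_mass_kg = 69, resorption_deficit = 0.2)
  g <- widmark_dose_grams(pk3)
  expect_equal(g * (1 - pk3$resorption_deficit) /
                 (pk3$body_mass_kg * pk3$r_factor),
               pk3$target_bac_gkg, tolerance = 1e-12)
})

test_that("beverage volume follows from ethanol mass, strength and density", {
  expect_equal(dose_to_beverage_ml(34.72, 0.40, 0.789), 110.0,
               tolerance = 1e-3)
  expect_equal(dose_to_beverage_ml(57, abv = 1, ethanol_density = 1), 57)
  expect_equal(dose_to_beverage_ml(34.72, 0.20, 0.789),
               2 * dose_to_beverage_ml(34.72, 0.40, 0.789),
               tolerance = 1e-12)
  expect_error(dose_to_beverage_ml(10, abv = 0), "abv")
})

test_that("pk parameter invariants are enforced", {
  expect_error(pk_params(body_mass_kg = -1), "positive")
  expect_error(pk_params(abv = 1.2), "abv")
  expect_error(pk_params(resorption_deficit = 1), "resorption_deficit")
})

test_that("the study comparison finds the published extrema and flatter brain curves", {
  brain <- study_brain()
  serum <- study_serum()
  cmp <- compare_matrices(
    data.frame(subject = brain$subject, time_min = brain$time_min,
               conc_gL = brain$conc_gL), serum)
  expect_equal(max(cmp$summary$max[cmp$summary$matrix == "brain"]), 0.68)
  expect_equal(max(cmp$summary$max[cmp$summary$matrix == "serum"]), 1.19)
  # flatness is quantified per subject; V1 and V3 have clearly flatter brain
  # curves, while V2's serum was already at peak at T1 and is itself flat
  expect_true(all(cmp$flatness$brain_flatter[cmp$flatness$subject
                                             %in% c("V1", "V3")]))
  expect_equal(cmp$flatness$cv_brain,
               sapply(c("V1", "V2", "V3"), function(s) {
                 x <- brain$conc_gL[brain$subject == s]
                 sd(x) / mean(x)
               }, USE.NAMES = FALSE), tolerance = 1e-12)
  # every serum draw from T2 on exceeds the temporally nearest brain value
  late <- cmp$pairs[cmp$pairs$timepoint %in% c("T2", "T3", "T4", "T5"), ]
  expect_equal(nrow(late), 12L)  # 4 timepoints x 3 subjects
  expect_true(all(late$serum_gL > late$brain_gL))
})

test_that("degenerate and unpairable comparisons follow the stated conventions", {
  const_b <- data.frame(subject = "V1", time_min = c(10, 50),
                        conc_gL = c(0.4, 0.4))
  const_s <- data.frame(subject = "V1", time_min = c(15, 55),
                        conc_gL = c(0.4, 0.4))
  cmp <- compare_matrices(const_b, const_s)
  expect_equal(cmp$summary$cv, c(0, 0))
  expect_equal(cmp$flatness$cv_ratio_brain_over_serum, 1)

  far <- data.frame(subject = "V1", time_min = c(500, 600),
                    conc_gL = c(0.1, 0.2))
  expect_error(compare_matrices(const_b, far), "overlapping")
  expect_error(compare_matrices(const_b[1, ], const_s), "2 timepoints")
})
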