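test_that("reference curve has the stated double-hump structure", {
  curve <- reference_curve()
  s <- curve$normalized_jcf
  expect_equal(max(s), 1.0)
  expect_equal(sum(s == 1), 1) # max attained at exactly one grid point
  interior <- 2:(length(s) - 1)
  n_max <- sum(s[interior] > s[interior - 1] & s[interior] > s[interior + 1])
  expect_equal(n_max, 2)
  # midstance trough around 0.6 of peak
  trough <- min(s[curve$stance_percent > 35 & curve$stance_percent < 65])
  expect_gt(trough, 0.4)
  expect_lt(trough, 0.8)
})

test_that("reference curve CSV override round-trips identically", {
  curve <- reference_curve()
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_curve(curve, path)
  back <- reference_curve(file = path)
  expect_equal(back$normalized_jcf, curve$normalized_jcf, tolerance = 1e-12)
  expect_equal(back$flexion_deg, curve$flexion_deg, tolerance = 1e-12)
  # negative user curves are rejected
  bad <- data.frame(stance_percent = c(0, 50, 100),
                    normalized_jcf = c(0.1, -0.2, 0.1),
                    flexion_deg = c(5, 5, 5))
  bad_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, bad_path, row.names = FALSE)
  expect_error(reference_curve(file = bad_path), "negative")
})

test_that("50/50 loading scales the curve by body weight and splits evenly", {
  curve <- reference_curve(peak_bw_multiplier = 2.6)
  ld <- loading_5050(toy_subject(mass = 73.6), curve)
  expect_equal(ld$peak_total, 2.6 * 73.6 * 9.81, tolerance = 1e-12) # 1877.3 N
  expect_equal(ld$peak_medial, ld$peak_total / 2)
  expect_equal(c(ld$share_medial, ld$share_lateral), c(0.5, 0.5))
  expect_equal(max(ld$force_medial), ld$peak_medial, tolerance = 1e-9)
  expect_true(all(ld$force_medial[curve$normalized_jcf == 0] == 0))
})

test_that("NN load-sharing schemes follow the predicted peak ratios", {
  curve <- reference_curve()
  sym <- stub_predictor(1.3, 1.3, 2.6)
  subj <- toy_subject(mass = 70)
  ld_sym <- loading_ls_nn(subj, curve, sym)
  ld_5050 <- loading_5050(subj, curve)
  expect_equal(ld_sym$force_medial, ld_5050$force_medial, tolerance = 1e-12)
  expect_equal(ld_sym$share_medial, 0.5)

  asym <- stub_predictor(1.8, 0.9, 2.6)
  ld_asym <- loading_ls_nn(subj, curve, asym)
  expect_equal(ld_asym$share_medial, 1.8 / 2.6, tolerance = 1e-12) # 0.692
  # shares do not depend on mass
  ld_heavy <- loading_ls_nn(toy_subject(mass = 140), curve, asym)
  expect_equal(ld_heavy$share_medial, ld_asym$share_medial)

  ld_peak <- loading_ls_peak_nn(subj, curve, asym)
  expect_equal(ld_peak$peak_medial, 1.8 * 70 * 9.81, tolerance = 1e-12) # 1236 N
  expect_equal(max(ld_peak$force_medial), ld_peak$peak_medial,
               tolerance = 1e-9)
  # heavier subject, same BW prediction: proportionally larger peaks
  ld_peak_heavy <- loading_ls_peak_nn(toy_subject(mass = 140), curve, asym)
  expect_equal(ld_peak_heavy$peak_medial / ld_peak$peak_medial, 2)
  # consistency: peak scheme equals share scheme when the predicted total
  # equals the reference multiplier
  expect_equal(ld_peak$force_medial, ld_asym$force_medial, tolerance = 1e-12)
})

test_that("flexion trajectory is fixed across subjects and schemes", {
  curve <- reference_curve()
  pred <- stub_predictor(1.5, 1.0, 2.4)
  lds <- list(loading_5050(toy_subject(mass = 50), curve),
              loading_5050(toy_subject(mass = 110), curve),
              loading_ls_nn(toy_subject(mass = 80), curve, pred),
              loading_ls_peak_nn(toy_subject(mass = 60), curve, pred))
  for (ld in lds) expect_identical(ld$flexion_deg, curve$flexion_deg)
})

test_that("cartilage-contact fraction rescales forces only", {
  curve <- reference_curve()
  full <- loading_5050(toy_subject(), curve, contact_fraction = 1)
  half <- loading_5050(toy_subject(), curve, contact_fraction = 0.5)
  expect_equal(half$force_medial, full$force_medial / 2)
  expect_equal(half$peak_total, full$peak_total)
})
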