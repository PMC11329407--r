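test_that("monotonic tensile threshold reproduces its printed segments", {
  expect_equal(threshold_kempson(25), 30)
  expect_equal(threshold_kempson(45), 10)
  expect_equal(threshold_kempson(52.5), 8.875) # 10 - 7.5 * 0.15
  expect_equal(threshold_kempson(65), 7)
  expect_equal(threshold_kempson(80), 6.8)
  expect_error(threshold_kempson(0), "positive")
  expect_error(threshold_kempson(-3), "positive")
})

test_that("monotonic threshold is continuous and non-increasing with age", {
  ages <- seq(0.01, 120, by = 0.01)
  v <- threshold_kempson(ages)
  expect_true(all(diff(v) <= 1e-12))
  expect_true(all(v > 0))
  for (bp in c(30, 45, 65, 75)) {
    expect_equal(threshold_kempson(bp), threshold_kempson(bp + 1e-9),
                 tolerance = 1e-6)
  }
})

test_that("fatigue threshold implements the age/cycles relation", {
  expect_equal(threshold_weightman(30, 1e6), 11.0)  # 25.4 - 4.5 - 9.9
  expect_equal(threshold_weightman(58, 1e6), 6.8)   # 25.4 - 8.7 - 9.9
  expect_equal(threshold_weightman(1e-9, 1), 25.4, tolerance = 1e-6)
  # strictly decreasing in age and in cycles
  ages <- seq(1, 80, by = 0.5)
  expect_true(all(diff(threshold_weightman(ages, 1e5)) < 0))
  for (a in c(20, 40, 60)) {
    v <- threshold_weightman(a, c(1e5, 1e6, 1e7))
    expect_true(all(diff(v) < 0))
  }
  expect_error(threshold_weightman(95, 1e7), "exhausted")
  expect_error(threshold_weightman(-1, 1e6), "positive")
  expect_error(threshold_weightman(30, 0.5), "N must be")
})

test_that("degenerated volume counts central-region exceedance", {
  tissue <- rep(c("femoral_cartilage", "tibial_cartilage"), 5)
  region <- c(rep("central", 6), rep("anterior", 2), rep("posterior", 2))
  mesh <- toy_mesh(rep(2, 10), tissue, region)
  env <- rep(0, 10)
  env[c(1, 2, 3)] <- 5 # three central elements exceed
  env[7] <- 50         # non-central exceedance must not count
  field <- list(envelope = env)
  res <- degenerated_volume(field, mesh, threshold = 1)
  expect_equal(res$fraction_compartment, 0.5) # 3 of 6 equal volumes
  expect_equal(res$fraction_femoral + res$fraction_tibial,
               res$fraction_compartment)
  expect_equal(res$reference_volume, 12)

  expect_equal(degenerated_volume(field, mesh, 100)$fraction_compartment, 0)
  all_on <- list(envelope = rep(10, 10))
  expect_equal(degenerated_volume(all_on, mesh, 1e-9)$fraction_compartment, 1)
  expect_error(degenerated_volume(field, mesh, 0), "positive")
  expect_error(degenerated_volume(list(envelope = 1:3), mesh, 1),
               "inconsistent")
})

test_that("degenerated volume is monotone in threshold and force", {
  m <- fixture_template("medial")
  curve <- reference_curve()
  subj <- toy_subject()
  f1 <- simulate_stance(m, loading_5050(subj, curve))
  fr <- sapply(c(2, 4, 6, 8), function(thr) {
    degenerated_volume(f1, m, thr)$fraction_compartment
  })
  expect_true(all(diff(fr) <= 0))
  # heavier subject (larger force), same threshold: no less degeneration
  f2 <- simulate_stance(m, loading_5050(toy_subject(mass = 95), curve))
  expect_gte(degenerated_volume(f2, m, 5)$fraction_compartment,
             degenerated_volume(f1, m, 5)$fraction_compartment)
})

test_that("knee-level fractions pool both compartments", {
  tissue <- rep("femoral_cartilage", 4)
  region <- rep("central", 4)
  med <- degenerated_volume(list(envelope = c(5, 5, 0, 0)),
                            toy_mesh(rep(1, 4), tissue, region), 1)
  lat <- degenerated_volume(list(envelope = c(5, 0, 0, 0)),
                            toy_mesh(rep(2, 4), tissue, region), 1)
  knee <- knee_degeneration(med, lat)
  expect_equal(knee$fraction_overall, (2 + 2) / (4 + 8))
  expect_equal(knee$fraction_medial, 0.5)
  expect_equal(knee$fraction_lateral, 0.25)
})
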