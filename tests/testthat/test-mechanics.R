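props_f <- cartilage_props("femur")
props_t <- cartilage_props("tibia")

test_that("material defaults carry the published constants", {
  expect_equal(props_t$xi_fp, 32)
  expect_equal(props_f$xi_fp, 215)
  expect_equal(c(props_t$E_nf, props_f$E_nf), c(0.106, 0.215))
  expect_equal(c(props_t$kappa0, props_f$kappa0), c(18, 6))
  expect_equal(props_f$beta_fp, 2.6)
  over <- cartilage_props("tibia", xi_fp = 10)
  expect_equal(over$xi_fp, 10)
})

test_that("column response is zero at rest and monotone in strain", {
  r0 <- column_response(0, props_f, props_t)
  expect_equal(r0$pressure, 0)
  expect_equal(r0$sigma_I_femoral, 0)
  eps <- seq(0.01, 0.59, by = 0.01)
  r <- column_response(eps, props_f, props_t)
  expect_true(all(diff(r$pressure) > 0))
  expect_true(all(diff(r$sigma_I_femoral) > 0))
  expect_false(any(r$saturated))
  expect_warning(column_response(0.6, props_f, props_t), "saturated")
})

test_that("series partition equalizes pressures, softer tibia strains more", {
  r <- column_response(0.3, props_f, props_t,
                       thickness_femoral = 1, thickness_tibial = 1)
  expect_gt(r$eps_tibial, r$eps_femoral)
  # root-find oracle: the two tissues carry the same pressure
  pf <- kneedegen:::.tissue_response(r$eps_femoral, props_f)$pressure
  pt <- kneedegen:::.tissue_response(r$eps_tibial, props_t)$pressure
  expect_equal(pf, pt, tolerance = 1e-8)
  # strains average back to the column strain (equal thicknesses)
  expect_equal((r$eps_femoral + r$eps_tibial) / 2, 0.3, tolerance = 1e-10)
})

test_that("stiff femoral fibrils raise surface stress at equal strain", {
  eps <- 0.3
  sf <- kneedegen:::.tissue_response(eps, props_f)$sigma_I
  st <- kneedegen:::.tissue_response(eps, props_t)$sigma_I
  expect_gt(sf, st)
  # zero-stiffness fibrils reduce sigma_I to the matrix term alone
  soft <- cartilage_props("femur", xi_fp = 0, xi_fs = 0)
  lam <- 1 - eps
  mu <- soft$E_nf / (3 * (1 + soft$nu_nf))
  expect_equal(kneedegen:::.tissue_response(eps, soft)$sigma_I,
               mu * (1 / lam - lam^2), tolerance = 1e-12)
})

test_that("contact columns track the condyle apex and flexion", {
  m <- fixture_template("medial")
  cols0 <- build_columns(m, 0)
  apex <- cols0[which.min(cols0$gap), ]
  # minimum gap at the column closest to the condyle apex (origin)
  expect_lt(abs(apex$x), m$meas$ap / m$nx)
  expect_lt(abs(apex$z), 30 / m$nz)
  # positive flexion moves the closest approach posteriorly (X decreases)
  cols15 <- build_columns(m, 15)
  expect_lt(cols15$x[which.min(cols15$gap)], apex$x)
  # column areas tile the plateau footprint
  expect_equal(sum(cols0$area), m$meas$ap * 30, tolerance = 1e-9)
})

test_that("frame equilibrium balances the applied force", {
  m <- fixture_template("medial")
  cols <- build_columns(m, 0)
  zero <- solve_contact_frame(cols, 0)
  expect_true(all(zero$pressure == 0))
  expect_lte(zero$delta, min(cols$gap, na.rm = TRUE))

  forces <- c(200, 400, 800, 1600)
  sols <- lapply(forces, function(f) solve_contact_frame(cols, f))
  for (i in seq_along(forces)) {
    expect_lt(sols[[i]]$residual / forces[i], 1e-6)
  }
  areas <- vapply(sols, `[[`, numeric(1), "contact_area")
  peaks <- vapply(sols, function(s) max(s$sigma_I_femoral), numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_true(all(diff(peaks) > 0))
  expect_error(solve_contact_frame(cols, 1e6), "capacity")
})

test_that("stance simulation satisfies the envelope and symmetry contracts", {
  m <- fixture_template("medial")
  curve <- reference_curve()
  ld <- loading_5050(toy_subject(), curve)
  # constant force and flexion: all frames identical
  ld_const <- ld
  ld_const$force_medial <- rep(800, length(ld$force_medial))
  ld_const$flexion_deg <- rep(5, length(ld$flexion_deg))
  f_const <- simulate_stance(m, ld_const)
  expect_lt(max(abs(f_const$sigma - f_const$sigma[, 1])), 1e-9)

  f <- simulate_stance(m, ld)
  expect_true(all(f$envelope + 1e-12 >= f$sigma))
  expect_true(all(f$residual / pmax(f$force, 1e-9) < 1e-6))
  expect_equal(dim(f$sigma), c(nrow(m$hexa), length(ld$force_medial)))
})

test_that("depth weights grade stress from superficial to deep", {
  m <- fixture_template("medial")
  ld <- loading_5050(toy_subject(), reference_curve())
  f <- simulate_stance(m, ld)
  env <- f$envelope
  fem <- m$tissue == "femoral_cartilage"
  sup <- max(env[fem & m$layer == 0])
  deep <- max(env[fem & m$layer == m$n_layers - 1])
  expect_equal(deep / sup, 0.25, tolerance = 1e-9)
})

test_that("medializing NN loading stresses the medial compartment more", {
  med <- fixture_template("medial")
  lat <- fixture_template("lateral")
  curve <- reference_curve()
  pred <- stub_predictor(1.8, 0.9, 2.6) # strongly medializing
  subj <- toy_subject()
  ld <- loading_ls_peak_nn(subj, curve, pred)
  f_med <- simulate_stance(med, ld)
  f_lat <- simulate_stance(lat, ld)
  expect_gt(max(f_med$envelope), max(f_lat$envelope) * 0.99)
})
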