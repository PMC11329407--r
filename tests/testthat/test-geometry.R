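test_that("template construction yields a valid layered hex mesh", {
  m <- fixture_template("medial")
  vols <- element_volumes(m)
  expect_true(all(vols > 0))
  q <- mesh_quality(m)
  expect_gt(q$min_jacobian, 0)
  expect_equal(m$meas$femoral_fraction, 0.55)
  # femoral cartilage sits above tibial cartilage along Y in every column
  gap <- m$nodes[m$surf_fem, 2] - m$nodes[m$surf_tib, 2]
  expect_true(all(gap > 0))
  expect_error(build_template("medial", nx = 2), "degenerate resolution")
  # lateral compartment is less congruent: tighter condyle radii
  pl <- template_defaults("lateral")
  pm <- template_defaults("medial")
  expect_lt(pl$condyle_r_ap, pm$condyle_r_ap)
  expect_lt(pl$condyle_r_ml, pm$condyle_r_ml)
})

test_that("doubling the resolution changes total volume by less than 2%", {
  v1 <- sum(element_volumes(build_template("medial", 8, 6, 3)))
  v2 <- sum(element_volumes(build_template("medial", 16, 12, 6)))
  expect_lt(abs(v2 - v1) / v1, 0.02)
})

test_that("identity scaling reproduces the template to 1e-12 mm", {
  m <- fixture_template("medial")
  meas <- list(icd = m$meas$icd, ap = m$meas$ap, js = m$meas$js,
               femoral_fraction = m$meas$femoral_fraction)
  s <- scale_mesh(m, meas, "fixed_ratio")
  expect_lt(max(abs(s$nodes - m$nodes)), 1e-12)
  s2 <- scale_mesh(m, meas, "scaled_ratio")
  expect_lt(max(abs(s2$nodes - m$nodes)), 1e-12)
})

test_that("ICD-only scaling halves Z and total volume", {
  m <- fixture_template("medial")
  meas <- list(icd = m$meas$icd / 2, ap = m$meas$ap, js = m$meas$js,
               femoral_fraction = m$meas$femoral_fraction)
  s <- scale_mesh(m, meas, "fixed_ratio")
  expect_equal(s$nodes[, 3], m$nodes[, 3] / 2, tolerance = 1e-14)
  expect_equal(sum(element_volumes(s)), sum(element_volumes(m)) / 2,
               tolerance = 1e-12)
})

test_that("scaled-ratio thickness follows the subject joint space split", {
  m <- fixture_template("medial")
  meas <- list(icd = 40.6, ap = 53.05, js = 4.79, femoral_fraction = 0.55)
  s <- scale_mesh(m, meas, "scaled_ratio")
  expect_equal(unname(s$thickness["femoral"]), 4.79 * 0.55) # 2.6345 mm
  expect_equal(unname(s$thickness["tibial"]), 4.79 * 0.45)  # 2.1555 mm
})

test_that("volume covariance is exact in fixed-ratio mode", {
  m <- fixture_template("lateral")
  meas <- list(icd = 37.1, ap = 66.2, js = 6.1, femoral_fraction = 0.47)
  s <- scale_mesh(m, meas, "fixed_ratio")
  factor <- (66.2 / m$meas$ap) * (37.1 / m$meas$icd) * (6.1 / m$meas$js)
  expect_equal(sum(element_volumes(s)), sum(element_volumes(m)) * factor,
               tolerance = 1e-12)
  # connectivity, labels and element count preserved
  expect_identical(s$hexa, m$hexa)
  expect_identical(s$tissue, m$tissue)
  expect_identical(s$layer, m$layer)
})

test_that("scaling a subject with unusual measurements keeps validity", {
  m <- fixture_template("medial")
  co <- generate_cohort(5, seed = 42)
  for (i in seq_len(3)) {
    s <- scale_mesh(m, cohort_measurements(co[i, ]), "scaled_ratio")
    expect_gt(mesh_quality(s)$min_jacobian, 0)
  }
  bad <- list(icd = 40.6, ap = 53.05, js = 4.79, femoral_fraction = 0.55)
  bad$js <- 0
  expect_error(scale_mesh(m, bad, "scaled_ratio"), "non-positive|positive")
})

test_that("mesh quality metrics are exact on box elements", {
  unit <- toy_mesh(1, "tibial_cartilage", "central")
  expect_equal(mesh_quality(unit)$aspect_median, 1.0)
  # a 2 x 1 x 1 box: stretch x of a unit cube
  box <- toy_mesh(1, "tibial_cartilage", "central")
  box$nodes[, 1] <- box$nodes[, 1] * 2
  expect_equal(mesh_quality(box)$aspect_median, 2.0)
  expect_equal(element_volumes(box), 2.0)
})

test_that("region partition counts and limits behave", {
  m <- fixture_template("medial")
  all_central <- partition_regions(m, 1)
  expect_true(all(all_central$region == "central"))
  third <- partition_regions(m, 1 / 3)
  n_total <- nrow(m$hexa)
  per_slab <- n_total / m$nx # elements per X-slab (both tissues, all layers)
  n_central <- sum(third$region == "central")
  expect_lt(abs(n_central - n_total / 3), per_slab + 1e-9)
  expect_true(all(c("anterior", "posterior") %in% third$region))
  expect_error(partition_regions(m, 0), "central_fraction")
  # band boundaries move with A-P scaling: labels are scale-invariant
  meas <- list(icd = m$meas$icd, ap = m$meas$ap * 1.7, js = m$meas$js,
               femoral_fraction = m$meas$femoral_fraction)
  s <- scale_mesh(m, meas, "fixed_ratio")
  expect_identical(s$region, m$region)
})
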