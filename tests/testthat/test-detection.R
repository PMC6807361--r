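test_that("numerical aperture sets the acceptance half-angle", {
  expect_equal(acceptance_half_angle(0.25), 14.48, tolerance = 1e-3)
  expect_equal(acceptance_half_angle(1), 90)
  expect_equal(acceptance_half_angle(0.5), 30)
  expect_equal(acceptance_half_angle(0.25, override_deg = 15), 15)
  expect_error(acceptance_half_angle(1.2), "n_medium")
  # the bundled microscope preset pins the cone to 15 degrees
  expect_equal(default_detector()$half_angle_deg, 15)
})

test_that("collect filters by exit angle and bins by exit radius", {
  exits <- data.frame(
    r_cm = c(0.001, 0.006, 0.006, 0.030, 0.2),
    angle_deg = c(0, 5, 40, 14, 10),
    weight = c(1, 0.5, 9, 0.25, 0.125))
  prof <- collect(exits, default_detector())
  expect_s3_class(prof, "radial_profile")
  expect_equal(nrow(prof), 10)
  expect_equal(prof$intensity[1], 1)       # 40-degree record rejected
  expect_equal(prof$intensity[2], 0.5)
  expect_equal(prof$count[7], 1)           # r = 0.030 cm -> seventh bin
  expect_equal(prof$fraction_of_first, prof$intensity / prof$intensity[1])
  # totals include accepted records beyond the binned range
  expect_equal(attr(prof, "accepted_weight"), 1.875)
  expect_equal(attr(prof, "accepted_count"), 4L)
})

test_that("collect is order-independent, idempotent under re-filtering, and monotone in aperture", {
  set.seed(41)
  exits <- data.frame(r_cm = abs(rnorm(500, 0, 0.02)),
                      angle_deg = runif(500, 0, 90),
                      weight = runif(500))
  det <- default_detector()
  p1 <- collect(exits, det)
  p2 <- collect(exits[sample(nrow(exits)), ], det)
  expect_equal(p1, p2)
  # re-collecting the already-accepted subset changes nothing
  acc <- exits[exits$angle_deg <= det$half_angle_deg, ]
  expect_equal(collect(acc, det), p1)
  # accepted weight is non-decreasing in the half-angle
  w <- vapply(c(5, 15, 30, 60, 90), function(ha)
    attr(collect(exits, detector_spec(half_angle_deg = ha)),
         "accepted_weight"), numeric(1))
  expect_true(all(diff(w) >= 0))
})

test_that("degenerate and empty exit sets give degenerate profiles, not errors", {
  one <- collect(data.frame(r_cm = 0, angle_deg = 0, weight = 2),
                 default_detector())
  expect_equal(one$fraction_of_first, c(1, rep(0, 9)))
  empty <- collect(data.frame(r_cm = numeric(0), angle_deg = numeric(0),
                              weight = numeric(0)), default_detector())
  expect_equal(empty$intensity, rep(0, 10))
  expect_equal(empty$count, rep(0, 10))
  expect_true(all(is.na(empty$fraction_of_first)))
})

test_that("the Berek depth of field combines diffraction and geometric terms", {
  d <- detector_spec(na = 0.25, magnification = 1, resolvable_e = 20e-4)
  dof <- berek_depth_of_field(d)
  expect_equal(dof$diffraction_cm, 8.8e-4)          # 8.8 um at 1100 nm
  expect_equal(dof$geometric_cm, 80e-4)             # 80 um for e=20um, M=1
  expect_equal(dof$dof_cm, dof$diffraction_cm + dof$geometric_cm)
  # doubling NA quarters the diffraction term
  d2 <- detector_spec(na = 0.5, magnification = 1, resolvable_e = 20e-4)
  expect_equal(berek_depth_of_field(d2)$diffraction_cm,
               dof$diffraction_cm / 4)
  # the geometric term vanishes at high magnification
  d3 <- detector_spec(na = 0.25, magnification = 1e9, resolvable_e = 20e-4)
  expect_equal(berek_depth_of_field(d3)$dof_cm, dof$diffraction_cm,
               tolerance = 1e-6)
  expect_error(berek_depth_of_field(default_detector()), "magnification")
})

test_that("the focus study ranks depths by accepted near-ballistic yield", {
  study <- simulate_focus_study(depths_mm = c(0.4, 1.4),
                                n_photons_excitation = 1e5,
                                n_photons_emission = 5e4, seed = 51)
  expect_s3_class(study, "focus_study")
  expect_equal(nrow(study$summary), 2)
  expect_true(all(diff(study$summary$accepted_weight) < 0))
  expect_equal(study$recommended_depth_mm, 0.4)
  expect_equal(study$summary$inherited_weight, c(1, 0.0015))
  # radial spread (first bin at half of maximum) is non-decreasing in depth
  spread <- vapply(study$profiles, function(p) {
    which(p$intensity >= max(p$intensity) / 2)[1]
  }, integer(1))
  expect_true(all(diff(spread) >= 0))
  # a single-depth study recommends that depth trivially
  one <- simulate_focus_study(depths_mm = 0.8, n_photons_excitation = 2e4,
                              n_photons_emission = 2e4, seed = 52)
  expect_equal(one$recommended_depth_mm, 0.8)
  expect_equal(nrow(one$summary), 1)
})

test_that("focus studies are reproducible from the global seed", {
  a <- simulate_focus_study(depths_mm = 0.4, n_photons_excitation = 2e4,
                            n_photons_emission = 2e4, seed = 60)
  b <- simulate_focus_study(depths_mm = 0.4, n_photons_excitation = 2e4,
                            n_photons_emission = 2e4, seed = 60)
  expect_identical(a$summary, b$summary)
  expect_identical(a$profiles, b$profiles)
})
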