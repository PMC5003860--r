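props_530 <- optical_properties(mua = 0.55, mus = 21, g = 0.82)
props_630 <- optical_properties(mua = 0.024, mus = 24, g = 0.87)
geom_fast <- detection_geometry(bin_xy_mm = 0.1, bin_z_mm = 0.1)

test_that("scatter power law matches hand calculation", {
  expect_equal(scatter_power_law(21, 530, 1.3, 530), 21)
  expect_equal(scatter_power_law(21, 530, 0, c(450, 600, 700)),
               rep(21, 3))
  expect_equal(scatter_power_law(21, 530, 1.3, 630),
               21 * (630 / 530)^(-1.3), tolerance = 1e-15)
  expect_error(scatter_power_law(-1, 530, 1.3, 630), "positive")
})

test_that("fixed seeds give bit-reproducible simulations", {
  a <- simulate_reflectance(props_530, geom_fast, n_photons = 1e4, seed = 3)
  b <- simulate_reflectance(props_530, geom_fast, n_photons = 1e4, seed = 3)
  expect_identical(a$dpf_pathlength_mm, b$dpf_pathlength_mm)
  expect_identical(a$sensitivity_xz, b$sensitivity_xz)
  expect_identical(a$detected_pathlengths, b$detected_pathlengths)
  c_ <- simulate_reflectance(props_530, geom_fast, n_photons = 1e4, seed = 4)
  expect_false(identical(a$dpf_pathlength_mm, c_$dpf_pathlength_mm))
})

test_that("photon weight is conserved and the adjoint identity holds", {
  r <- simulate_reflectance(props_530, geom_fast, n_photons = 3e4, seed = 5)
  expect_lt(weight_conservation(r)$relative_error, 1e-6)
  # sum of the partial-pathlength map equals mean pathlength x detected
  # weight, photon set being the same on both sides
  lhs <- sum(r$sensitivity_xz) + r$overflow
  rhs <- r$dpf_pathlength_mm * r$w_detected
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_true(all(r$sensitivity_xz >= 0))
  expect_equal(colSums(r$sensitivity_xz), r$depth_profile)
  expect_equal(rowSums(r$sensitivity_xz), r$lateral_profile)
})

test_that("perturbation finite difference reproduces the mean pathlength", {
  r <- simulate_reflectance(props_530, geom_fast, n_photons = 5e4, seed = 6)
  delta <- 1e-3
  fd <- -(log(reweighted_reflectance(r, delta)) -
            log(r$total_reflectance)) / delta
  expect_equal(fd, r$dpf_pathlength_mm, tolerance = 0.05)
})

test_that("strong absorption shortens pathlengths and kills reflectance", {
  lo <- simulate_reflectance(props_530, geom_fast, n_photons = 2e4, seed = 8)
  hi <- simulate_reflectance(optical_properties(100, 21, 0.82), geom_fast,
                             n_photons = 2e4, seed = 8)
  expect_lt(hi$total_reflectance, 0.05 * lo$total_reflectance)
  expect_lt(hi$dpf_pathlength_mm, lo$dpf_pathlength_mm)
  # monotone X decrease across a mu_a sweep at fixed scatter
  Xs <- vapply(c(0.05, 0.5, 5), function(mua)
    simulate_reflectance(optical_properties(mua, 21, 0.82), geom_fast,
                         n_photons = 2e4, seed = 9)$dpf_pathlength_mm, 0)
  expect_true(all(diff(Xs) < 0))
})

test_that("red light travels further and probes deeper than green", {
  g <- simulate_reflectance(props_530, geom_fast, n_photons = 5e4, seed = 10)
  r <- simulate_reflectance(props_630, geom_fast, n_photons = 5e4, seed = 10)
  expect_gt(r$dpf_pathlength_mm, g$dpf_pathlength_mm)
  z <- attr(g$sensitivity_xz, "z_centers_mm")
  mean_depth <- function(s) sum(z * s$depth_profile) / sum(s$depth_profile)
  expect_gt(mean_depth(r), mean_depth(g))
})

test_that("dpf standard error shrinks like one over root n", {
  dpf_batch <- function(n, seeds) vapply(seeds, function(s)
    simulate_reflectance(props_530, geom_fast, n_photons = n,
                         seed = s)$dpf_pathlength_mm, 0)
  se1 <- sd(dpf_batch(2e3, 101:110))
  se4 <- sd(dpf_batch(8e3, 201:210))
  # expect roughly a factor 2; allow wide slack for 10-batch noise
  expect_gt(se1 / se4, 1.2)
  expect_lt(se1 / se4, 3.5)
})

test_that("fluorescence geometry weights detection to superficial layers", {
  prof_uniform <- rep(1, 20)
  f <- simulate_fluorescence(optical_properties(0.33, 21, 0.8),
                             optical_properties(0.55, 21, 0.82),
                             prof_uniform,
                             detection_geometry(bin_z_mm = 0.1),
                             n_photons = 2e4, seed = 12)
  det <- f$detected_fraction_by_depth
  expect_gt(det[1], det[10])
  expect_gt(det[1], det[20])
  expect_gt(f$x_ex_mm, 0)
  expect_gt(f$x_em_mm, 0)

  # surface-confined fluorophore without absorption: short legs, maximal
  # detected fraction
  noabs <- optical_properties(0, 21, 0.8)
  surf <- simulate_fluorescence(noabs, noabs, c(1, rep(0, 19)),
                                detection_geometry(bin_z_mm = 0.1),
                                n_photons = 2e4, seed = 13)
  deep <- simulate_fluorescence(noabs, noabs, c(rep(0, 15), rep(1, 5)),
                                detection_geometry(bin_z_mm = 0.1),
                                n_photons = 2e4, seed = 13)
  expect_gt(surf$detected_total, deep$detected_total)
  # legs lengthen with fluorophore depth
  expect_lt(surf$x_em_mm, deep$x_em_mm)
  expect_lt(surf$x_ex_mm, deep$x_ex_mm)
  # deep-only labelling: every detected photon originated from that layer
  expect_equal(sum(deep$source_by_depth[1:15]), 0)
  # with realistic absorption the surface excitation leg is sub-millimetre
  # (long wandering paths are attenuated away)
  abs_ex <- optical_properties(1, 21, 0.8)
  surf_abs <- simulate_fluorescence(abs_ex, abs_ex, c(1, rep(0, 19)),
                                    detection_geometry(bin_z_mm = 0.1),
                                    n_photons = 2e4, seed = 13)
  expect_lt(surf_abs$x_ex_mm, 1)
})

test_that("pathlength tables are assembled per wavelength deterministically", {
  props <- list("530" = props_530)
  pt <- pathlength_table(props, geom_fast, n_photons = 5e3, seed = 14)
  expect_s3_class(pt, "pathlength_table")
  expect_equal(nrow(pt), 1)
  props2 <- list("500" = props_530, "530" = props_530)
  pt2 <- pathlength_table(props2, geom_fast, n_photons = 5e3, seed = 14)
  expect_identical(pt2$X_mm[1], pt2$X_mm[2])
  expect_identical(pt2$X_mm[2], pt$X_mm[1])
  expect_error(pathlength_table(list()), "at least one")
})

test_that("the packaged pathlength fixture loads and interpolates", {
  pt <- load_pathlengths()
  expect_true(all(pt$X_mm > 0))
  expect_gt(pathlength_at(pt, 630), pathlength_at(pt, 530))
  expect_error(pathlength_at(pt, 2000), "outside")
})
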