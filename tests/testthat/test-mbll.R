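make_stack <- function(counts, dark = 0) {
  image_stack(counts, channel = "t", dark = dark)
}

test_that("constant movies give zero reflectance change and gain cancels", {
  arr <- array(500, c(10, 4, 4))
  r <- reflectance_ratio(make_stack(arr), 1:3)
  expect_equal(max(abs(r$dr_over_r)), 0)
  # arbitrary positive gain map leaves the ratio untouched
  set.seed(1)
  gain <- matrix(runif(16, 0.5, 2), 4, 4)
  arr2 <- array(rexp(160, 1 / 500) + 100, c(10, 4, 4))
  rg <- reflectance_ratio(make_stack(sweep(arr2, 2:3, gain, "*")), 1:3)
  r0 <- reflectance_ratio(make_stack(arr2), 1:3)
  expect_equal(rg$ratio, r0$ratio, tolerance = 1e-12)
})

test_that("pixels at or below the dark level are masked, not propagated", {
  arr <- array(500, c(6, 3, 3))
  arr[, 2, 2] <- 40                       # below the dark level
  r <- reflectance_ratio(make_stack(arr, dark = 50), 1:2)
  expect_false(r$valid[2, 2])
  expect_true(all(is.na(r$ratio[, 2, 2])))
  expect_true(all(!is.na(r$ratio[, 1, 1])))
  expect_error(reflectance_ratio(make_stack(arr), integer(0)), "non-empty")
})

test_that("delta mu_a follows the closed form and round-trips", {
  expect_equal(delta_mua(array(1, c(2, 2, 2)), X = 2),
               array(0, c(2, 2, 2)))
  expect_equal(delta_mua(array(exp(-0.1), c(1, 1, 1)), X = 1)[1], 0.1)
  dm <- array(runif(27, -0.05, 0.3), c(3, 3, 3))
  X <- 0.7
  expect_equal(delta_mua(exp(-dm * X), X), dm, tolerance = 1e-12)
  # non-positive ratios are masked
  expect_true(is.na(delta_mua(array(c(-1, 1), c(2, 1, 1)), 1)[1, 1, 1]))
})

fwd_dmua <- function(d_hbo, d_hbr, xi) {
  list(a = xi[1, 1] * d_hbo + xi[1, 2] * d_hbr,
       b = xi[2, 1] * d_hbo + xi[2, 2] * d_hbr)
}

test_that("two-wavelength inversion recovers forward-generated truth", {
  xi <- xi_matrix(hb_table, list(530, 630))
  z <- array(0, c(4, 3, 3))
  h0 <- solve_two_wavelengths(z, z, xi)
  expect_equal(max(abs(h0$d_hbo)), 0)
  expect_equal(max(abs(h0$d_hbt)), 0)

  d_hbo <- array(1e-6, c(4, 3, 3))
  d_hbr <- array(-5e-7, c(4, 3, 3))
  f <- fwd_dmua(d_hbo, d_hbr, xi)
  h <- solve_two_wavelengths(f$a, f$b, xi, wavelengths_nm = c(530, 630))
  expect_equal(h$d_hbo, d_hbo, tolerance = 1e-12)
  expect_equal(h$d_hbr, d_hbr, tolerance = 1e-12)
  expect_identical(h$d_hbt, h$d_hbo + h$d_hbr)

  xi_same <- xi_matrix(hb_table, list(530, 530))
  expect_error(solve_two_wavelengths(f$a, f$b, xi_same,
                                     wavelengths_nm = c(530, 530)),
               "530.*singular|singular")
})

test_that("multi-wavelength least squares matches the determined and oracle cases", {
  xi2 <- xi_matrix(hb_table, list(530, 630))
  d_hbo <- array(rnorm(36, 0, 1e-6), c(4, 3, 3))
  d_hbr <- array(rnorm(36, 0, 1e-6), c(4, 3, 3))
  f <- fwd_dmua(d_hbo, d_hbr, xi2)
  h2 <- solve_two_wavelengths(f$a, f$b, xi2)
  hm <- solve_multiwavelength(list(f$a, f$b), xi2)
  expect_equal(hm$d_hbo, h2$d_hbo, tolerance = 1e-10)

  xi3 <- xi_matrix(hb_table, list(490, 530, 630))
  dm3 <- list(xi3[1, 1] * d_hbo + xi3[1, 2] * d_hbr,
              xi3[2, 1] * d_hbo + xi3[2, 2] * d_hbr,
              xi3[3, 1] * d_hbo + xi3[3, 2] * d_hbr)
  h3 <- solve_multiwavelength(dm3, xi3)
  expect_equal(h3$d_hbo, d_hbo, tolerance = 1e-10)
  expect_lt(max(h3$residual), 1e-12)

  set.seed(7)
  dm3n <- dm3
  dm3n[[2]] <- dm3n[[2]] + array(rnorm(36, 0, 1e-3), c(4, 3, 3))
  hn <- solve_multiwavelength(dm3n, xi3)
  expect_gt(max(hn$residual), 0)
  # normal-equations oracle, computed explicitly
  B <- rbind(as.vector(dm3n[[1]]), as.vector(dm3n[[2]]),
             as.vector(dm3n[[3]]))
  sol <- solve(t(xi3) %*% xi3) %*% t(xi3) %*% B
  expect_equal(as.vector(hn$d_hbo), sol[1, ], tolerance = 1e-10)
  expect_equal(as.vector(hn$d_hbr), sol[2, ], tolerance = 1e-10)

  expect_error(solve_multiwavelength(list(f$a), xi2[1, , drop = FALSE]),
               "at least two")
  xi_rank1 <- rbind(c(1, 2), c(2, 4), c(3, 6))
  expect_error(solve_multiwavelength(dm3, xi_rank1), "rank deficient")
})

test_that("isosbestic HbT estimate is pathlength-consistent with the solver", {
  iso <- find_isosbestic(hb_table)
  xi_iso <- (iso$xi_hbo + iso$xi_hbr) / 2
  r1 <- isosbestic_hbt(array(1, c(2, 2, 2)), X_iso = 0.45,
                       xi_iso_decadic = xi_iso)
  expect_equal(max(abs(r1$d_hbt)), 0)

  # forward data where one channel is isosbestic: the pathlength-free
  # estimate and the two-wavelength solve agree on dHbT
  xi <- xi_matrix(hb_table, list(iso$wavelength_nm, 630))
  d_hbo <- array(2e-6, c(3, 2, 2)); d_hbr <- array(1e-6, c(3, 2, 2))
  f <- fwd_dmua(d_hbo, d_hbr, xi)
  X_iso <- 0.45
  ratio_iso <- exp(-f$a * X_iso)
  hbt_iso <- isosbestic_hbt(ratio_iso, X_iso, xi_iso)$d_hbt
  h <- solve_two_wavelengths(f$a, f$b, xi)
  expect_equal(hbt_iso, h$d_hbt, tolerance = 0.01)
  expect_warning(isosbestic_hbt(ratio_iso, X_iso, xi_iso, table = hb_table,
                                wavelength_nm = 630), "not isosbestic")
})

test_that("halving the pathlength doubles inferred concentrations", {
  xi <- xi_matrix(hb_table, list(530, 630))
  d_hbo <- array(1e-6, c(3, 2, 2)); d_hbr <- array(5e-7, c(3, 2, 2))
  f <- fwd_dmua(d_hbo, d_hbr, xi)
  X <- c(0.5, 3.0)
  ratio_a <- exp(-f$a * X[1]); ratio_b <- exp(-f$b * X[2])
  h_full <- solve_two_wavelengths(delta_mua(ratio_a, X[1]),
                                  delta_mua(ratio_b, X[2]), xi)
  h_half <- solve_two_wavelengths(delta_mua(ratio_a, X[1] / 2),
                                  delta_mua(ratio_b, X[2] / 2), xi)
  expect_equal(h_half$d_hbo, 2 * h_full$d_hbo, tolerance = 1e-10)
  expect_equal(h_half$d_hbt, 2 * h_full$d_hbt, tolerance = 1e-10)
})

test_that("pairwise consistency passes on consistent data and flags pathlength errors", {
  xi <- xi_matrix(hb_table, list(490, 530, 630))
  set.seed(11)
  d_hbo <- array(rnorm(48, 1e-6, 5e-7), c(4, 4, 3))
  d_hbr <- array(rnorm(48, -5e-7, 5e-7), c(4, 4, 3))
  dm <- lapply(1:3, function(i) xi[i, 1] * d_hbo + xi[i, 2] * d_hbr)
  pc <- pairwise_consistency(dm, xi, c(490, 530, 630))
  expect_lt(pc$discrepancy, 1e-10)
  expect_true(pc$pass)
  expect_length(pc$pairs, 3)

  # a 40% pathlength error on one wavelength breaks the agreement
  dm_bad <- dm
  dm_bad[[3]] <- dm_bad[[3]] * 1.4
  pc_bad <- pairwise_consistency(dm_bad, xi, c(490, 530, 630))
  expect_false(pc_bad$pass)
  expect_gt(pc_bad$discrepancy, pc_bad$tolerance)

  expect_error(pairwise_consistency(dm[1:2], xi[1:2, ], c(490, 530)),
               "three")
  expect_error(pairwise_consistency(dm, xi, c(530, 530, 630)), "distinct")
})
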