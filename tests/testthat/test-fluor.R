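# Phantoms configured so each correction's own assumptions hold exactly.

scene_exem <- function(...) small_scene(...)
# single-wavelength assumptions: same band at excitation and emission, and
# the reflectance pathlength equal to the sum of the two legs
scene_single <- function(...) small_scene(
  lambda_ex = 530, lambda_em = 530,
  pathlengths = c("530" = 0.56 + 0.57, "630" = 3.0), ...)

test_that("dark subtraction enables the gain field to cancel", {
  ph <- small_scene()
  fl <- forward_fluorescence(ph)
  r <- dark_subtract_ratio(fl, 1:10)
  # D = 0 stack: plain ratio
  arr <- array(rep(c(200, 300), 8), c(2, 2, 4))
  st0 <- image_stack(arr, dark = 0)
  expect_equal(dark_subtract_ratio(st0, 1)$ratio[2, 1, 1], 1.5)
  # constructing a stack without any dark argument defaults are explicit;
  # a NULL dark is refused
  st_bad <- st0; st_bad$dark <- NULL
  expect_error(dark_subtract_ratio(st_bad, 1), "dark")
  # gain invariance after subtraction
  ph2 <- small_scene()
  ph2$S_map <- ph2$S_map * 3
  fl2 <- forward_fluorescence(ph2)
  r2 <- dark_subtract_ratio(fl2, 1:10)
  expect_equal(r2$ratio, r$ratio, tolerance = 1e-12)
})

test_that("skipping dark subtraction biases dF/F, subtracting removes the bias", {
  ph <- small_scene()
  fl <- forward_fluorescence(ph, sigma = 0.03)  # dim: ~300 counts vs D=100
  act <- ph$masks$activity & !ph$masks$vessel
  truth <- ph$truth_cf
  # correct processing with the ex-em correction recovers the truth
  hemo <- invert_phantom(ph, c("530", "630"))
  model <- crosstalk_model(ph$x_ex, ph$x_em, xi_ex = ph$xi_ex,
                           xi_em = ph$xi_em)
  good <- correct_ex_em(dark_subtract_ratio(fl, 1:10), hemo, model)
  tr_good <- apply(matrix(good$ratio, nrow = ph$n_time)[, act], 1, mean)
  expect_lt(rel_rms(tr_good, truth), 1e-6)
  # same pipeline with the dark wrongly assumed zero: biased
  fl_nodark <- fl; fl_nodark$dark <- 0
  bad <- correct_ex_em(dark_subtract_ratio(fl_nodark, 1:10), hemo, model)
  tr_bad <- apply(matrix(bad$ratio, nrow = ph$n_time)[, act], 1, mean)
  expect_gt(rel_rms(tr_bad - 1, truth - 1), 0.05)
})

test_that("single-wavelength division is exact under its own assumptions", {
  ph <- scene_single()
  fl <- dark_subtract_ratio(forward_fluorescence(ph), 1:10)
  refl <- reflectance_ratio(forward_reflectance(ph, "530")[["530"]], 1:10)
  # identity when the reflectance ratio is 1
  unit <- refl; unit$ratio <- array(1, dim(refl$ratio))
  expect_equal(correct_single_wavelength(fl, unit)$ratio, fl$ratio)
  corr <- correct_single_wavelength(fl, refl)
  act <- ph$masks$activity & !ph$masks$vessel
  tr <- apply(matrix(corr$ratio, nrow = ph$n_time)[, act], 1, mean)
  expect_lt(rel_rms(tr, ph$truth_cf), 1e-10)
  # mismatched movies are refused
  expect_error(correct_single_wavelength(fl, refl$ratio[1:10, , ]),
               "share shape")
})

test_that("single-wavelength correction degrades gracefully off-assumption", {
  # unequal ex/em attenuation: division leaves a bounded residual that the
  # ex-em method does not have
  ph <- scene_exem()
  fl <- dark_subtract_ratio(forward_fluorescence(ph), 1:10)
  refl530 <- reflectance_ratio(forward_reflectance(ph, "530")[["530"]], 1:10)
  hemo <- invert_phantom(ph, c("530", "630"))
  model <- crosstalk_model(ph$x_ex, ph$x_em, xi_ex = ph$xi_ex,
                           xi_em = ph$xi_em)
  act <- ph$masks$activity & !ph$masks$vessel
  trace_of <- function(cr)
    apply(matrix(cr$ratio, nrow = ph$n_time)[, act], 1, mean)
  err_single <- rel_rms(trace_of(correct_single_wavelength(fl, refl530)),
                        ph$truth_cf)
  err_exem <- rel_rms(trace_of(correct_ex_em(fl, hemo, model)),
                      ph$truth_cf)
  expect_lt(err_exem, err_single)
  expect_lt(err_single, 0.05)    # bounded, not catastrophic
})

test_that("ex-em correction is exact with matched pathlengths and flips the dip", {
  ph <- scene_exem()
  fl <- dark_subtract_ratio(forward_fluorescence(ph), 1:10)
  hemo <- invert_phantom(ph, c("530", "630"))
  model <- crosstalk_model(ph$x_ex, ph$x_em, xi_ex = ph$xi_ex,
                           xi_em = ph$xi_em)
  # zero haemodynamics: multiplier is exactly 1
  z <- hemo_movie(array(0, dim(hemo$d_hbo)), array(0, dim(hemo$d_hbo)))
  expect_equal(correct_ex_em(fl, z, model)$ratio, fl$ratio)
  corr <- correct_ex_em(fl, hemo, model)
  act <- ph$masks$activity & !ph$masks$vessel
  tt <- (seq_len(ph$n_time) - 1) / ph$fs
  stim <- tt >= ph$stim_on & tt < ph$stim_off
  stim_core <- tt >= ph$stim_on + 0.5 & tt < ph$stim_off
  tr_un <- apply(matrix(fl$dff, nrow = ph$n_time)[, act], 1, mean)
  tr_co <- apply(matrix(corr$dff, nrow = ph$n_time)[, act], 1, mean)
  # uncorrected trace dips below baseline at peak hyperaemia; corrected
  # stays non-negative throughout and positive once the indicator rises
  expect_lt(min(tr_un[stim]), -0.005)
  expect_gte(min(tr_co[stim]), 0)
  expect_gt(min(tr_co[stim_core]), 0)
  expect_lt(rel_rms(tr_co + 1, ph$truth_cf), 1e-6)
})

test_that("corrections are invariant to fluorophore brightness", {
  ph <- scene_exem()
  hemo <- invert_phantom(ph, c("530", "630"))
  model <- crosstalk_model(ph$x_ex, ph$x_em, xi_ex = ph$xi_ex,
                           xi_em = ph$xi_em)
  c1 <- correct_ex_em(dark_subtract_ratio(forward_fluorescence(ph, 1),
                                          1:10), hemo, model)
  c2 <- correct_ex_em(dark_subtract_ratio(forward_fluorescence(ph, 2),
                                          1:10), hemo, model)
  expect_equal(c1$ratio, c2$ratio, tolerance = 1e-12)
})

test_that("correction suppresses vessel artefacts by an order of magnitude", {
  ph <- scene_exem()
  fl <- dark_subtract_ratio(forward_fluorescence(ph), 1:10)
  hemo <- invert_phantom(ph, c("530", "630"))
  model <- crosstalk_model(ph$x_ex, ph$x_em, xi_ex = ph$xi_ex,
                           xi_em = ph$xi_em)
  corr <- correct_ex_em(fl, hemo, model)
  inside <- ph$masks$vessel & ph$masks$activity
  outside <- !ph$masks$vessel & ph$masks$activity
  artefact <- function(dff) {
    M <- matrix(dff, nrow = ph$n_time)
    sqrt(mean((rowMeans(M[, inside]) - rowMeans(M[, outside]))^2))
  }
  expect_gt(artefact(fl$dff) / artefact(corr$dff), 10)
})

test_that("log-space PCA captures rank-1 contamination and matches its oracle", {
  set.seed(31)
  nt <- 80; npx <- 10
  tc <- sin(seq(0, 3 * pi, length.out = nt)) * 0.05
  spat <- runif(npx * npx, 0.2, 1)
  lnF <- -outer(tc, spat) + rnorm(nt * npx * npx, 0, 1e-4)
  ratio <- array(exp(lnF), c(nt, npx, npx))
  fl <- structure(list(ratio = ratio, dff = ratio - 1,
                       valid = matrix(TRUE, npx, npx),
                       baseline_window = 1:10, channel = "f"),
                  class = "fluor_ratio")
  out <- correct_pca_log(fl, reference = tc)
  expect_equal(out$removed$index, 1)
  # corrected movie temporally flat within 3x the injected noise floor
  sd_t <- apply(matrix(out$ratio, nrow = nt), 2, sd)
  expect_lt(mean(sd_t), 3e-4)
  # subtraction oracle in log space, bit-wise against the library path
  M <- log(matrix(ratio, nrow = nt))
  mu <- colMeans(M); Mc <- sweep(M, 2, mu)
  sv <- svd(Mc, nu = 5, nv = 5)
  tc1 <- sv$u[, 1] * sv$d[1]
  oracle <- exp(sweep(Mc - tcrossprod(tc1, sv$v[, 1]), 2, mu, "+"))
  expect_equal(matrix(out$ratio, nrow = nt), oracle, tolerance = 1e-12)
  # no contamination: nothing passes the correlation threshold
  flat <- array(exp(rnorm(nt * 16, 0, 1e-4)), c(nt, 4, 4))
  fl2 <- structure(list(ratio = flat, dff = flat - 1,
                        valid = matrix(TRUE, 4, 4),
                        baseline_window = 1:10, channel = "f"),
                   class = "fluor_ratio")
  out2 <- correct_pca_log(fl2, reference = tc)
  expect_null(out2$removed)
  expect_equal(out2$ratio, fl2$ratio)
  # ambiguous selection is refused
  expect_error(correct_pca_log(fl), "ambiguous")
})

test_that("PCA and ex-em corrections agree on the matched phantom", {
  ph <- scene_exem()
  fl <- dark_subtract_ratio(forward_fluorescence(ph), 1:10)
  hemo <- invert_phantom(ph, c("530", "630"))
  model <- crosstalk_model(ph$x_ex, ph$x_em, xi_ex = ph$xi_ex,
                           xi_em = ph$xi_em)
  exem <- correct_ex_em(fl, hemo, model)
  pca <- correct_pca_log(fl, reference = hemo)
  act <- ph$masks$activity & !ph$masks$vessel
  tr_e <- apply(matrix(exem$dff, nrow = ph$n_time)[, act], 1, mean)
  tr_p <- apply(matrix(pca$dff, nrow = ph$n_time)[, act], 1, mean)
  expect_lt(sqrt(mean((tr_e - tr_p)^2)), 0.05)
})

test_that("gamma-kernel fits recover known kinetics", {
  set.seed(41)
  dt <- 0.01; n <- 1500
  u <- rbinom(n, 1, 0.05) * runif(n, 0.5, 2)
  tk <- seq(0, by = dt, length.out = n)
  kern <- dgamma(tk, shape = 2, scale = 0.3) * dt
  y <- 1.5 * convolve(u, rev(kern), type = "open")[1:n] +
    rnorm(n, 0, 1e-3)
  fit <- fit_gamma_kernel(u, y, dt)
  expect_false(fit$degenerate)
  expect_equal(fit$shape, 2, tolerance = 0.1)
  expect_equal(fit$scale, 0.3, tolerance = 0.1)
  expect_equal(fit$amplitude, 1.5, tolerance = 0.1)
  # zero spike train: amplitude unidentifiable, flagged not fitted
  z <- fit_gamma_kernel(rep(0, n), y, dt)
  expect_true(z$degenerate)
  expect_true(is.na(z$amplitude))
  # narrow kernel limit: prediction approaches the scaled input
  fitd <- fit_gamma_kernel(u, 2 * u, dt)
  expect_lt(sqrt(mean((fitd$fitted - 2 * u)^2)) / sqrt(mean((2 * u)^2)),
            0.05)
})
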