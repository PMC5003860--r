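#' Image stack container
#'
#' A single-channel intensity movie with its dark reference. Data are stored
#' as a time x height x width array of counts; the dark signal is either a
#' scalar or a per-pixel height x width matrix.
#'
#' @param data numeric array, time x height x width.
#' @param channel channel label.
#' @param dark scalar or height x width matrix of dark counts (>= 0).
#' @param timestamps optional frame times in seconds (length = n frames).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, channel = "ch", dark = 0, timestamps = NULL) {
  if (length(dim(data)) != 3) stop("data must be a time x height x width array")
  if (any(!is.finite(data))) stop("intensity counts must be finite")
  d <- dim(data)
  if (is.matrix(dark)) {
    if (!identical(dim(dark), d[2:3]))
      stop("dark matrix must match the pixel grid")
  } else if (length(dark) != 1) {
    stop("dark must be a scalar or a height x width matrix")
  }
  if (any(dark < 0)) stop("dark must be >= 0")
  if (is.null(timestamps)) timestamps <- seq_len(d[1]) - 1
  if (length(timestamps) != d[1])
    stop("timestamps must have one entry per frame")
  structure(list(data = data, channel = channel, dark = dark,
                 timestamps = as.numeric(timestamps)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack '%s': %d frames, %d x %d px\n",
              x$channel, d[1], d[2], d[3]))
  invisible(x)
}

# Subtract dark from every frame (dark broadcast over time).
subtract_dark <- function(stack) {
  d <- dim(stack$data)
  dk <- if (is.matrix(stack$dark)) stack$dark else
    matrix(stack$dark, d[2], d[3])
  sweep(stack$data, 2:3, dk, "-")
}

#' Ratiometric reflectance movie
#'
#' Divides each dark-subtracted frame by the mean dark-subtracted baseline
#' frame. Static gain fields and the illumination distribution cancel in the
#' ratio, which is why the ratio (and dR/R = ratio - 1) is the lab-portable
#' quantity. Pixels whose baseline does not exceed the dark level are masked
#' invalid (NA in outputs, FALSE in `valid`), never silently propagated.
#'
#' @param stack an [image_stack()].
#' @param baseline_window integer frame indices defining the baseline epoch
#'   t0 (non-empty).
#' @return list of class `refl_ratio`: `ratio` (T x H x W), `dr_over_r`
#'   (ratio - 1), `valid` (H x W logical), `baseline_window`, `channel`.
#' @export
reflectance_ratio <- function(stack, baseline_window) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) == 0 || any(baseline_window < 1) ||
      any(baseline_window > d[1]))
    stop("baseline window must be a non-empty set of valid frame indices")
  sub <- subtract_dark(stack)
  base <- apply(sub[baseline_window, , , drop = FALSE], 2:3, mean)
  valid <- base > 0
  base[!valid] <- NA_real_
  ratio <- sweep(sub, 2:3, base, "/")  # NA baseline poisons masked pixels
  structure(list(ratio = ratio, dr_over_r = ratio - 1, valid = valid,
                 baseline_window = baseline_window, channel = stack$channel),
            class = "refl_ratio")
}

#' Differential absorption from a reflectance ratio
#'
#' `dmua = -ln(I(t)/I(t0)) / X`, the modified Beer-Lambert estimate of the
#' change in absorption coefficient, with X the mean differential pathlength
#' (mm) for that wavelength. Non-positive ratios are masked (NA).
#'
#' @param ratio a `refl_ratio` or a bare ratio array.
#' @param X mean differential pathlength (mm, > 0).
#' @return array of delta mu_a (mm^-1), same shape as the ratio.
#' @export
delta_mua <- function(ratio, X) {
  if (inherits(ratio, "refl_ratio")) ratio <- ratio$ratio
  if (!is.numeric(X) || length(X) != 1 || X <= 0)
    stop("X must be a positive scalar pathlength in mm")
  bad <- !is.na(ratio) & ratio <= 0
  if (any(bad)) ratio[bad] <- NA_real_
  -log(ratio) / X
}

#' Haemoglobin concentration-change movie
#'
#' @param d_hbo,d_hbr arrays (T x H x W) of concentration changes (M).
#'   `d_hbt` is always set to their sum.
#' @param baseline_window frame indices of the baseline epoch.
#' @param wavelengths_nm wavelengths used in the inversion (metadata).
#' @return An object of class `hemo_movie` with fields `d_hbo`, `d_hbr`,
#'   `d_hbt`.
#' @export
hemo_movie <- function(d_hbo, d_hbr, baseline_window = NULL,
                       wavelengths_nm = NULL) {
  if (!identical(dim(d_hbo), dim(d_hbr)))
    stop("d_hbo and d_hbr must have identical shape")
  structure(list(d_hbo = d_hbo, d_hbr = d_hbr, d_hbt = d_hbo + d_hbr,
                 baseline_window = baseline_window,
                 wavelengths_nm = wavelengths_nm),
            class = "hemo_movie")
}

#' @export
print.hemo_movie <- function(x, ...) {
  d <- dim(x$d_hbo)
  cat(sprintf("hemo_movie: %d frames, %d x %d px (wavelengths: %s)\n",
              d[1], d[2], d[3],
              if (is.null(x$wavelengths_nm)) "?" else
                paste(x$wavelengths_nm, collapse = "/")))
  invisible(x)
}

#' Extinction matrix for a set of channels
#'
#' Builds the n_wavelengths x 2 extinction matrix (columns HbO, HbR) on the
#' natural-log mm^-1 M^-1 scale expected by the solvers, from point
#' wavelengths or [led_band()]s.
#'
#' @param table an [extinction_table()].
#' @param bands list of [led_band()]s and/or numeric wavelengths (nm).
#' @return numeric matrix, one row per band, columns (HbO, HbR).
#' @export
xi_matrix <- function(table, bands) {
  rows <- lapply(bands, function(b) {
    if (inherits(b, "led_band"))
      c(band_effective_extinction(table, b, "HbO"),
        band_effective_extinction(table, b, "HbR"))
    else
      c(xi_at(table, b, "HbO"), xi_at(table, b, "HbR"))
  })
  xi_natural_mm(do.call(rbind, rows))
}

#' Two-wavelength haemoglobin inversion
#'
#' Solves the 2x2 linear system
#' `dmua(lambda_i) = xi_HbO(lambda_i) dHbO + xi_HbR(lambda_i) dHbR`
#' per pixel and frame. Extinctions must already be on the natural-log
#' mm^-1 M^-1 scale (see [xi_natural_mm()]; [xi_matrix()] builds such a
#' matrix from a table).
#'
#' @param dmua_a,dmua_b delta mu_a arrays (mm^-1) at the two wavelengths,
#'   identical shape.
#' @param xi 2x2 matrix, rows = wavelengths (a, b), columns = (HbO, HbR),
#'   natural-log mm^-1 M^-1.
#' @param wavelengths_nm optional length-2 labels for error messages and
#'   metadata.
#' @param max_condition condition number beyond which the pair is rejected
#'   as effectively singular.
#' @return A [hemo_movie()].
#' @export
solve_two_wavelengths <- function(dmua_a, dmua_b, xi, wavelengths_nm = NULL,
                                  max_condition = 1e8) {
  if (!identical(dim(dmua_a), dim(dmua_b)))
    stop("delta mu_a movies must share shape")
  xi <- as.matrix(xi)
  if (!identical(dim(xi), c(2L, 2L))) stop("xi must be 2x2")
  lab <- if (is.null(wavelengths_nm)) "(a, b)" else
    paste0("(", paste(wavelengths_nm, collapse = ", "), " nm)")
  if (!all(is.finite(xi)) || kappa(xi, exact = TRUE) > max_condition)
    stop("extinction matrix for wavelength pair ", lab,
         " is singular or ill-conditioned")
  inv <- solve(xi)
  d_hbo <- inv[1, 1] * dmua_a + inv[1, 2] * dmua_b
  d_hbr <- inv[2, 1] * dmua_a + inv[2, 2] * dmua_b
  hemo_movie(d_hbo, d_hbr, wavelengths_nm = wavelengths_nm)
}

#' Multi-wavelength least-squares haemoglobin inversion
#'
#' Per-pixel linear least squares of delta mu_a at >= 2 wavelengths onto the
#' (HbO, HbR) extinction columns. With exactly two wavelengths this reduces
#' to [solve_two_wavelengths()]. Also returns the per-pixel, per-frame
#' residual norm.
#'
#' @param dmua_list list of delta mu_a arrays (one per wavelength, identical
#'   shape).
#' @param xi n x 2 extinction matrix (natural-log mm^-1 M^-1), rows matching
#'   `dmua_list`.
#' @param wavelengths_nm optional labels.
#' @return A [hemo_movie()] with an extra `residual` array (T x H x W,
#'   Euclidean norm of the per-sample residual over wavelengths).
#' @export
solve_multiwavelength <- function(dmua_list, xi, wavelengths_nm = NULL) {
  xi <- as.matrix(xi)
  n <- length(dmua_list)
  if (n < 2) stop("at least two wavelengths are required")
  if (nrow(xi) != n || ncol(xi) != 2)
    stop("xi must be n_wavelengths x 2")
  if (qr(xi)$rank < 2) stop("extinction matrix is rank deficient")
  shp <- dim(dmua_list[[1]])
  for (m in dmua_list)
    if (!identical(dim(m), shp)) stop("delta mu_a movies must share shape")
  B <- do.call(rbind, lapply(dmua_list, as.vector))  # n x (T*H*W)
  pinv <- solve(crossprod(xi), t(xi))                # 2 x n
  sol <- pinv %*% ifelse(is.na(B), 0, B)
  # propagate masks: any NA across wavelengths masks the pixel sample
  na_any <- colSums(is.na(B)) > 0
  sol[, na_any] <- NA_real_
  res <- xi %*% sol - B
  rnorm <- sqrt(colSums(res^2))
  rnorm[na_any] <- NA_real_
  out <- hemo_movie(array(sol[1, ], shp), array(sol[2, ], shp),
                    wavelengths_nm = wavelengths_nm)
  out$residual <- array(rnorm, shp)
  out
}

#' Pathlength-free total-haemoglobin estimate at an isosbestic wavelength
#'
#' At a wavelength where HbO and HbR extinctions are equal, the reflectance
#' ratio depends only on the total haemoglobin change:
#' `dHbT = -ln(I/I0) / (X * xi_iso)`, with `xi_iso` the common extinction on
#' the natural-log scale. The raw `-ln(ratio)` is also returned since it is
#' proportional to dHbT irrespective of the pathlength and extinction
#' estimates.
#'
#' @param ratio a `refl_ratio` or ratio array at the isosbestic channel.
#' @param X_iso pathlength at the isosbestic wavelength (mm).
#' @param xi_iso_decadic isosbestic extinction (cm^-1 M^-1, decadic); the
#'   mean of the table's HbO/HbR values at that wavelength is the usual
#'   choice.
#' @param table,wavelength_nm optional: when given, the wavelength is checked
#'   to be isosbestic on the table within `iso_tol` (relative extinction
#'   difference); a warning is raised otherwise.
#' @param iso_tol relative tolerance for the isosbestic check (default 5%).
#' @return list: `d_hbt` (T x H x W, M), `neg_log_ratio` (pathlength-free).
#' @export
isosbestic_hbt <- function(ratio, X_iso, xi_iso_decadic, table = NULL,
                           wavelength_nm = NULL, iso_tol = 0.05) {
  if (!is.null(table) && !is.null(wavelength_nm)) {
    xo <- xi_at(table, wavelength_nm, "HbO")
    xr <- xi_at(table, wavelength_nm, "HbR")
    if (abs(xo - xr) / ((xo + xr) / 2) > iso_tol)
      warning("wavelength ", wavelength_nm,
              " nm is not isosbestic within ", 100 * iso_tol,
              "% on this table")
  }
  if (inherits(ratio, "refl_ratio")) ratio <- ratio$ratio
  nlr <- -log(ifelse(!is.na(ratio) & ratio <= 0, NA_real_, ratio))
  list(d_hbt = nlr / (X_iso * xi_natural_mm(xi_iso_decadic)),
       neg_log_ratio = nlr)
}

#' Pairwise-consistency check of a three-wavelength conversion
#'
#' Converts delta mu_a at three wavelengths to (dHbO, dHbR) using each of the
#' three possible pairs. If the modified Beer-Lambert assumptions (shared
#' chromophore mixture, correct pathlengths) hold, the three pairwise
#' solutions agree; a wavelength-dependent pathlength error breaks the
#' agreement. The discrepancy metric is the maximum over pairs of the RMS
#' difference from the pair-mean solution, relative to the RMS of the mean
#' solution (computed jointly over dHbO and dHbR).
#'
#' @param dmua_list list of exactly three delta mu_a arrays.
#' @param xi 3x2 extinction matrix (natural-log mm^-1 M^-1).
#' @param wavelengths_nm length-3 distinct wavelengths (labels).
#' @param tolerance maximum relative discrepancy accepted as "in agreement".
#' @return list of class `pairwise_consistency`: `pairs` (named list of
#'   [hemo_movie()]s), `discrepancy` (scalar), `pass` (logical), `tolerance`.
#' @export
pairwise_consistency <- function(dmua_list, xi, wavelengths_nm,
                                 tolerance = 0.05) {
  if (length(dmua_list) != 3)
    stop("exactly three wavelengths are required")
  if (length(wavelengths_nm) != 3 || anyDuplicated(wavelengths_nm))
    stop("three distinct wavelengths are required")
  xi <- as.matrix(xi)
  idx <- list(c(1, 2), c(2, 3), c(1, 3))
  pairs <- lapply(idx, function(ij)
    solve_two_wavelengths(dmua_list[[ij[1]]], dmua_list[[ij[2]]],
                          xi[ij, , drop = FALSE],
                          wavelengths_nm = wavelengths_nm[ij]))
  names(pairs) <- vapply(idx, function(ij)
    paste(wavelengths_nm[ij], collapse = "&"), "")
  stack <- function(h) c(h$d_hbo, h$d_hbr)
  mats <- vapply(pairs, stack, numeric(2 * length(dmua_list[[1]])))
  mu <- rowMeans(mats)
  scale <- sqrt(mean(mu^2, na.rm = TRUE))
  disc <- if (scale == 0) 0 else
    max(apply(mats, 2, function(v) sqrt(mean((v - mu)^2, na.rm = TRUE)))) /
      scale
  structure(list(pairs = pairs, discrepancy = disc,
                 pass = disc <= tolerance, tolerance = tolerance),
            class = "pairwise_consistency")
}

#' @export
print.pairwise_consistency <- function(x, ...) {
  cat(sprintf("pairwise consistency: discrepancy %.3g (tolerance %.3g) -> %s\n",
              x$discrepancy, x$tolerance, if (x$pass) "pass" else "FAIL"))
  invisible(x)
}
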