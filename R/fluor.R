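#' Dark-subtracted ratiometric fluorescence movie
#'
#' `ratio = (F - D)(t) / mean_baseline(F - D)`. Subtracting the dark signal
#' D before taking the ratio is what lets the static gain field (illumination
#' x detection x expression non-uniformity) cancel; on cameras the dark
#' level can be up to ~100 counts, comparable to dim fluorescence. The dark
#' reference must be supplied explicitly -- pass 0 to assert a dark-free
#' signal rather than having it assumed silently.
#'
#' @param stack an [image_stack()] whose `dark` field is set (scalar or
#'   per-pixel matrix); if the stack has no meaningful dark and you know
#'   that, construct it with `dark = 0`.
#' @param baseline_window frame indices of the baseline epoch.
#' @return list of class `fluor_ratio`: `ratio` (T x H x W), `dff`
#'   (ratio - 1), `valid`, `baseline_window`, `channel`.
#' @export
dark_subtract_ratio <- function(stack, baseline_window) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(stack$dark))
    stop("dark reference missing: supply a dark image/scalar ",
         "(use 0 explicitly for a dark-free signal)")
  r <- reflectance_ratio(stack, baseline_window)
  structure(list(ratio = r$ratio, dff = r$dr_over_r, valid = r$valid,
                 baseline_window = r$baseline_window, channel = r$channel),
            class = "fluor_ratio")
}

#' Single-wavelength haemodynamic correction
#'
#' Divides the fluorescence ratio by a co-registered diffuse-reflectance
#' ratio acquired near the fluorophore's emission band. Valid under two
#' approximations: the absorption change is the same at the excitation and
#' emission bands, and the reflectance pathlength approximates the sum of
#' the excitation and emission legs.
#'
#' @param fluor a `fluor_ratio`.
#' @param refl_ratio a `refl_ratio` (or bare ratio array) frame-aligned with
#'   the fluorescence movie.
#' @return list of class `corrected_fluor`: `ratio` (corrected), `dff`
#'   (corrected - 1), `method`.
#' @export
correct_single_wavelength <- function(fluor, refl_ratio) {
  stopifnot(inherits(fluor, "fluor_ratio"))
  rr <- if (inherits(refl_ratio, "refl_ratio")) refl_ratio$ratio else
    refl_ratio
  if (!identical(dim(fluor$ratio), dim(rr)))
    stop("fluorescence and reflectance movies must share shape ",
         "(frames x pixels) and frame clock")
  corrected <- fluor$ratio / rr
  structure(list(ratio = corrected, dff = corrected - 1,
                 method = "single_wavelength"),
            class = "corrected_fluor")
}

#' Cross-talk model for the excitation-emission correction
#'
#' Effective pathlengths for the excitation and emission legs of the
#' fluorescence path, and the decadic extinctions at the two bands. The
#' defaults X_est(ex) = 0.56 mm, X_est(em) = 0.57 mm are values found to
#' minimise vessel artefacts in Thy1-GCaMP mouse preparations; they are
#' preparation-specific configuration, not constants.
#'
#' @param x_est_ex,x_est_em effective pathlengths (mm, > 0).
#' @param xi_ex,xi_em length-2 vectors `c(xi_hbo, xi_hbr)` of decadic
#'   extinctions (cm^-1 M^-1) at the excitation and emission bands.
#' @return An object of class `crosstalk_model`.
#' @export
crosstalk_model <- function(x_est_ex = 0.56, x_est_em = 0.57,
                            xi_ex, xi_em) {
  if (x_est_ex <= 0 || x_est_em <= 0) stop("pathlengths must be positive")
  if (length(xi_ex) != 2 || length(xi_em) != 2)
    stop("xi_ex and xi_em must each be c(xi_hbo, xi_hbr)")
  if (any(c(xi_ex, xi_em) <= 0)) stop("band extinctions must be positive")
  structure(list(x_est_ex = x_est_ex, x_est_em = x_est_em,
                 xi_ex = xi_ex, xi_em = xi_em),
            class = "crosstalk_model")
}

# Delta mu_a movie at an arbitrary band from a haemoglobin movie, using
# decadic band extinctions c(xi_hbo, xi_hbr).
dmua_from_hemo <- function(hemo, xi_decadic) {
  xin <- xi_natural_mm(xi_decadic)
  xin[1] * hemo$d_hbo + xin[2] * hemo$d_hbr
}

#' Excitation-emission haemodynamic correction
#'
#' Computes per-pixel absorption changes at the excitation and emission
#' bands from a haemoglobin movie (itself inverted from >= 2 reflectance
#' wavelengths), then removes the multiplicative attenuation:
#' `corrected = ratio * exp(dmua_ex * X_est_ex + dmua_em * X_est_em)`.
#'
#' @param fluor a `fluor_ratio`.
#' @param hemo a [hemo_movie()] co-acquired with the fluorescence channel.
#' @param model a [crosstalk_model()].
#' @return list of class `corrected_fluor`: `ratio`, `dff`, `method`,
#'   `dmua_ex`, `dmua_em`.
#' @export
correct_ex_em <- function(fluor, hemo, model) {
  stopifnot(inherits(fluor, "fluor_ratio"), inherits(hemo, "hemo_movie"),
            inherits(model, "crosstalk_model"))
  if (!identical(dim(fluor$ratio), dim(hemo$d_hbo)))
    stop("fluorescence and haemoglobin movies must share shape")
  dmua_ex <- dmua_from_hemo(hemo, model$xi_ex)
  dmua_em <- dmua_from_hemo(hemo, model$xi_em)
  corrected <- fluor$ratio *
    exp(dmua_ex * model$x_est_ex + dmua_em * model$x_est_em)
  structure(list(ratio = corrected, dff = corrected - 1, method = "ex_em",
                 dmua_ex = dmua_ex, dmua_em = dmua_em),
            class = "corrected_fluor")
}

#' PCA correction of log-fluorescence
#'
#' Haemodynamic contamination of fluorescence is multiplicative, so in the
#' logarithm it is an additively separable component. The movie's log-ratio
#' is centred per pixel over time, decomposed by SVD over pixels x time, and
#' the haemodynamic component is identified as the one whose time course has
#' the largest absolute correlation with a reference haemodynamic trace
#' (from a haemoglobin movie or a reflectance ratio). Without a reference,
#' an explicit component index must be given: component order is not stable
#' across datasets, so the selection is never guessed automatically. The
#' selected rank-1 term is subtracted in log space and the result
#' exponentiated.
#'
#' @param fluor a `fluor_ratio`.
#' @param reference optional [hemo_movie()] or `refl_ratio` (or a bare
#'   numeric time course) supplying the haemodynamic reference trace.
#' @param component explicit component index (used when no reference is
#'   given).
#' @param n_components number of leading components to examine.
#' @param cor_threshold minimum |correlation| with the reference for a
#'   component to be treated as haemodynamic; if none passes, the movie is
#'   returned unchanged.
#' @return list of class `corrected_fluor`: `ratio`, `dff`, `method`,
#'   `removed` (list: `index`, `time_course`, `spatial_map`, `correlation`)
#'   or NULL when nothing was removed, and `candidates` (correlations of the
#'   leading components).
#' @export
correct_pca_log <- function(fluor, reference = NULL, component = NULL,
                            n_components = 5, cor_threshold = 0.5) {
  stopifnot(inherits(fluor, "fluor_ratio"))
  d <- dim(fluor$ratio)
  nt <- d[1]
  if (nt < n_components)
    stop("movie length (", nt, ") must be >= requested components (",
         n_components, ")")
  valid <- as.vector(fluor$valid)
  M <- matrix(fluor$ratio, nrow = nt)   # time x pixels
  M <- log(M[, valid, drop = FALSE])
  mu <- colMeans(M)
  Mc <- sweep(M, 2, mu)
  sv <- svd(Mc, nu = n_components, nv = n_components)
  k <- min(n_components, length(sv$d))
  tc <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)

  ref_trace <- NULL
  if (!is.null(reference)) {
    ref_trace <- if (inherits(reference, "hemo_movie"))
      apply(matrix(reference$d_hbt, nrow = nt), 1, mean, na.rm = TRUE)
    else if (inherits(reference, "refl_ratio"))
      apply(matrix(-log(reference$ratio), nrow = nt), 1, mean, na.rm = TRUE)
    else as.numeric(reference)
    if (length(ref_trace) != nt)
      stop("reference trace length must match the movie")
  }

  cors <- if (is.null(ref_trace)) rep(NA_real_, k) else
    vapply(seq_len(k), function(j) {
      if (stats::sd(tc[, j]) == 0) return(0)
      abs(stats::cor(tc[, j], ref_trace))
    }, 0)

  if (is.null(component)) {
    if (is.null(ref_trace))
      stop("component selection is ambiguous: supply a haemodynamic ",
           "reference or an explicit component index; leading component ",
           "count examined: ", k)
    if (max(cors) < cor_threshold) {
      # nothing identifiable as haemodynamic: return input unchanged
      return(structure(list(ratio = fluor$ratio, dff = fluor$ratio - 1,
                            method = "pca_log", removed = NULL,
                            candidates = cors),
                       class = "corrected_fluor"))
    }
    component <- which.max(cors)
  } else if (component < 1 || component > k) {
    stop("component index out of range 1..", k)
  }

  rank1 <- tcrossprod(tc[, component], sv$v[, component])
  Lc <- Mc - rank1
  out_valid <- exp(sweep(Lc, 2, mu, "+"))
  ratio <- array(NA_real_, d)
  R <- matrix(ratio, nrow = nt)
  R[, valid] <- out_valid
  ratio <- array(R, d)
  spatial <- matrix(NA_real_, d[2], d[3])
  spatial[valid] <- sv$v[, component]
  structure(list(ratio = ratio, dff = ratio - 1, method = "pca_log",
                 removed = list(index = component,
                                time_course = tc[, component],
                                spatial_map = spatial,
                                correlation = cors[component]),
                 candidates = cors),
            class = "corrected_fluor")
}

#' Fit a gamma-kernel neural-to-fluorescence model
#'
#' Models a corrected fluorescence trace as spiking activity convolved with
#' a gamma kernel: `pred = amplitude * (mua_rate (*) gamma_pdf(shape, rate
#' scale))`, capturing the combined dynamics of intracellular calcium and
#' indicator binding. The amplitude is profiled out linearly; shape and
#' scale are optimised in log space by Nelder-Mead least squares.
#'
#' @param mua_spike_rate multi-unit activity rate time series.
#' @param fluorescence corrected dF/F time series, same sampling.
#' @param dt sample interval (s).
#' @param init optional `c(shape, scale)` starting values.
#' @return list: `shape`, `scale` (s), `amplitude`, `residual` (RMS),
#'   `fitted`, `degenerate` (TRUE when the spike train carries no signal and
#'   the amplitude is unidentifiable), `convergence` (optim code).
#' @export
fit_gamma_kernel <- function(mua_spike_rate, fluorescence, dt,
                             init = c(2, 0.3)) {
  y <- as.numeric(fluorescence)
  u <- as.numeric(mua_spike_rate)
  if (length(y) != length(u))
    stop("series must share length and sampling rate")
  n <- length(y)
  if (all(u == 0)) {
    return(list(shape = NA_real_, scale = NA_real_, amplitude = NA_real_,
                residual = sqrt(mean(y^2)), fitted = rep(0, n),
                degenerate = TRUE, convergence = NA_integer_))
  }
  conv_pred <- function(shape, scale) {
    tk <- seq(0, by = dt, length.out = n)
    # per-bin kernel mass; degenerates cleanly to a delta as scale -> 0
    kern <- stats::pgamma(tk + dt, shape = shape, scale = scale) -
      stats::pgamma(tk, shape = shape, scale = scale)
    stats::convolve(u, rev(kern), type = "open")[seq_len(n)]
  }
  obj <- function(par) {
    p <- conv_pred(exp(par[1]), exp(par[2]))
    den <- sum(p^2)
    if (!is.finite(den) || den == 0) return(sum(y^2))
    a <- sum(p * y) / den
    sum((y - a * p)^2)
  }
  fit <- stats::optim(log(init), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$convergence != 0 && fit$convergence != 1)
    stop("gamma-kernel fit did not converge (optim code ",
         fit$convergence, ", objective ", signif(fit$value, 4), ")")
  shape <- exp(fit$par[1]); scale <- exp(fit$par[2])
  p <- conv_pred(shape, scale)
  a <- sum(p * y) / sum(p^2)
  list(shape = shape, scale = scale, amplitude = a,
       residual = sqrt(mean((y - a * p)^2)), fitted = a * p,
       degenerate = FALSE, convergence = fit$convergence)
}

#' Low-pass filter a movie or trace over time
#'
#' Simple FFT low-pass (hard cutoff) along the time axis, the recommended
#' pre-processing step to suppress heart-rate and breathing bands before
#' regression or PCA corrections (typical cutoff 3-5 Hz).
#'
#' @param x time series vector or T x H x W array.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz cutoff frequency (Hz), default 5.
#' @return filtered object of the same shape.
#' @export
lowpass_time <- function(x, fs, cutoff_hz = 5) {
  filt1 <- function(v) {
    n <- length(v)
    f <- stats::fft(v)
    freq <- (seq_len(n) - 1) / n * fs
    freq <- pmin(freq, fs - freq)
    f[freq > cutoff_hz] <- 0
    Re(stats::fft(f, inverse = TRUE)) / n
  }
  if (is.null(dim(x))) return(filt1(x))
  d <- dim(x)
  M <- matrix(x, nrow = d[1])
  out <- apply(M, 2, filt1)
  array(out, d)
}
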