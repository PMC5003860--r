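# Synthetic cortical phantom: vessel compartments over blurred parenchyma,
# compartment-specific haemoglobin dynamics, a fluorophore activity signal,
# and the multiplicative forward model that turns them into camera counts.

# Separable Gaussian blur with replicate padding (small kernels only).
blur_gauss <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    stats::convolve(vp, rev(k), type = "open")[(2 * r + 1):(2 * r + length(v))]
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(m2, 1, pad_conv))
}

# Stimulus-locked response: boxcar stimulus convolved with a gamma kernel,
# peak-normalised. Deterministic.
stim_response <- function(n_time, fs, stim_on, stim_off, shape, scale) {
  tt <- (seq_len(n_time) - 1) / fs
  stim <- as.numeric(tt >= stim_on & tt < stim_off)
  kern <- stats::dgamma(tt, shape = shape, scale = scale) / fs
  resp <- stats::convolve(stim, rev(kern), type = "open")[seq_len(n_time)]
  if (max(resp) > 0) resp / max(resp) else resp
}

#' Generate a synthetic cortical scene
#'
#' Builds a deterministic phantom: surface artery and vein bands (plus
#' arteriole/venule for the five-compartment variant) over a blurred
#' capillary/parenchyma background, compartment-specific dHbO/dHbR/dHbT
#' time courses with the expected vascular signatures (artery: blood volume
#' rises with little deoxy change; vein: strong deoxy washout with minimal
#' volume change; capillary: intermediate, delayed), a fluorophore activity
#' ratio with fast onset and adaptation, a smooth static gain field, a dark
#' level, and the effective pathlengths for each channel. All randomness
#' derives from `seed`.
#'
#' @param seed RNG seed fixing the gain field and any noise drawn later.
#' @param nx,ny image height and width (pixels).
#' @param n_time frames per channel.
#' @param fs frame rate per channel (Hz).
#' @param stim_on,stim_off stimulus window (s).
#' @param n_compartments 3 (artery, capillary, vein) or 5 (adds arteriole
#'   and venule).
#' @param amp_scale global scaling of the haemoglobin response amplitudes.
#' @param dark_level camera dark level (counts; default 100, the upper end
#'   of typical EMCCD dark signal).
#' @param i0 illumination counts at baseline (pre-gain). 1e4 counts gives a
#'   per-frame shot-noise amplitude SNR of 100 (40 dB).
#' @param noise `"none"` or `"shot"` (Poisson on pre-dark counts, scaled by
#'   `gain`); `read_noise_sd` adds Gaussian read noise in counts.
#' @param gain camera counts per photoelectron for the scaled-Poisson model.
#' @param read_noise_sd Gaussian read noise (counts).
#' @param table [extinction_table()] used by the forward model.
#' @param pathlengths named numeric vector X(lambda) in mm for the
#'   reflectance channels (names = wavelength in nm).
#' @param x_ex,x_em effective excitation/emission-leg pathlengths (mm) of
#'   the fluorescence forward model.
#' @param lambda_ex,lambda_em excitation and emission wavelengths (nm) for
#'   band extinctions.
#' @param cf_amplitude peak fluorophore activity (dF/F at onset).
#' @param cf_sustain sustained activity level as a fraction of the peak
#'   (adaptation).
#' @param capillary_blur_sigma Gaussian blur radius (px) of the capillary
#'   background field.
#' @return An object of class `phantom`.
#' @export
make_scene <- function(seed = 1, nx = 40, ny = 40, n_time = 120, fs = 10,
                       stim_on = 2, stim_off = 7, n_compartments = 3,
                       amp_scale = 1, dark_level = 100, i0 = 1e4,
                       noise = c("none", "shot"), gain = 1,
                       read_noise_sd = 0,
                       table = load_extinction(),
                       pathlengths = c("530" = 0.45, "630" = 3.0,
                                       "490" = 0.55),
                       x_ex = 0.56, x_em = 0.57,
                       lambda_ex = 488, lambda_em = 530,
                       cf_amplitude = 0.08, cf_sustain = 0.25,
                       capillary_blur_sigma = 2) {
  noise <- match.arg(noise)
  if (!n_compartments %in% c(1, 3, 5))
    stop("n_compartments must be 1, 3 or 5")
  if (nx < 16 || ny < 16) stop("scene must be at least 16 x 16 px")
  set.seed(as.integer(seed))

  col_band <- function(lo, hi) {
    m <- matrix(FALSE, nx, ny)
    m[, max(1, round(lo * ny)):min(ny, round(hi * ny))] <- TRUE
    m
  }
  masks <- list()
  if (n_compartments >= 3) {
    masks$artery <- col_band(0.18, 0.24)
    masks$vein <- col_band(0.76, 0.84)
  }
  if (n_compartments == 5) {
    masks$arteriole <- col_band(0.34, 0.37)
    masks$venule <- col_band(0.64, 0.67)
  }
  vessel <- Reduce(`|`, masks, matrix(FALSE, nx, ny))
  parenchyma <- !vessel
  # capillary bed: blurred parenchyma indicator (background-like field)
  capillary_w <- blur_gauss(parenchyma * 1, capillary_blur_sigma)
  capillary_w[vessel] <- 0

  # compartment weights: binary vessels + continuous capillary field
  weights <- c(lapply(masks, function(m) m * 1),
               list(capillary = capillary_w))

  # temporal signatures (M): every compartment has its own transit delay
  # (arterial side leads, venous side lags), so the concatenated signatures
  # are linearly independent -- the premise that makes seeded unmixing work
  sig <- function(hbt_peak, hbr_peak, shape, scale) {
    resp <- stim_response(n_time, fs, stim_on, stim_off, shape, scale)
    list(d_hbt = amp_scale * hbt_peak * resp,
         d_hbr = amp_scale * hbr_peak * resp)
  }
  truth <- list(
    artery = sig(12e-6, -0.5e-6, 3, 0.35),
    arteriole = sig(9e-6, -1e-6, 3, 0.45),
    capillary = sig(10e-6, -2e-6, 5, 0.5),
    venule = sig(6e-6, -4e-6, 6, 0.55),
    vein = sig(1e-6, -5e-6, 7, 0.6))
  truth <- truth[names(weights)]
  truth <- lapply(truth, function(s)
    c(s, list(d_hbo = s$d_hbt - s$d_hbr)))

  # fluorophore activity: fast rise at stimulus onset, adaptation to a
  # sustained plateau, decay at offset
  tt <- (seq_len(n_time) - 1) / fs
  on <- as.numeric(tt >= stim_on & tt < stim_off)
  onset <- stim_response(n_time, fs, stim_on, stim_off, 1.5, 0.15)
  adapt <- exp(-pmax(tt - stim_on, 0) / 1.5)
  act <- onset * (cf_sustain + (1 - cf_sustain) * adapt)
  if (max(act) > 0) act <- act / max(act)
  truth_cf <- 1 + cf_amplitude * act

  # fluorophore-expressing region: central disc covering parenchyma and
  # vessel crossings (uniform expression, so vessel artefacts in the
  # uncorrected movie are pure contamination)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rr <- outer(seq_len(nx), seq_len(ny),
              function(i, j) sqrt((i - cx)^2 + (j - cy)^2))
  activity <- rr <= 0.4 * min(nx, ny)

  # smooth static gain field (vignetting-like), deterministic from seed
  S_map <- 1 + 0.3 * blur_gauss(matrix(stats::runif(nx * ny, -1, 1), nx, ny),
                                4)

  band_xi <- function(lambda)
    c(xi_at(table, lambda, "HbO"), xi_at(table, lambda, "HbR"))

  structure(list(
    nx = nx, ny = ny, n_time = n_time, fs = fs,
    stim_on = stim_on, stim_off = stim_off,
    masks = c(masks, list(vessel = vessel, parenchyma = parenchyma,
                          activity = activity)),
    weights = weights, truth = truth, truth_cf = truth_cf,
    S_map = S_map, dark_level = dark_level, i0 = i0,
    noise = noise, gain = gain, read_noise_sd = read_noise_sd,
    table = table, pathlengths = pathlengths,
    x_ex = x_ex, x_em = x_em,
    lambda_ex = lambda_ex, lambda_em = lambda_em,
    xi_ex = band_xi(lambda_ex), xi_em = band_xi(lambda_em),
    seed = as.integer(seed), pixel_pitch_um = 20),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d x %d px, %d frames @ %g Hz, %d compartments\n",
              x$nx, x$ny, x$n_time, x$fs, length(x$weights)))
  invisible(x)
}

#' Ground-truth concentration fields of a phantom
#'
#' Expands the compartment weights and time courses into full T x H x W
#' arrays of dHbO/dHbR/dHbT (M), i.e. the truth the inverse pipeline should
#' recover.
#'
#' @param phantom a [make_scene()] phantom.
#' @return A [hemo_movie()].
#' @export
truth_fields <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  nt <- phantom$n_time
  acc <- function(field) {
    out <- array(0, c(nt, phantom$nx, phantom$ny))
    for (nm in names(phantom$weights)) {
      w <- phantom$weights[[nm]]
      tc <- phantom$truth[[nm]][[field]]
      out <- out + outer(tc, w)
    }
    out
  }
  hemo_movie(acc("d_hbo"), acc("d_hbr"))
}

# Delta mu_a field (mm^-1) of the phantom at a wavelength, from the truth.
phantom_dmua <- function(phantom, lambda) {
  h <- truth_fields(phantom)
  xi <- xi_natural_mm(c(xi_at(phantom$table, lambda, "HbO"),
                        xi_at(phantom$table, lambda, "HbR")))
  xi[1] * h$d_hbo + xi[2] * h$d_hbr
}

# Camera noise applied to pre-dark expected counts; deterministic given the
# RNG state.
apply_noise <- function(counts, phantom) {
  if (phantom$noise == "shot") {
    counts <- phantom$gain *
      array(stats::rpois(length(counts), counts / phantom$gain), dim(counts))
  }
  if (phantom$read_noise_sd > 0)
    counts <- counts + array(stats::rnorm(length(counts), 0,
                                          phantom$read_noise_sd),
                             dim(counts))
  counts
}

#' Forward-model reflectance movies from a phantom
#'
#' `I(r,t) = S(r) I0 exp(-dmua(r,t,lambda) X(lambda)) + D + noise`, the
#' modified Beer-Lambert law run forwards with the phantom's truth
#' concentrations. Channel k's noise stream is seeded from
#' `phantom$seed + 1000 * k`, so reruns are bit-identical.
#'
#' @param phantom a [make_scene()] phantom.
#' @param channels wavelengths to render (names into
#'   `phantom$pathlengths`); default all.
#' @return named list of [image_stack()], one per channel.
#' @export
forward_reflectance <- function(phantom, channels = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  if (is.null(channels)) channels <- names(phantom$pathlengths)
  channels <- as.character(channels)
  missing <- setdiff(channels, names(phantom$pathlengths))
  if (length(missing))
    stop("no pathlength configured for channel(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(seq_along(channels), function(k) {
    ch <- channels[k]
    lambda <- as.numeric(ch)
    dmua <- phantom_dmua(phantom, lambda)
    X <- phantom$pathlengths[[ch]]
    counts <- sweep(exp(-dmua * X), 2:3, phantom$S_map * phantom$i0, "*")
    set.seed(phantom$seed + 1000L * k)
    counts <- apply_noise(counts, phantom)
    image_stack(counts + phantom$dark_level, channel = ch,
                dark = phantom$dark_level,
                timestamps = (seq_len(phantom$n_time) - 1) / phantom$fs)
  })
  names(out) <- channels
  out
}

#' Forward-model the fluorescence movie from a phantom
#'
#' `F(r,t) = S(r) sigma c_f(r,t) exp(-[dmua_ex x_ex + dmua_em x_em]) + D +
#' noise`: the fluorophore activity modulated by the multiplicative
#' haemodynamic attenuation of the excitation and emission legs. The
#' attenuation is multiplicative in the ratio, so scaling the brightness
#' `sigma` changes no downstream corrected dF/F.
#'
#' @param phantom a [make_scene()] phantom.
#' @param sigma fluorophore brightness (conversion efficiency x baseline
#'   concentration), arbitrary counts scale.
#' @return An [image_stack()] for the fluorescence channel.
#' @export
forward_fluorescence <- function(phantom, sigma = 1) {
  stopifnot(inherits(phantom, "phantom"))
  dmua_ex <- phantom_dmua(phantom, phantom$lambda_ex)
  dmua_em <- phantom_dmua(phantom, phantom$lambda_em)
  atten <- exp(-(dmua_ex * phantom$x_ex + dmua_em * phantom$x_em))
  cf <- 1 + outer(phantom$truth_cf - 1, phantom$masks$activity * 1)
  counts <- sweep(cf * atten, 2:3,
                  phantom$S_map * phantom$i0 * sigma, "*")
  set.seed(phantom$seed + 77L)
  counts <- apply_noise(counts, phantom)
  image_stack(counts + phantom$dark_level, channel = "fluor",
              dark = phantom$dark_level,
              timestamps = (seq_len(phantom$n_time) - 1) / phantom$fs)
}

#' Write phantom truth tables as CSV
#'
#' Long-format truth time courses (compartment, time_s, quantity, value)
#' plus the fluorophore activity ratio; written atomically.
#'
#' @param phantom a [make_scene()] phantom.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(phantom, path) {
  tt <- (seq_len(phantom$n_time) - 1) / phantom$fs
  rows <- do.call(rbind, lapply(names(phantom$truth), function(nm) {
    s <- phantom$truth[[nm]]
    do.call(rbind, lapply(c("d_hbo", "d_hbr", "d_hbt"), function(q)
      data.frame(compartment = nm, time_s = tt, quantity = q,
                 value = s[[q]])))
  }))
  rows <- rbind(rows, data.frame(compartment = "activity", time_s = tt,
                                 quantity = "cf_ratio",
                                 value = phantom$truth_cf))
  write_atomic_csv(rows, path)
  invisible(path)
}
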