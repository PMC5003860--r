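#' Optical properties of the tissue at one wavelength
#'
#' @param mua absorption coefficient (mm^-1, natural log), >= 0.
#' @param mus scattering coefficient (mm^-1), > 0.
#' @param g Henyey-Greenstein anisotropy, in (-1, 1).
#' @param n_rel refractive index of tissue relative to the detection medium
#'   (>= 1). Default 1.37 (brain/air).
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(mua, mus, g = 0.85, n_rel = 1.37) {
  if (mua < 0) stop("mua must be >= 0")
  if (mus <= 0) stop("mus must be > 0")
  if (g <= -1 || g >= 1) stop("g must be in (-1, 1)")
  if (n_rel < 1) stop("n_rel must be >= 1")
  structure(list(mua = mua, mus = mus, g = g, n_rel = n_rel),
            class = "optical_properties")
}

#' Detection geometry for the wide-field simulation
#'
#' Uniform planar, unidirectional illumination with a low-NA detection lens.
#' The sensitivity grid is binned in lateral distance x from the detection
#' pixel centre (signed, half-open bins) and depth z below the surface.
#'
#' @param na numerical-aperture acceptance (sine of the half-angle in the
#'   detection medium), in (0, 1].
#' @param x_half_extent_mm lateral half-width of the sensitivity grid (mm).
#' @param z_extent_mm depth extent of the sensitivity grid (mm).
#' @param bin_xy_mm,bin_z_mm bin sizes (mm).
#' @param depth_cutoff_mm photons deeper than this are terminated and
#'   counted as transmitted (default 10 mm, far beyond visible-band
#'   penetration in cortex).
#' @return An object of class `detection_geometry`.
#' @export
detection_geometry <- function(na = 0.2, x_half_extent_mm = 2.5,
                               z_extent_mm = 5, bin_xy_mm = 0.05,
                               bin_z_mm = 0.05, depth_cutoff_mm = 10) {
  if (na <= 0 || na > 1) stop("na must be in (0, 1]")
  if (bin_xy_mm <= 0 || bin_z_mm <= 0 || x_half_extent_mm <= 0 ||
      z_extent_mm <= 0 || depth_cutoff_mm <= 0)
    stop("geometry extents and bins must be positive")
  structure(list(na = na, x_half_extent_mm = x_half_extent_mm,
                 z_extent_mm = z_extent_mm, bin_xy_mm = bin_xy_mm,
                 bin_z_mm = bin_z_mm, depth_cutoff_mm = depth_cutoff_mm),
            class = "detection_geometry")
}

#' Scattering coefficient spectral power law
#'
#' `mus(lambda) = mus_ref * (lambda / lambda_ref)^(-b)`; for brain tissue b
#' is typically between 1.3 and 2.
#'
#' @param mus_ref scattering coefficient at the reference wavelength (mm^-1).
#' @param lambda_ref reference wavelength (nm).
#' @param b scatter power (dimensionless).
#' @param lambda target wavelength(s) (nm).
#' @return mus at `lambda` (mm^-1).
#' @export
scatter_power_law <- function(mus_ref, lambda_ref, b, lambda) {
  if (mus_ref <= 0 || lambda_ref <= 0 || any(lambda <= 0))
    stop("mus_ref, lambda_ref and lambda must be positive")
  mus_ref * (lambda / lambda_ref)^(-b)
}

#' Monte Carlo diffuse-reflectance simulation
#'
#' Simulates photon transport in a homogeneous semi-infinite medium under
#' uniform planar unidirectional illumination and low-NA surface detection.
#' Absorption is continuous weight attenuation along the path (so the stored
#' detected pathlengths support absorption-perturbation identities);
#' scattering is Henyey-Greenstein; Russian roulette terminates low-weight
#' photons; an optional Fresnel boundary reflects photons back at the
#' surface according to `n_rel`.
#'
#' The result's `dpf_pathlength_mm` is the detected-weight-averaged total
#' pathlength X -- the mean differential pathlength used by the modified
#' Beer-Lambert conversion. `sensitivity_xz` is the partial-pathlength map
#' d(M)/d(mu_a)(x, z) relative to the detection pixel.
#'
#' @param props [optical_properties()].
#' @param geom [detection_geometry()].
#' @param n_photons number of photons (>= 1e4 recommended for map output).
#' @param seed RNG seed (all randomness derives from it; fixed seed gives a
#'   bit-reproducible result).
#' @param fresnel apply Fresnel reflection at the exit surface (default
#'   TRUE; set FALSE for an index-matched boundary).
#' @param roulette_weight,roulette_survive Russian-roulette threshold and
#'   survival probability.
#' @param max_steps per-photon step cap (safety).
#' @return An object of class `sensitivity_result`: `dpf_pathlength_mm`,
#'   `sensitivity_xz` (nx x nz, with `x_centers_mm`/`z_centers_mm` attrs),
#'   `depth_profile`, `lateral_profile`, `overflow`, `total_reflectance`,
#'   weight ledger (`w_*`), `detected_pathlengths`, `detected_weights`,
#'   `n_photons`, `seed`, `props`, `geom`.
#' @export
simulate_reflectance <- function(props, geom = detection_geometry(),
                                 n_photons = 1e5, seed = 1,
                                 fresnel = TRUE, roulette_weight = 1e-4,
                                 roulette_survive = 0.1, max_steps = 1e6L) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(geom, "detection_geometry"))
  set.seed(as.integer(seed))
  raw <- .mc_reflectance(as.integer(n_photons), props$mua, props$mus,
                         props$g, props$n_rel, geom$na,
                         geom$depth_cutoff_mm, geom$x_half_extent_mm,
                         geom$z_extent_mm, geom$bin_xy_mm, geom$bin_z_mm,
                         fresnel, roulette_weight, roulette_survive,
                         as.integer(max_steps))
  sens <- raw$sensitivity_xz
  if (any(!is.finite(sens))) stop("non-finite weights in sensitivity map")
  nx <- nrow(sens); nz <- ncol(sens)
  attr(sens, "x_centers_mm") <-
    -geom$x_half_extent_mm + (seq_len(nx) - 0.5) * geom$bin_xy_mm
  attr(sens, "z_centers_mm") <- (seq_len(nz) - 0.5) * geom$bin_z_mm
  structure(c(raw[setdiff(names(raw), "sensitivity_xz")],
              list(sensitivity_xz = sens,
                   depth_profile = colSums(sens),
                   lateral_profile = rowSums(sens),
                   n_photons = as.integer(n_photons),
                   seed = as.integer(seed),
                   fresnel = fresnel, props = props, geom = geom)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(paste0("sensitivity_result: %d photons, X = %.3f mm, ",
                     "R_detected = %.4f\n"),
              x$n_photons, x$dpf_pathlength_mm, x$total_reflectance))
  invisible(x)
}

#' Weight-conservation ledger of a simulation
#'
#' Detected + escaped-outside-NA + transmitted-below-cutoff + absorbed +
#' roulette losses - roulette gains must equal the launched weight.
#'
#' @param result a `sensitivity_result`.
#' @return list with `accounted`, `launched`, `relative_error`.
#' @export
weight_conservation <- function(result) {
  acc <- result$w_detected + result$w_escaped + result$w_transmitted +
    result$w_absorbed + result$w_roulette_loss - result$w_roulette_gain
  launched <- result$n_photons
  list(accounted = acc, launched = launched,
       relative_error = abs(acc - launched) / launched)
}

#' Reflectance under a perturbed absorption, from the same photon set
#'
#' Re-weights the stored detected photons for an absorption change `dmua`:
#' `R(mua + dmua) = sum_i w_i exp(-dmua * L_i) / N`. The finite difference
#' `-(ln R(mua+d) - ln R(mua)) / d` converges to the mean detected
#' pathlength as d -> 0 (the adjoint identity behind the sensitivity map).
#'
#' @param result a `sensitivity_result`.
#' @param dmua absorption perturbation (mm^-1).
#' @return perturbed total reflectance (fraction of launched photons).
#' @export
reweighted_reflectance <- function(result, dmua) {
  sum(result$detected_weights * exp(-dmua * result$detected_pathlengths)) /
    result$n_photons
}

#' Monte Carlo epifluorescence simulation
#'
#' Two-leg transport: excitation photons propagate at the excitation-band
#' properties and build a depth-resolved fluence; emission photons are
#' launched isotropically from depths sampled proportional to fluence times
#' the fluorophore depth profile, propagate at the emission-band properties,
#' and are detected at the surface within the NA cone.
#'
#' @param props_ex,props_em [optical_properties()] at the excitation and
#'   emission bands.
#' @param fluorophore_depth_profile non-negative vector of relative
#'   fluorophore density per depth bin (bin size `bin_z_mm`, starting at the
#'   surface); normalised internally.
#' @param geom [detection_geometry()] (`na`, `bin_z_mm`, `depth_cutoff_mm`
#'   used).
#' @param n_photons photons per pass.
#' @param seed RNG seed.
#' @inheritParams simulate_reflectance
#' @return list of class `fluor_sensitivity`: `x_ex_mm` (mean excitation-leg
#'   pathlength, conversion- and detection-weighted), `x_em_mm` (mean
#'   emission-leg pathlength of detected photons), `detected_fraction_by_depth`,
#'   `source_by_depth`, `z_centers_mm`, `detected_total`, `n_photons`, `seed`.
#' @export
simulate_fluorescence <- function(props_ex, props_em,
                                  fluorophore_depth_profile,
                                  geom = detection_geometry(),
                                  n_photons = 1e5, seed = 1,
                                  fresnel = TRUE, roulette_weight = 1e-4,
                                  roulette_survive = 0.1, max_steps = 1e6L) {
  stopifnot(inherits(props_ex, "optical_properties"),
            inherits(props_em, "optical_properties"),
            inherits(geom, "detection_geometry"))
  prof <- as.numeric(fluorophore_depth_profile)
  if (any(prof < 0) || sum(prof) <= 0)
    stop("fluorophore depth profile must be non-negative with positive sum")
  prof <- prof / sum(prof)
  set.seed(as.integer(seed))
  raw <- .mc_fluorescence(as.integer(n_photons),
                          props_ex$mua, props_ex$mus, props_ex$g,
                          props_em$mua, props_em$mus, props_em$g,
                          props_ex$n_rel, geom$na, geom$depth_cutoff_mm,
                          prof, geom$bin_z_mm, fresnel, roulette_weight,
                          roulette_survive, as.integer(max_steps))
  nz <- length(prof)
  # excitation leg: mean path to reach each depth bin, weighted by the
  # emission source strength and per-bin detection probability
  mean_L_bin <- ifelse(raw$fluence > 0, raw$fluence_L / raw$fluence, 0)
  det_frac <- ifelse(raw$launched_w > 0, raw$detected_w / raw$launched_w, 0)
  wts <- raw$source * det_frac
  x_ex <- if (sum(wts) > 0) sum(mean_L_bin * wts) / sum(wts) else NA_real_
  structure(list(x_ex_mm = x_ex,
                 x_em_mm = raw$mean_emission_path_mm,
                 detected_fraction_by_depth = det_frac,
                 source_by_depth = raw$source / sum(raw$source),
                 z_centers_mm = (seq_len(nz) - 0.5) * geom$bin_z_mm,
                 detected_total = raw$w_detected_total / n_photons,
                 n_photons = as.integer(n_photons),
                 seed = as.integer(seed)),
            class = "fluor_sensitivity")
}

#' Simulated pathlength table over wavelengths
#'
#' Runs [simulate_reflectance()] at each wavelength's optical properties and
#' collects the mean differential pathlengths X(lambda) into a table
#' consumable by the modified Beer-Lambert conversion. Each wavelength is
#' simulated from the same seed, so identical properties give identical X.
#'
#' @param props_by_wavelength named list: names are wavelengths in nm,
#'   values [optical_properties()].
#' @param geom [detection_geometry()].
#' @param n_photons photons per wavelength.
#' @param seed RNG seed.
#' @param ... passed to [simulate_reflectance()].
#' @return data frame of class `pathlength_table` with columns
#'   `wavelength_nm`, `X_mm`.
#' @export
pathlength_table <- function(props_by_wavelength,
                             geom = detection_geometry(),
                             n_photons = 1e5, seed = 1, ...) {
  if (length(props_by_wavelength) < 1)
    stop("at least one wavelength is required")
  wl <- as.numeric(names(props_by_wavelength))
  if (any(is.na(wl))) stop("list names must be wavelengths in nm")
  X <- vapply(props_by_wavelength, function(p)
    simulate_reflectance(p, geom, n_photons = n_photons, seed = seed,
                         ...)$dpf_pathlength_mm, 0)
  out <- data.frame(wavelength_nm = wl, X_mm = unname(X))
  class(out) <- c("pathlength_table", "data.frame")
  out
}

#' Load a pathlength table from CSV
#'
#' Two-column CSV `wavelength_nm`, `X_mm` (header required). The packaged
#' default is a synthetic table generated by [pathlength_table()] at
#' literature optical properties for cortex.
#'
#' @param path CSV path; default the packaged fixture.
#' @return A `pathlength_table` data frame.
#' @export
load_pathlengths <- function(path = system.file("extdata",
                                                "pathlength_mc_synthetic.csv",
                                                package = "wfomtools")) {
  if (!nzchar(path) || !file.exists(path))
    stop("pathlength table not found: '", path, "'")
  tab <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "X_mm") %in% names(tab)))
    stop("pathlength table '", path,
         "' must have columns wavelength_nm, X_mm")
  if (any(tab$X_mm <= 0)) stop("pathlengths must be positive")
  class(tab) <- c("pathlength_table", "data.frame")
  tab
}

#' Interpolate a pathlength table at a wavelength
#'
#' @param table a `pathlength_table`.
#' @param wavelength_nm wavelength(s) in nm, within the table range.
#' @return X in mm.
#' @export
pathlength_at <- function(table, wavelength_nm) {
  if (any(wavelength_nm < min(table$wavelength_nm)) ||
      any(wavelength_nm > max(table$wavelength_nm)))
    stop("wavelength outside pathlength table range")
  stats::approx(table$wavelength_nm, table$X_mm, xout = wavelength_nm)$y
}
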