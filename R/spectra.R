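#' Haemoglobin extinction table
#'
#' Container for molar extinction spectra of oxy- and deoxyhaemoglobin on a
#' common wavelength grid. Extinctions are stored decadic (base-10), in
#' cm^-1 M^-1, as in the standard compilations. All absorption coefficients
#' computed from them inside this package are natural-log mu_a in mm^-1; the
#' ln(10) (and cm to mm) conversion is applied exactly once, in
#' [xi_natural_mm()] / [baseline_mua()].
#'
#' @param wavelength_nm strictly increasing wavelength grid (nm), covering at
#'   least 450-700 nm.
#' @param xi_hbo,xi_hbr molar extinction of HbO2 / Hb (cm^-1 M^-1, decadic),
#'   positive, same length as `wavelength_nm`.
#' @return An object of class `extinction_table`.
#' @export
extinction_table <- function(wavelength_nm, xi_hbo, xi_hbr) {
  wavelength_nm <- as.numeric(wavelength_nm)
  xi_hbo <- as.numeric(xi_hbo)
  xi_hbr <- as.numeric(xi_hbr)
  n <- length(wavelength_nm)
  if (length(xi_hbo) != n || length(xi_hbr) != n)
    stop("wavelength_nm, xi_hbo and xi_hbr must have equal length")
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(xi_hbo)) ||
      any(!is.finite(xi_hbr)))
    stop("extinction table entries must be finite")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing with no duplicates")
  if (any(xi_hbo <= 0) || any(xi_hbr <= 0))
    stop("extinction coefficients must be positive")
  if (wavelength_nm[1] > 450 || wavelength_nm[n] < 700)
    stop("wavelength grid must cover at least 450-700 nm")
  structure(list(wavelength_nm = wavelength_nm, xi_hbo = xi_hbo,
                 xi_hbr = xi_hbr),
            class = "extinction_table")
}

#' Load the packaged haemoglobin extinction fixture
#'
#' Reads a 3-column CSV (`wavelength_nm`, `xi_hbo`, `xi_hbr`; header
#' required). The packaged default is a synthetic stand-in for the standard
#' HbO2/Hb compilation, built from literature anchor values and linearly
#' interpolated to a 1-nm grid over 450-700 nm.
#'
#' @param path path to a CSV file; default the packaged fixture.
#' @return An [extinction_table()].
#' @export
load_extinction <- function(path = system.file("extdata",
                                               "hb_extinction_synthetic.csv",
                                               package = "wfomtools")) {
  if (!nzchar(path) || !file.exists(path))
    stop("extinction fixture not found: '", path, "'")
  tab <- tryCatch(utils::read.csv(path),
                  error = function(e)
                    stop("could not parse extinction fixture '", path, "': ",
                         conditionMessage(e)))
  need <- c("wavelength_nm", "xi_hbo", "xi_hbr")
  if (!all(need %in% names(tab)))
    stop("extinction fixture '", path, "' must have columns ",
         paste(need, collapse = ", "))
  extinction_table(tab$wavelength_nm, tab$xi_hbo, tab$xi_hbr)
}

#' @export
print.extinction_table <- function(x, ...) {
  cat(sprintf("extinction_table: %d wavelengths, %.0f-%.0f nm\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  invisible(x)
}

#' Query extinction coefficients at arbitrary wavelengths
#'
#' Linear interpolation on the table grid; querying outside the grid is an
#' error (no extrapolation).
#'
#' @param table an [extinction_table()].
#' @param wavelength_nm wavelengths to query (nm).
#' @param chromophore `"HbO"` or `"HbR"`.
#' @return extinction (cm^-1 M^-1, decadic), same length as `wavelength_nm`.
#' @export
xi_at <- function(table, wavelength_nm, chromophore = c("HbO", "HbR")) {
  stopifnot(inherits(table, "extinction_table"))
  chromophore <- match.arg(chromophore)
  if (any(wavelength_nm < min(table$wavelength_nm)) ||
      any(wavelength_nm > max(table$wavelength_nm)))
    stop("wavelength outside extinction table grid (",
         min(table$wavelength_nm), "-", max(table$wavelength_nm), " nm)")
  y <- if (chromophore == "HbO") table$xi_hbo else table$xi_hbr
  stats::approx(table$wavelength_nm, y, xout = wavelength_nm)$y
}

#' LED illumination band
#'
#' Describes one illumination channel's spectral band: either an explicit
#' measured spectrum (wavelength + relative emission weight, normalised
#' internally to unit area) or a parametric approximation around a centre
#' wavelength (`"gaussian"` with the given FWHM, `"boxcar"` of width FWHM, or
#' `"delta"` for a monochromatic line).
#'
#' @param name channel label.
#' @param centre_nm centre wavelength (nm); required for parametric shapes.
#' @param fwhm_nm full width at half maximum (nm) for gaussian/boxcar.
#' @param shape `"gaussian"`, `"boxcar"` or `"delta"`.
#' @param spectrum optional data frame with columns `wavelength_nm`, `weight`
#'   (measured spectrum; overrides the parametric shape).
#' @return An object of class `led_band`.
#' @export
led_band <- function(name, centre_nm = NULL, fwhm_nm = NULL,
                     shape = c("gaussian", "boxcar", "delta"),
                     spectrum = NULL) {
  shape <- match.arg(shape)
  if (!is.null(spectrum)) {
    if (!all(c("wavelength_nm", "weight") %in% names(spectrum)))
      stop("measured spectrum needs columns wavelength_nm, weight")
    if (any(spectrum$weight < 0)) stop("spectrum weights must be >= 0")
    if (sum(spectrum$weight) <= 0) stop("spectrum weights sum to zero")
    shape <- "measured"
  } else {
    if (is.null(centre_nm)) stop("centre_nm required without a spectrum")
    if (shape != "delta" && (is.null(fwhm_nm) || fwhm_nm <= 0))
      stop("fwhm_nm > 0 required for shape '", shape, "'")
  }
  structure(list(name = name, centre_nm = centre_nm, fwhm_nm = fwhm_nm,
                 shape = shape, spectrum = spectrum),
            class = "led_band")
}

# Band weights evaluated on the extinction-table grid, normalised so the
# trapezoid-rule integral over the grid is 1. Delta bands are handled
# separately (pointwise lookup).
band_weights_on_grid <- function(band, grid_nm) {
  w <- switch(band$shape,
    delta = stop("delta band has no grid weights"),
    gaussian = {
      sd <- band$fwhm_nm / (2 * sqrt(2 * log(2)))
      exp(-0.5 * ((grid_nm - band$centre_nm) / sd)^2)
    },
    boxcar = as.numeric(abs(grid_nm - band$centre_nm) <= band$fwhm_nm / 2),
    measured = {
      sp <- band$spectrum
      out <- stats::approx(sp$wavelength_nm, sp$weight, xout = grid_nm,
                           yleft = 0, yright = 0)$y
      out
    })
  area <- trapz_grid(grid_nm, w)
  if (area <= 0) stop("band '", band$name, "' has no support on the grid")
  w / area
}

trapz_grid <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Spectrum-weighted effective extinction of a band
#'
#' Integrates the extinction spectrum under the band's (unit-area) emission
#' spectrum on the table grid: `int w(lambda) xi(lambda) dlambda`. For a
#' finite-width band this is the effective extinction the band "sees"; for a
#' delta band it is the pointwise value.
#'
#' @inheritParams xi_at
#' @param band an [led_band()]. Its support must lie within the table grid.
#' @return effective extinction (cm^-1 M^-1, decadic).
#' @export
band_effective_extinction <- function(table, band,
                                      chromophore = c("HbO", "HbR")) {
  stopifnot(inherits(table, "extinction_table"), inherits(band, "led_band"))
  chromophore <- match.arg(chromophore)
  if (band$shape == "delta")
    return(xi_at(table, band$centre_nm, chromophore))
  grid <- table$wavelength_nm
  lo <- min(grid); hi <- max(grid)
  supp <- band_support(band)
  if (supp[1] < lo || supp[2] > hi)
    stop("band '", band$name, "' support [", round(supp[1], 1), ", ",
         round(supp[2], 1), "] nm extends outside the table grid")
  w <- band_weights_on_grid(band, grid)
  xi <- if (chromophore == "HbO") table$xi_hbo else table$xi_hbr
  trapz_grid(grid, w * xi)
}

# Effective support used for the out-of-grid check; gaussians truncated at
# +/- 3 sigma (beyond that the weight is < 1.2e-4 of peak).
band_support <- function(band) {
  switch(band$shape,
    delta = rep(band$centre_nm, 2),
    gaussian = {
      sd <- band$fwhm_nm / (2 * sqrt(2 * log(2)))
      band$centre_nm + c(-3, 3) * sd
    },
    boxcar = band$centre_nm + c(-0.5, 0.5) * band$fwhm_nm,
    measured = range(band$spectrum$wavelength_nm[band$spectrum$weight > 0]))
}

#' Baseline blood-content assumptions
#'
#' The standard brain-tissue assumptions used to derive a baseline absorption
#' spectrum: haemoglobin concentration in whole blood, blood volume fraction
#' of tissue, and mean haemoglobin oxygen saturation. Defaults are 2 mM,
#' 3 % and 75 %.
#'
#' @param hb_blood_molar haemoglobin concentration in whole blood (M).
#' @param blood_volume_fraction volume fraction of blood in tissue, in [0,1].
#' @param oxygen_saturation mean HbO fraction of total haemoglobin, in [0,1].
#' @return An object of class `blood_assumptions`.
#' @export
blood_assumptions <- function(hb_blood_molar = 2e-3,
                              blood_volume_fraction = 0.03,
                              oxygen_saturation = 0.75) {
  if (hb_blood_molar < 0 || blood_volume_fraction < 0 ||
      oxygen_saturation < 0)
    stop("blood assumptions must be non-negative")
  if (oxygen_saturation > 1) stop("oxygen_saturation must be <= 1")
  if (blood_volume_fraction > 1) stop("blood_volume_fraction must be <= 1")
  structure(list(hb_blood_molar = hb_blood_molar,
                 blood_volume_fraction = blood_volume_fraction,
                 oxygen_saturation = oxygen_saturation),
            class = "blood_assumptions")
}

#' Convert decadic extinction to natural-log mm^-1 per molar
#'
#' `xi_natural = xi_decadic * ln(10) / 10`: the ln(10) moves from base-10 to
#' natural exponent, the /10 from cm^-1 to mm^-1. This is the single place
#' the base/unit conversion happens.
#'
#' @param xi_decadic_cm extinction in cm^-1 M^-1, decadic.
#' @return extinction in mm^-1 M^-1 on the natural-log scale.
#' @export
xi_natural_mm <- function(xi_decadic_cm) xi_decadic_cm * log(10) / 10

#' Baseline tissue absorption coefficient
#'
#' Natural-log absorption coefficient of bulk tissue (mm^-1) implied by the
#' blood-content assumptions:
#' `mu_a = ln(10)/10 * C_Hb * BVF * (S * xi_HbO + (1-S) * xi_HbR)`,
#' with extinctions taken at a single wavelength or integrated over an LED
#' band.
#'
#' @inheritParams xi_at
#' @param blood a [blood_assumptions()].
#' @param wavelength_or_band a wavelength in nm (possibly vectorised) or an
#'   [led_band()].
#' @return mu_a in mm^-1 (natural log).
#' @export
baseline_mua <- function(table, blood, wavelength_or_band) {
  stopifnot(inherits(table, "extinction_table"),
            inherits(blood, "blood_assumptions"))
  if (inherits(wavelength_or_band, "led_band")) {
    xo <- band_effective_extinction(table, wavelength_or_band, "HbO")
    xr <- band_effective_extinction(table, wavelength_or_band, "HbR")
  } else {
    xo <- xi_at(table, wavelength_or_band, "HbO")
    xr <- xi_at(table, wavelength_or_band, "HbR")
  }
  s <- blood$oxygen_saturation
  xi_mix <- s * xo + (1 - s) * xr
  xi_natural_mm(xi_mix) * blood$hb_blood_molar * blood$blood_volume_fraction
}

#' Empirical isosbestic wavelength of a table
#'
#' Grid wavelength minimising |xi_HbO - xi_HbR| within a search window
#' (default 500-560 nm, around the green isosbestic point).
#'
#' @inheritParams xi_at
#' @param window length-2 search window (nm).
#' @return list with `wavelength_nm`, `xi_hbo`, `xi_hbr`, `rel_diff`.
#' @export
find_isosbestic <- function(table, window = c(500, 560)) {
  stopifnot(inherits(table, "extinction_table"))
  sel <- table$wavelength_nm >= window[1] & table$wavelength_nm <= window[2]
  if (!any(sel)) stop("no grid wavelengths in the search window")
  d <- abs(table$xi_hbo - table$xi_hbr)[sel]
  i <- which(sel)[which.min(d)]
  list(wavelength_nm = table$wavelength_nm[i],
       xi_hbo = table$xi_hbo[i], xi_hbr = table$xi_hbr[i],
       rel_diff = abs(table$xi_hbo[i] - table$xi_hbr[i]) /
         ((table$xi_hbo[i] + table$xi_hbr[i]) / 2))
}

#' HbO contribution to red-band reflectance sensitivity
#'
#' Two readings of "fractional HbO contribution" to absorption in a red band:
#' `equal_concentration` weights HbO and HbR equally
#' (`xi_HbO / (xi_HbO + xi_HbR)`), `saturation_weighted` weights them by the
#' baseline saturation (`S xi_HbO / (S xi_HbO + (1-S) xi_HbR)`). Both are
#' returned; which one a given report intends is context-dependent.
#'
#' @inheritParams baseline_mua
#' @return list with both fractions.
#' @export
hbo_fraction_red <- function(table, blood, wavelength_or_band) {
  if (inherits(wavelength_or_band, "led_band")) {
    xo <- band_effective_extinction(table, wavelength_or_band, "HbO")
    xr <- band_effective_extinction(table, wavelength_or_band, "HbR")
  } else {
    xo <- xi_at(table, wavelength_or_band, "HbO")
    xr <- xi_at(table, wavelength_or_band, "HbR")
  }
  s <- blood$oxygen_saturation
  list(equal_concentration = xo / (xo + xr),
       saturation_weighted = s * xo / (s * xo + (1 - s) * xr))
}
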