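# Readers/writers, strobe demultiplexing, run configuration and the
# end-to-end pipeline. Conventions: image origin top-left, row-major,
# 1-based pixel indices in R interfaces (0-based in JSON ROI files); TIFF is
# multipage grayscale, 16-bit unsigned for counts and 32-bit float for
# derived products. All file writes are atomic (write to a temp file in the
# target directory, then rename).

write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("atomic rename failed for '", path, "'")
  invisible(path)
}

write_atomic_csv <- function(df, path)
  write_atomic(path, function(p)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE))

#' Write a movie as a multipage TIFF
#'
#' Counts movies are written 16-bit unsigned (values must fit in 0..65535).
#' Float products are written 32-bit, affinely mapped into [0, 1] (TIFF
#' sample storage), with the offset/scale recorded in a `<path>.scale.json`
#' sidecar so [read_movie_tiff()] restores the physical values. One page
#' per frame, frames in time order.
#'
#' @param movie T x H x W array.
#' @param path output path.
#' @param format `"uint16"` for counts, `"float"` for derived quantities.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, format = c("uint16", "float")) {
  format <- match.arg(format)
  if (length(dim(movie)) != 3) stop("movie must be T x H x W")
  if (format == "uint16") {
    if (any(movie < 0 | movie > 65535))
      stop("counts outside the 16-bit range")
    frames <- lapply(seq_len(dim(movie)[1]), function(t)
      movie[t, , ] / 65535)
    write_atomic(path, function(p)
      tiff::writeTIFF(frames, p, bits.per.sample = 16))
  } else {
    fin <- movie[is.finite(movie)]
    lo <- if (length(fin)) min(fin) else 0
    hi <- if (length(fin)) max(fin) else 1
    if (hi <= lo) hi <- lo + 1
    scaled <- (movie - lo) / (hi - lo)
    scaled[!is.finite(scaled)] <- 0
    frames <- lapply(seq_len(dim(movie)[1]), function(t) scaled[t, , ])
    write_atomic(path, function(p)
      tiff::writeTIFF(frames, p, bits.per.sample = 32, reduce = FALSE))
    write_atomic(paste0(path, ".scale.json"), function(p)
      jsonlite::write_json(list(lo = lo, hi = hi), p, auto_unbox = TRUE,
                           digits = NA))
  }
  invisible(path)
}

#' Read a multipage TIFF as a movie array
#'
#' Inverse of [write_movie_tiff()]. 16-bit files are rescaled back to
#' counts; float files are mapped back to physical values through their
#' `.scale.json` sidecar (taken as already-physical if the sidecar is
#' absent).
#'
#' @param path TIFF path.
#' @param format `"uint16"` or `"float"` (how the file was written).
#' @return T x H x W array.
#' @export
read_movie_tiff <- function(path, format = c("uint16", "float")) {
  format <- match.arg(format)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  if (format == "uint16") {
    arr <- round(arr * 65535)
  } else {
    side <- paste0(path, ".scale.json")
    if (file.exists(side)) {
      sc <- jsonlite::read_json(side, simplifyVector = TRUE)
      arr <- arr * (sc$hi - sc$lo) + sc$lo
    }
  }
  arr
}

#' Demultiplex an interleaved strobe acquisition
#'
#' Frame k (1-based) of the raw movie belongs to channel
#' `strobe_order[((k - 1) mod n) + 1]`. A trailing partial strobe cycle is
#' dropped with a message.
#'
#' @param stack an [image_stack()] of raw interleaved frames (its `dark`
#'   and timestamps are carried to every channel; per-channel darks can be
#'   assigned afterwards).
#' @param strobe_order character vector of channel names in strobe order.
#' @return named list of [image_stack()], one per distinct channel, frame
#'   order preserved.
#' @export
demux <- function(stack, strobe_order) {
  stopifnot(inherits(stack, "image_stack"))
  strobe_order <- as.character(strobe_order)
  n <- length(strobe_order)
  if (n == 0) stop("strobe_order must be non-empty")
  nt <- dim(stack$data)[1]
  n_cycles <- nt %/% n
  if (n_cycles == 0) stop("fewer frames than strobe channels")
  dropped <- nt - n_cycles * n
  if (dropped > 0)
    message("demux: dropping trailing partial cycle (", dropped, " frame",
            if (dropped > 1) "s" else "", ")")
  out <- lapply(unique(strobe_order), function(ch) {
    slots <- which(strobe_order == ch)
    idx <- as.vector(outer(slots, (seq_len(n_cycles) - 1) * n, "+"))
    idx <- sort(idx)
    image_stack(stack$data[idx, , , drop = FALSE], channel = ch,
                dark = stack$dark, timestamps = stack$timestamps[idx])
  })
  names(out) <- unique(strobe_order)
  out
}

#' Interleave per-channel movies into a strobe acquisition
#'
#' Inverse of [demux()] for equal-length channels; used by the phantom
#' writer and in round-trip tests.
#'
#' @param stacks named list of [image_stack()] with equal frame counts.
#' @param strobe_order channel names in strobe order (each exactly once).
#' @return An [image_stack()] of interleaved frames.
#' @export
interleave <- function(stacks, strobe_order) {
  strobe_order <- as.character(strobe_order)
  if (!setequal(strobe_order, names(stacks)) ||
      length(strobe_order) != length(stacks))
    stop("strobe_order must list each channel exactly once")
  nt <- dim(stacks[[1]]$data)[1]
  d <- dim(stacks[[1]]$data)
  out <- array(0, c(nt * length(stacks), d[2], d[3]))
  ts <- numeric(nt * length(stacks))
  for (k in seq_along(strobe_order)) {
    ch <- strobe_order[k]
    idx <- seq(k, by = length(stacks), length.out = nt)
    out[idx, , ] <- stacks[[ch]]$data
    ts[idx] <- stacks[[ch]]$timestamps
  }
  image_stack(out, channel = "interleaved", dark = stacks[[1]]$dark,
              timestamps = ts)
}

#' Extract ROI time courses as a long-format table
#'
#' @param hemo a [hemo_movie()].
#' @param rois named list of logical masks or n x 2 (row, col) matrices.
#' @param fs frame rate (Hz) for the time column.
#' @return data frame (roi, time_s, quantity, value).
#' @export
roi_time_courses <- function(hemo, rois, fs = 1) {
  nt <- dim(hemo$d_hbo)[1]
  d <- dim(hemo$d_hbo)
  do.call(rbind, lapply(names(rois), function(nm) {
    roi <- rois[[nm]]
    idx <- if (is.logical(roi)) which(roi) else
      (roi[, 2] - 1) * d[2] + roi[, 1]
    do.call(rbind, lapply(c("d_hbo", "d_hbr", "d_hbt"), function(q) {
      M <- matrix(hemo[[q]], nrow = nt)
      data.frame(roi = nm, time_s = (seq_len(nt) - 1) / fs, quantity = q,
                 value = rowMeans(M[, idx, drop = FALSE], na.rm = TRUE))
    }))
  }))
}

#' Read a run configuration
#'
#' YAML (or JSON) file with fields: `channels` (list of {name, role,
#' centre_nm, fwhm_nm}), `strobe_order`, `baseline_window` ([first, last]
#' frame, 1-based), `correction_method` (single|exem|pca), `seed`, optional
#' `pathlengths` (map wavelength -> X mm), `x_est_ex`, `x_est_em`,
#' `consistency_tolerance`, `unmix_rois`.
#'
#' @param path config file path.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
    else yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a raw config list (already parsed).
#' @export
validate_run_config <- function(cfg) {
  need <- c("channels", "strobe_order", "baseline_window",
            "correction_method")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("run config missing field(s): ", paste(miss, collapse = ", "))
  ch_names <- vapply(cfg$channels, function(ch) ch$name, "")
  if (!all(cfg$strobe_order %in% ch_names))
    stop("strobe order references undeclared channel(s): ",
         paste(setdiff(cfg$strobe_order, ch_names), collapse = ", "))
  if (length(cfg$baseline_window) != 2)
    stop("exactly one baseline window [first, last] is required")
  roles <- vapply(cfg$channels, function(ch) ch$role, "")
  refl <- ch_names[roles == "reflectance"]
  if (cfg$correction_method == "exem" && length(refl) < 2)
    stop("Ex-Em correction requires >= 2 reflectance wavelengths")
  if (!cfg$correction_method %in% c("single", "exem", "pca", "none"))
    stop("unknown correction method '", cfg$correction_method, "'")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

#' Run the full phantom-to-maps pipeline
#'
#' demux -> dark subtraction -> ratiometric movies -> modified Beer-Lambert
#' conversion (with three-wavelength pairwise-consistency check when three
#' reflectance channels are present) -> the chosen fluorescence correction
#' -> optional compartment unmixing. Every stage's parameters land in the
#' QC report; outputs are deterministic given the config and inputs.
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @param raw an [image_stack()] of raw interleaved frames, or a named list
#'   of per-channel stacks (already demuxed).
#' @param out_dir output directory (created if needed); NULL skips file
#'   output and returns results in memory only.
#' @param extinction an [extinction_table()].
#' @param pathlengths a `pathlength_table` or named vector X(lambda) mm;
#'   defaults to the config's `pathlengths`.
#' @return list: `hemo`, `consistency` (or NULL), `corrected` (or NULL),
#'   `unmix` (or NULL), `qc` (the QC report list).
#' @export
run_pipeline <- function(config, raw, out_dir = NULL,
                         extinction = load_extinction(),
                         pathlengths = NULL) {
  config <- validate_run_config(unclass(config))
  stage <- "demux"
  res <- tryCatch({
    stacks <- if (inherits(raw, "image_stack"))
      demux(raw, config$strobe_order) else raw
    ch_names <- vapply(config$channels, function(ch) ch$name, "")
    roles <- stats::setNames(vapply(config$channels, function(ch) ch$role,
                                    ""), ch_names)
    centres <- stats::setNames(vapply(config$channels, function(ch)
      as.numeric(ch$centre_nm), 0), ch_names)

    if (is.null(pathlengths)) pathlengths <- unlist(config$pathlengths)
    X_of <- function(lambda) {
      if (inherits(pathlengths, "pathlength_table"))
        pathlength_at(pathlengths, lambda)
      else {
        x <- pathlengths[[as.character(lambda)]]
        if (is.null(x)) stop("no pathlength for ", lambda, " nm")
        x
      }
    }

    bw <- seq(config$baseline_window[[1]], config$baseline_window[[2]])
    refl_ch <- ch_names[roles == "reflectance"]
    fluor_ch <- ch_names[roles == "fluorescence_excitation"]

    stage <- "ratiometric"
    ratios <- lapply(refl_ch, function(ch)
      reflectance_ratio(stacks[[ch]], bw))
    names(ratios) <- refl_ch

    stage <- "mbll"
    lambdas <- centres[refl_ch]
    dmuas <- lapply(refl_ch, function(ch)
      delta_mua(ratios[[ch]], X_of(centres[ch])))
    xi <- xi_matrix(extinction, as.list(lambdas))
    consistency <- NULL
    if (length(refl_ch) >= 3) {
      stage <- "pairwise_consistency"
      consistency <- pairwise_consistency(
        dmuas[1:3], xi[1:3, , drop = FALSE], lambdas[1:3],
        tolerance = if (is.null(config$consistency_tolerance)) 0.05
                    else config$consistency_tolerance)
    }
    hemo <- if (length(refl_ch) == 2)
      solve_two_wavelengths(dmuas[[1]], dmuas[[2]], xi,
                            wavelengths_nm = lambdas)
    else solve_multiwavelength(dmuas, xi, wavelengths_nm = lambdas)

    corrected <- NULL
    if (length(fluor_ch) && config$correction_method != "none") {
      stage <- paste0("correction_", config$correction_method)
      fl <- dark_subtract_ratio(stacks[[fluor_ch[1]]], bw)
      corrected <- switch(config$correction_method,
        single = correct_single_wavelength(fl, ratios[[1]]),
        exem = {
          xex <- if (is.null(config$x_est_ex)) 0.56 else config$x_est_ex
          xem <- if (is.null(config$x_est_em)) 0.57 else config$x_est_em
          lam_ex <- centres[fluor_ch[1]]
          lam_em <- if (is.null(config$lambda_em)) lambdas[1] else
            config$lambda_em
          model <- crosstalk_model(
            xex, xem,
            xi_ex = c(xi_at(extinction, lam_ex, "HbO"),
                      xi_at(extinction, lam_ex, "HbR")),
            xi_em = c(xi_at(extinction, lam_em, "HbO"),
                      xi_at(extinction, lam_em, "HbR")))
          correct_ex_em(fl, hemo, model)
        },
        pca = correct_pca_log(fl, reference = hemo))
    }

    unmix_res <- NULL
    if (!is.null(config$unmix_rois)) {
      stage <- "unmix"
      basis <- build_basis(hemo, config$unmix_rois)
      unmix_res <- unmix_nnls(hemo, basis)
    }

    qc <- list(
      channels = as.list(roles), wavelengths_nm = as.list(lambdas),
      baseline_window = config$baseline_window,
      pathlengths_mm = as.list(stats::setNames(
        vapply(lambdas, X_of, 0), names(lambdas))),
      extinction_at_channels = lapply(lambdas, function(l)
        list(xi_hbo = xi_at(extinction, l, "HbO"),
             xi_hbr = xi_at(extinction, l, "HbR"))),
      correction_method = config$correction_method,
      x_est_ex = config$x_est_ex, x_est_em = config$x_est_em,
      seed = config$seed,
      pairwise_consistency = if (is.null(consistency)) "not run" else
        list(discrepancy = consistency$discrepancy,
             tolerance = consistency$tolerance,
             result = if (consistency$pass) "pass" else "fail"))

    list(hemo = hemo, consistency = consistency, corrected = corrected,
         unmix = unmix_res, qc = qc)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (q in c("d_hbo", "d_hbr", "d_hbt"))
      write_movie_tiff(res$hemo[[q]], file.path(out_dir,
                                                paste0(q, ".tif")),
                       format = "float")
    if (!is.null(res$corrected))
      write_movie_tiff(res$corrected$dff,
                       file.path(out_dir, "corrected_dff.tif"),
                       format = "float")
    write_atomic(file.path(out_dir, "qc_report.json"), function(p)
      jsonlite::write_json(res$qc, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null"))
  }
  res
}
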