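#' Build a vascular-compartment basis from seed regions
#'
#' Extracts the mean dHbO, dHbR and dHbT time courses over each seed region
#' and concatenates them (in that fixed block order) into one signature row
#' per compartment. Seed regions are the user-identified vascular
#' compartments (artery, vein, capillary bed, ...) in a trial-averaged
#' haemoglobin movie.
#'
#' @param hemo a [hemo_movie()].
#' @param seed_rois named list; each element is a logical H x W mask or an
#'   n x 2 integer matrix of (row, col) pixel coordinates (1-based).
#' @param blocks haemoglobin blocks to concatenate; default all three.
#'   dHbT is a linear combination of the other two -- kept by default for
#'   fidelity to the concatenated-signature convention, droppable via
#'   `blocks = c("hbo", "hbr")`.
#' @return list of class `compartment_basis`: `basis` (compartments x
#'   (len(blocks) * T)), `names`, `blocks`, `n_time`, `seed_rois`.
#' @export
build_basis <- function(hemo, seed_rois, blocks = c("hbo", "hbr", "hbt")) {
  stopifnot(inherits(hemo, "hemo_movie"))
  blocks <- match.arg(blocks, c("hbo", "hbr", "hbt"), several.ok = TRUE)
  if (is.null(names(seed_rois)) || any(!nzchar(names(seed_rois))))
    stop("seed_rois must be a named list")
  d <- dim(hemo$d_hbo)
  nt <- d[1]
  rows <- lapply(names(seed_rois), function(nm) {
    roi <- seed_rois[[nm]]
    if (is.logical(roi)) {
      if (!identical(dim(roi), d[2:3]))
        stop("ROI '", nm, "' mask does not match the image grid")
      idx <- which(roi)
    } else {
      roi <- as.matrix(roi)
      if (ncol(roi) != 2) stop("ROI '", nm, "' must be an n x 2 matrix")
      if (nrow(roi) == 0) stop("ROI '", nm, "' is empty")
      if (any(roi[, 1] < 1 | roi[, 1] > d[2] | roi[, 2] < 1 |
              roi[, 2] > d[3]))
        stop("ROI '", nm, "' has out-of-bounds pixels")
      idx <- (roi[, 2] - 1) * d[2] + roi[, 1]
    }
    if (length(idx) == 0) stop("ROI '", nm, "' is empty")
    trace_of <- function(a) {
      M <- matrix(a, nrow = nt)
      rowMeans(M[, idx, drop = FALSE], na.rm = TRUE)
    }
    unlist(lapply(blocks, function(b)
      trace_of(hemo[[paste0("d_", b)]])), use.names = FALSE)
  })
  basis <- do.call(rbind, rows)
  if (any(!is.finite(basis))) stop("basis rows must be finite")
  rownames(basis) <- names(seed_rois)
  structure(list(basis = basis, names = names(seed_rois), blocks = blocks,
                 n_time = nt, seed_rois = seed_rois),
            class = "compartment_basis")
}

#' Non-negative spatio-temporal unmixing
#'
#' At every pixel, fits the concatenated (dHbO, dHbR, dHbT) trace as a
#' non-negative linear combination of the compartment signatures:
#' `min || y(r,.) - sum_k P_k(r) B_k(.) ||^2  s.t.  P_k(r) >= 0`
#' (Lawson-Hanson NNLS). Basis rows are not normalised by default, so the
#' coefficient maps read as the "concentration" of each signature in each
#' pixel; `normalize = TRUE` rescales rows to unit norm (and coefficients
#' correspondingly) for display.
#'
#' @param hemo a [hemo_movie()].
#' @param basis a [compartment_basis()] built on the same time axis.
#' @param normalize rescale basis rows to unit Euclidean norm before
#'   fitting.
#' @return list of class `compartment_maps`: `P` (H x W x n_compartments,
#'   >= 0), `residual` (H x W fit residual norm), `names`, `normalize`,
#'   `row_norms`.
#' @export
unmix_nnls <- function(hemo, basis, normalize = FALSE) {
  stopifnot(inherits(hemo, "hemo_movie"),
            inherits(basis, "compartment_basis"))
  d <- dim(hemo$d_hbo)
  nt <- d[1]
  if (basis$n_time != nt)
    stop("basis time length (", basis$n_time,
         ") does not match movie (", nt, ")")
  B <- basis$basis
  row_norms <- sqrt(rowSums(B^2))
  if (normalize) {
    if (any(row_norms == 0)) stop("cannot normalise a zero basis row")
    B <- B / row_norms
  }
  if (nrow(B) > 1 && qr(t(B))$rank < nrow(B))
    warning("basis rows are collinear; coefficients are not unique")
  A <- t(B)                                    # (blocks*T) x K
  Y <- do.call(rbind, lapply(basis$blocks, function(b)
    matrix(hemo[[paste0("d_", b)]], nrow = nt)))  # (blocks*T) x pixels
  npix <- ncol(Y)
  K <- nrow(B)
  P <- matrix(NA_real_, K, npix)
  res <- rep(NA_real_, npix)
  for (p in seq_len(npix)) {
    y <- Y[, p]
    if (any(is.na(y))) next
    fit <- pracma::lsqnonneg(A, y)
    P[, p] <- fit$x
    res[p] <- sqrt(max(fit$resid.norm, 0))  # resid.norm is a squared norm
  }
  Parr <- array(t(P), c(d[2], d[3], K),
                dimnames = list(NULL, NULL, basis$names))
  structure(list(P = Parr, residual = matrix(res, d[2], d[3]),
                 names = basis$names, normalize = normalize,
                 row_norms = row_norms),
            class = "compartment_maps")
}

#' Colour-composite of compartment maps
#'
#' Normalises each coefficient map by its maximum (scaling recorded in the
#' result) and blends them additively into an RGB image with one palette
#' colour per compartment.
#'
#' @param maps a `compartment_maps`.
#' @param palette character vector of colours, at least one per compartment.
#'   Default supports up to five compartments (red, blue, green, magenta,
#'   cyan).
#' @return H x W x 3 RGB array in [0, 1], with attributes `palette` and
#'   `scales` (the per-map maxima used for normalisation).
#' @export
render_merge <- function(maps,
                         palette = c("#FF0000", "#0050FF", "#00C000",
                                     "#FF00FF", "#00C8C8")) {
  stopifnot(inherits(maps, "compartment_maps"))
  K <- dim(maps$P)[3]
  if (K > length(palette))
    stop("palette has ", length(palette), " colours for ", K,
         " compartments")
  d <- dim(maps$P)[1:2]
  rgb_img <- array(0, c(d, 3))
  scales <- numeric(K)
  for (k in seq_len(K)) {
    m <- maps$P[, , k]
    m[is.na(m)] <- 0
    scales[k] <- max(m)
    if (scales[k] > 0) m <- m / scales[k]
    col <- grDevices::col2rgb(palette[k]) / 255
    for (ch in 1:3) rgb_img[, , ch] <- rgb_img[, , ch] + m * col[ch]
  }
  rgb_img[rgb_img > 1] <- 1
  attr(rgb_img, "palette") <- palette[seq_len(K)]
  attr(rgb_img, "scales") <- scales
  rgb_img
}
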