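# Shared fixtures and independent oracles for the suite.

hb_table <- load_extinction()
blood_default <- blood_assumptions()

# Small noise-free phantom shared across tests (regenerated cheaply).
small_scene <- function(...) {
  make_scene(seed = 42, nx = 24, ny = 24, n_time = 60, fs = 10, ...)
}

# Invert a phantom's forward reflectance with the package's own MBLL chain,
# using the phantom's true pathlengths (the matched-model round trip).
invert_phantom <- function(phantom, channels = names(phantom$pathlengths),
                           baseline = 1:10) {
  stacks <- forward_reflectance(phantom, channels)
  dmuas <- lapply(channels, function(ch)
    delta_mua(reflectance_ratio(stacks[[ch]], baseline),
              phantom$pathlengths[[ch]]))
  xi <- xi_matrix(phantom$table, as.list(as.numeric(channels)))
  if (length(channels) == 2)
    solve_two_wavelengths(dmuas[[1]], dmuas[[2]], xi,
                          wavelengths_nm = as.numeric(channels))
  else
    solve_multiwavelength(dmuas, xi, wavelengths_nm = as.numeric(channels))
}

rel_rms <- function(est, truth) {
  sqrt(mean((est - truth)^2, na.rm = TRUE)) /
    sqrt(mean(truth^2, na.rm = TRUE))
}

# Exhaustive non-negative least-squares oracle: try every support set,
# solve the unconstrained LS on it, keep feasible candidates, return the
# one with the smallest residual. Independent of pracma.
nnls_enum <- function(A, b) {
  K <- ncol(A)
  best <- list(x = rep(0, K), res = sum(b^2))
  for (m in seq_len(2^K) - 1) {
    S <- which(bitwAnd(m, 2^(seq_len(K) - 1)) > 0)
    if (length(S) == 0) next
    As <- A[, S, drop = FALSE]
    x_s <- tryCatch(qr.solve(As, b), error = function(e) NULL)
    if (is.null(x_s) || any(x_s < -1e-12)) next
    x <- rep(0, K)
    x[S] <- pmax(x_s, 0)
    res <- sum((b - A %*% x)^2)
    if (res < best$res - 1e-15) best <- list(x = x, res = res)
  }
  best
}

# Independent trapezoid-rule integration (oracle for band integrals).
trapz_oracle <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (y[i] + y[i + 1]) / 2 * (x[i + 1] - x[i])
  s
}
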