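# Independent oracles and small fixture builders used across the suite.

# Receptor-noise-limited chromatic distance as a quadratic form: Mahalanobis
# distance of the log-catch difference in the opponent space orthogonal to
# the intensity direction (1, ..., 1), with receptor noise covariance
# diag(e^2). Independent of the closed-form expressions in the package.
rnl_qform <- function(df, e) {
  Sinv <- diag(1 / e^2, length(e))
  one <- rep(1, length(e))
  M <- Sinv - (Sinv %*% one %*% t(one) %*% Sinv) / as.numeric(t(one) %*% Sinv %*% one)
  sqrt(as.numeric(t(df) %*% M %*% df))
}

# Gaussian bump reflectance on a grid, percent units.
gauss_refl <- function(wl, mu, sd, amp = 50, base = 5) {
  base + amp * exp(-(wl - mu)^2 / (2 * sd^2))
}

# Build a spectra object from named columns on a grid.
make_spectra <- function(wl, ..., meta = NULL) {
  cols <- list(...)
  spectra(wl, do.call(cbind, cols), meta)
}

# Riemann-sum quantum catch on a refined grid (independent of .trapz).
riemann_catch <- function(wl, refl, sens, step = 0.1) {
  grid <- seq(min(wl), max(wl), by = step)
  r <- stats::approx(wl, refl, grid)$y
  s <- stats::approx(wl, sens, grid)$y
  sum(r * s) * step
}

# Strict local maxima by exhaustive neighbor comparison (prominence 0 rule).
naive_maxima <- function(wl, y) {
  idx <- which(vapply(2:(length(y) - 1), function(i)
    y[i] > y[i - 1] && y[i] > y[i + 1], logical(1))) + 1L
  wl[idx]
}
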