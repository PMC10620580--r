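#' Trapezoidal integral on a (possibly irregular) grid
#' @noRd
.trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

#' Quantum catches of spectra under a visual system
#'
#' For each measurement, the catch of receptor i is the trapezoidal integral
#' \deqn{Q_i = \int R(\lambda)\, S_i(\lambda)\, I(\lambda)\, d\lambda}
#' over the shared modelling grid, with `R` the reflectance, `S_i` the
#' receptor sensitivity, and `I` the illuminant (flat, "ideal", by default).
#' The achromatic catch uses the system's achromatic curve. Catches are kept
#' absolute (not sum-normalized): the receptor-noise distances downstream
#' consume log catches, in which overall scale cancels for the chromatic
#' distance. Viewing conditions are ideal throughout (flat illumination and
#' background, homogeneous ocular transmission), so no von Kries step is
#' applied.
#'
#' @param x a `spectra` object on the same grid as the system (non-negative
#'   reflectance; see [offset_nonnegative()]).
#' @param system a `visual_system`.
#' @param illuminant optional numeric irradiance spectrum on the grid
#'   (non-negative); default flat 1.
#' @return an object of class `quantum_catch`: list with `Q` (samples x
#'   receptors matrix), `Q_achro`, their natural logs `f` and `f_achro`,
#'   `sample_id`, and `system` (the system name).
#' @export
quantum_catch <- function(x, system, illuminant = NULL) {
  stopifnot(inherits(x, "spectra"), inherits(system, "visual_system"))
  if (length(x$wl) != length(system$wl) || any(x$wl != system$wl))
    stop("spectra and visual system must share the modelling grid", call. = FALSE)
  if (any(x$refl < 0))
    stop("reflectance must be non-negative; apply offset_nonnegative() first",
         call. = FALSE)
  if (is.null(illuminant)) illuminant <- rep(1, length(x$wl))
  if (length(illuminant) != length(x$wl) || any(illuminant < 0))
    stop("illuminant must be a non-negative spectrum on the grid", call. = FALSE)
  n <- ncol(x$refl)
  S <- system$sensitivities
  Q <- matrix(NA_real_, n, ncol(S),
              dimnames = list(colnames(x$refl), colnames(S)))
  Qa <- numeric(n)
  ach <- system$achromatic$curve
  for (j in seq_len(n)) {
    r <- x$refl[, j] * illuminant
    Q[j, ] <- apply(S, 2, function(s) .trapz(x$wl, r * s))
    Qa[j] <- .trapz(x$wl, r * ach)
  }
  bad <- which(Q <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("degenerate catch: receptor %s of sample '%s' caught no light",
                 colnames(Q)[bad[1, 2]], rownames(Q)[bad[1, 1]]), call. = FALSE)
  if (any(Qa <= 0))
    stop(sprintf("degenerate achromatic catch for sample '%s'",
                 rownames(Q)[which(Qa <= 0)[1]]), call. = FALSE)
  structure(list(sample_id = colnames(x$refl), system = system$name,
                 Q = Q, f = log(Q), Q_achro = Qa, f_achro = log(Qa),
                 meta = x$meta),
            class = "quantum_catch")
}

#' @export
print.quantum_catch <- function(x, ...) {
  cat(sprintf("Quantum catches: %d sample(s) under system '%s'\n",
              nrow(x$Q), x$system))
  print(utils::head(x$Q, 4))
  if (nrow(x$Q) > 4) cat("...\n")
  invisible(x)
}
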