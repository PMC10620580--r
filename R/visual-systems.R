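#' A1 visual-pigment spectral sensitivity template
#'
#' Reconstructs a full photoreceptor sensitivity curve from its wavelength of
#' peak absorbance alone, using the standard A1 (Govardovskii-type) nomogram:
#' an alpha band
#' \deqn{S(x) = 1 / (e^{69.7(a-x)} + e^{28(0.922-x)} + e^{-14.9(1.104-x)} + 0.674)}
#' with \eqn{x = \lambda_{max}/\lambda} and
#' \eqn{a = 0.8795 + 0.0459 e^{-(\lambda_{max}-300)^2/11940}}, plus a beta
#' band \eqn{0.26\, e^{-((\lambda - (189 + 0.315\lambda_{max}))/(-40.5 + 0.195\lambda_{max}))^2}},
#' summed and peak-normalized to 1.
#'
#' @param lambda_max wavelength of peak sensitivity in nm, within 300--700.
#' @param wl wavelength grid in nm (regular).
#' @return numeric vector of sensitivities in `[0, 1]` on `wl`, maximum 1 at
#'   the grid point nearest `lambda_max`.
#' @export
a1_template <- function(lambda_max, wl = 300:700) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 ||
      lambda_max < 300 || lambda_max > 700)
    stop("lambda_max must be a single value in [300, 700] nm", call. = FALSE)
  x <- lambda_max / wl
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  # The beta-band parametrization is fitted on pigments with lambda_max well
  # above its own centre (189 + 0.315 lambda_max); for UV/violet pigments
  # below 400 nm that centre collides with the alpha peak and would displace
  # it, so the beta-band is added only for lambda_max >= 400 nm.
  if (lambda_max >= 400) {
    lm_beta <- 189 + 0.315 * lambda_max
    b_beta <- -40.5 + 0.195 * lambda_max
    beta <- 0.26 * exp(-((wl - lm_beta) / b_beta)^2)
  } else {
    beta <- 0
  }
  s <- alpha + beta
  s / max(s)
}

#' Construct a visual system
#'
#' A visual system bundles an ordered receptor set (shortest to longest
#' lambda-max), their sensitivity curves on the modelling grid, relative
#' receptor densities, the Weber fraction of the reference (longest
#' lambda-max) receptor, and an achromatic-channel definition.
#'
#' @param name system name.
#' @param lambda_max named or unnamed numeric vector of receptor peak
#'   wavelengths in nm; sorted ascending internally.
#' @param wl modelling wavelength grid.
#' @param densities relative receptor abundances, positive, recycled to the
#'   receptor count; default all 1.
#' @param weber Weber fraction of the reference receptor, in (0, 1);
#'   default 0.1.
#' @param achromatic achromatic channel: `"summed_all"` (pointwise sum of all
#'   receptor curves), `list(type = "double_cone", lambda = <nm>)`,
#'   `list(type = "template", lambda = <nm>)`, or a numeric curve on `wl`.
#' @param sensitivities optional matrix of measured sensitivity curves
#'   (`length(wl)` rows, one column per receptor in `lambda_max` order);
#'   when absent, curves are generated with [a1_template()].
#' @return an object of class `visual_system`.
#' @export
visual_system <- function(name, lambda_max, wl = 300:700, densities = 1,
                          weber = 0.1, achromatic = "summed_all",
                          sensitivities = NULL) {
  lambda_max <- sort(as.numeric(lambda_max))
  n <- length(lambda_max)
  if (n < 2 || n > 4)
    stop("2 to 4 receptors supported", call. = FALSE)
  densities <- rep_len(as.numeric(densities), n)
  if (any(densities <= 0)) stop("densities must be positive", call. = FALSE)
  if (!is.numeric(weber) || weber <= 0 || weber >= 1)
    stop("weber fraction must lie in (0, 1)", call. = FALSE)
  if (is.null(sensitivities)) {
    S <- vapply(lambda_max, a1_template, numeric(length(wl)), wl = wl)
  } else {
    S <- as.matrix(sensitivities)
    if (nrow(S) != length(wl) || ncol(S) != n)
      stop("sensitivities must be length(wl) x n_receptors", call. = FALSE)
  }
  rnames <- .receptor_names(lambda_max)
  colnames(S) <- rnames
  names(lambda_max) <- names(densities) <- rnames
  if (is.character(achromatic) && length(achromatic) == 1)
    achromatic <- list(type = achromatic)
  if (is.numeric(achromatic)) {
    if (length(achromatic) != length(wl))
      stop("achromatic curve must match the grid", call. = FALSE)
    achromatic <- list(type = "curve", curve = achromatic / max(achromatic))
  }
  obj <- structure(list(name = name, lambda_max = lambda_max, wl = wl,
                        sensitivities = S, densities = densities,
                        weber = weber, achromatic = achromatic,
                        chromatic_dim = n),
                   class = "visual_system")
  obj$achromatic$curve <- achromatic_channel(obj)
  obj
}

.receptor_names <- function(lm) {
  n <- length(lm)
  base <- if (n == 4) {
    if (lm[1] < 400) c("UVS", "SWS", "MWS", "LWS") else c("VS", "SWS", "MWS", "LWS")
  } else if (n == 3) {
    if (lm[1] < 400) c("UVS", "MWS", "LWS") else c("SWS", "MWS", "LWS")
  } else c("SWS", "LWS")
  base
}

#' Achromatic sensitivity curve of a visual system
#'
#' `summed_all`: pointwise sum of all receptor curves, peak-normalized.
#' `double_cone` / `template`: an A1 template at the stated lambda-max (the
#' double-cone member pigment for birds, the R1-6 rhodopsin proxy for flies).
#' `curve`: a user-supplied measured curve.
#'
#' @param system a `visual_system`.
#' @return numeric sensitivity curve on the system grid, maximum 1.
#' @export
achromatic_channel <- function(system) {
  stopifnot(inherits(system, "visual_system"))
  ac <- system$achromatic
  switch(ac$type,
    summed_all = {
      s <- rowSums(system$sensitivities)
      s / max(s)
    },
    double_cone = ,
    template = a1_template(ac$lambda, system$wl),
    curve = ac$curve,
    stop("unknown achromatic channel type: ", ac$type, call. = FALSE))
}

#' The six built-in predator visual systems
#'
#' Visual systems for the six predator (or predator-proxy) species used in
#' the discrimination analysis, each built from published receptor peak
#' wavelengths:
#' \itemize{
#'   \item `lizard` (\emph{Ctenophorus ornatus}, trichromat): 440, 493, 571 nm
#'   \item `spider` (jumping spider \emph{Habronattus pyrrithrix}, trichromat):
#'     377, 530, 626 nm
#'   \item `bee` (honey bee \emph{Apis mellifera}, trichromat; a proxy for
#'     grasshopper vision): 344, 436, 544 nm
#'   \item `fly` (housefly \emph{Musca domestica}, tetrachromat):
#'     360, 420, 490, 520 nm
#'   \item `starling` (\emph{Sturnus vulgaris}, tetrachromat):
#'     362, 449, 504, 563 nm
#'   \item `peafowl` (\emph{Pavo cristatus}, tetrachromat):
#'     432, 477, 537, 605 nm
#' }
#' Achromatic channels: the double-cone model for starling (563 nm) and
#' peafowl (605 nm, chicken double-cone proxy), the R1-6 photoreceptor model
#' for the fly (490 nm template), and the summed response of all receptors
#' for lizard, spider and bee. Densities default to 1 and the Weber fraction
#' to 0.1 on the longest-wavelength receptor; both are declared proxies and
#' can be overridden.
#'
#' @param wl modelling wavelength grid, 300--700 nm at 1 nm by default.
#' @param densities,weber optional named lists overriding the per-system
#'   defaults, e.g. `weber = list(bee = 0.13)`.
#' @return named list of six `visual_system` objects.
#' @export
builtin_systems <- function(wl = 300:700, densities = list(), weber = list()) {
  defs <- list(
    lizard   = list(lm = c(440, 493, 571), ach = list(type = "summed_all")),
    spider   = list(lm = c(377, 530, 626), ach = list(type = "summed_all")),
    bee      = list(lm = c(344, 436, 544), ach = list(type = "summed_all")),
    fly      = list(lm = c(360, 420, 490, 520),
                    ach = list(type = "template", lambda = 490)),
    starling = list(lm = c(362, 449, 504, 563),
                    ach = list(type = "double_cone", lambda = 563)),
    peafowl  = list(lm = c(432, 477, 537, 605),
                    ach = list(type = "double_cone", lambda = 605))
  )
  out <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    visual_system(nm, d$lm, wl = wl,
                  densities = if (nm %in% names(densities)) densities[[nm]] else 1,
                  weber = if (nm %in% names(weber)) weber[[nm]] else 0.1,
                  achromatic = d$ach)
  })
  names(out) <- names(defs)
  out
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("Visual system '%s' (%d receptors)\n", x$name, x$chromatic_dim))
  cat("  lambda_max:", paste(sprintf("%s=%g", names(x$lambda_max), x$lambda_max),
                             collapse = ", "), "nm\n")
  cat(sprintf("  densities: %s; Weber fraction: %g; achromatic: %s\n",
              paste(x$densities, collapse = ", "), x$weber, x$achromatic$type))
  invisible(x)
}
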