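#' Receptor noise vector of a visual system
#'
#' Intensity-independent ("neural") noise: with the reference receptor r
#' taken as the longest lambda-max class, the noise-to-signal ratio of
#' receptor i is \deqn{e_i = \nu \sqrt{\eta_r / \eta_i}} where \eqn{\nu} is
#' the Weber fraction of the reference receptor and \eqn{\eta_i} the relative
#' receptor densities. The achromatic channel noise defaults to \eqn{\nu}.
#'
#' @param system a `visual_system`.
#' @param e_achro achromatic-channel noise; default the system Weber fraction.
#' @return list with `e` (per-receptor noise, receptor order) and `e_achro`.
#' @export
noise_vector <- function(system, e_achro = NULL) {
  stopifnot(inherits(system, "visual_system"))
  eta <- system$densities
  if (any(eta <= 0)) stop("densities must be positive", call. = FALSE)
  r <- which.max(system$lambda_max)
  e <- system$weber * sqrt(eta[r] / eta)
  list(e = e, e_achro = if (is.null(e_achro)) system$weber else e_achro)
}

#' Chromatic distance under the receptor-noise-limited model
#'
#' Noise-weighted opponent distance between two stimuli given their log
#' quantum catches, in just-noticeable-difference (JND) units. With
#' \eqn{\Delta f_i = f_i(A) - f_i(B)}:
#' \itemize{
#'   \item dichromat: \eqn{\Delta S = |\Delta f_1 - \Delta f_2| / \sqrt{e_1^2 + e_2^2}}
#'   \item trichromat: \eqn{\Delta S^2 = [e_1^2(\Delta f_3-\Delta f_2)^2 +
#'     e_2^2(\Delta f_3-\Delta f_1)^2 + e_3^2(\Delta f_2-\Delta f_1)^2] /
#'     [(e_1 e_2)^2 + (e_1 e_3)^2 + (e_2 e_3)^2]}
#'   \item tetrachromat: the analogous ratio with all six pairwise
#'     \eqn{\Delta f} differences weighted by the complementary noise
#'     products.
#' }
#'
#' @param fA,fB numeric log-catch vectors of equal length 2--4, receptor
#'   order shortest to longest lambda-max.
#' @param e positive noise vector of the same length (see [noise_vector()]).
#' @return non-negative chromatic distance in JND.
#' @export
chromatic_distance <- function(fA, fB, e) {
  n <- length(fA)
  if (length(fB) != n || length(e) != n)
    stop("fA, fB and e must have equal length", call. = FALSE)
  if (any(e <= 0)) stop("noise values must be positive", call. = FALSE)
  df <- fA - fB
  if (n == 2) {
    abs(df[1] - df[2]) / sqrt(e[1]^2 + e[2]^2)
  } else if (n == 3) {
    num <- e[1]^2 * (df[3] - df[2])^2 +
           e[2]^2 * (df[3] - df[1])^2 +
           e[3]^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
    sqrt(num / den)
  } else if (n == 4) {
    num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
           (e[1] * e[3])^2 * (df[4] - df[2])^2 +
           (e[1] * e[4])^2 * (df[3] - df[2])^2 +
           (e[2] * e[3])^2 * (df[4] - df[1])^2 +
           (e[2] * e[4])^2 * (df[3] - df[1])^2 +
           (e[3] * e[4])^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
           (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
    sqrt(num / den)
  } else {
    stop("2 to 4 receptors supported", call. = FALSE)
  }
}

#' Achromatic distance under the receptor-noise-limited model
#'
#' \eqn{\Delta L = |f_{achro}(A) - f_{achro}(B)| / e_{achro}} in JND units.
#'
#' @param fA,fB log achromatic catches.
#' @param e_achro positive achromatic noise.
#' @return non-negative achromatic distance in JND.
#' @export
achromatic_distance <- function(fA, fB, e_achro) {
  if (e_achro <= 0) stop("e_achro must be positive", call. = FALSE)
  abs(fA - fB) / e_achro
}

#' All pairwise chromatic and achromatic distances
#'
#' Evaluates the receptor-noise-limited distances for every unordered pair of
#' samples in a quantum-catch set.
#'
#' @param catches a `quantum_catch` object.
#' @param system the `visual_system` the catches were computed under.
#' @param e_achro optional achromatic noise override.
#' @return data frame of class `color_distance` with columns `sample_a`,
#'   `sample_b`, `system`, `dS`, `dL` (JND units).
#' @export
pairwise_distances <- function(catches, system, e_achro = NULL) {
  stopifnot(inherits(catches, "quantum_catch"),
            inherits(system, "visual_system"))
  if (catches$system != system$name)
    stop("catches were computed under system '", catches$system,
         "', not '", system$name, "'", call. = FALSE)
  nv <- noise_vector(system, e_achro)
  ids <- catches$sample_id
  n <- length(ids)
  pairs <- if (n >= 2) utils::combn(n, 2) else matrix(integer(0), 2, 0)
  dS <- dL <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    dS[k] <- chromatic_distance(catches$f[i, ], catches$f[j, ], nv$e)
    dL[k] <- achromatic_distance(catches$f_achro[i], catches$f_achro[j],
                                 nv$e_achro)
  }
  out <- data.frame(sample_a = ids[pairs[1, ]], sample_b = ids[pairs[2, ]],
                    system = system$name, dS = dS, dL = dL,
                    stringsAsFactors = FALSE)
  class(out) <- c("color_distance", "data.frame")
  out
}
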