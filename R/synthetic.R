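#' Configuration for the synthetic reflectance generator
#'
#' Defaults emulate the measured study design: a club-legged-grasshopper-like
#' block (`sibiricus`: 22 green, 12 brown and 4 pied individuals, patchier
#' and therefore lower-contrast and more variable) and a
#' steppe-grasshopper-like block (`dorsatus`: 12 uniform brown, 14
#' dorsal-green and 8 lateral-green individuals, cleaner patterning), each
#' measured on 2 patches (dorsal, lateral) with 5 replicates. Green patches
#' carry reflectance peaks at 520 and 580 nm and depressed violet--blue
#' reflectance; brown patches a single 590 nm peak, an elevated baseline and
#' a violet--blue shoulder. Peak positions are study facts; amplitudes and
#' the per-species contrast/variability settings are generator conventions,
#' calibrated once so the qualitative discriminability pattern of the study
#' emerges, then frozen.
#'
#' @param baseline flat baseline reflectance, percent.
#' @param green_peaks,green_amps,green_width green-profile peak centers (nm),
#'   amplitudes (percent, at contrast 1) and Gaussian SD (nm).
#' @param brown_peak,brown_amp,brown_width brown-profile 590 nm peak.
#' @param brown_elevation flat brown baseline elevation, percent.
#' @param shoulder_amp,shoulder_center,shoulder_width brown violet--blue
#'   shoulder (logistic step), percent / nm / nm.
#' @param noise_sd additive measurement noise SD per wavelength, percent.
#' @param species named list of per-species blocks, each with `n` (named
#'   vector of individuals per morph), `contrast` (morph-contrast scaling in
#'   (0, 1]) and `indiv_cv` (SD of the per-individual log-normal amplitude
#'   multiplier).
#' @param n_replicates measurements per patch per individual.
#' @param wl modelling grid.
#' @param seed default RNG seed for [gen_morph_spectra()].
#' @return a list of class `spectra_gen_config`.
#' @export
spectra_gen_config <- function(baseline = 6,
                               green_peaks = c(520, 580),
                               green_amps = c(14, 12),
                               green_width = 18,
                               brown_peak = 590, brown_amp = 18,
                               brown_width = 25,
                               brown_elevation = 6,
                               shoulder_amp = 8, shoulder_center = 470,
                               shoulder_width = 30,
                               noise_sd = 1,
                               species = list(
                                 sibiricus = list(
                                   n = c(green = 22, brown = 12, pied = 4),
                                   contrast = 0.18, indiv_cv = 0.25),
                                 dorsatus = list(
                                   n = c(brown = 12, dorsal_green = 14,
                                         lateral_green = 8),
                                   contrast = 0.70, indiv_cv = 0.12)),
                               n_replicates = 5,
                               wl = 300:700, seed = 1L) {
  stopifnot(green_width > 0, brown_width > 0, shoulder_width > 0,
            all(green_amps >= 0), brown_amp >= 0, shoulder_amp >= 0,
            noise_sd >= 0, n_replicates >= 1)
  structure(as.list(environment()), class = "spectra_gen_config")
}

.gauss <- function(wl, mu, sd) exp(-(wl - mu)^2 / (2 * sd^2))

#' Noise-free morph reflectance profiles
#'
#' @param cfg a `spectra_gen_config`.
#' @param contrast morph-contrast scaling applied to the profile deviations.
#' @return matrix with columns `green` and `brown` on `cfg$wl`.
#' @export
morph_profiles <- function(cfg = spectra_gen_config(), contrast = 1) {
  wl <- cfg$wl
  green_dev <- cfg$green_amps[1] * .gauss(wl, cfg$green_peaks[1], cfg$green_width) +
               cfg$green_amps[2] * .gauss(wl, cfg$green_peaks[2], cfg$green_width)
  brown_dev <- cfg$brown_elevation +
               cfg$brown_amp * .gauss(wl, cfg$brown_peak, cfg$brown_width) +
               cfg$shoulder_amp /
                 (1 + exp((wl - cfg$shoulder_center) / cfg$shoulder_width))
  cbind(green = cfg$baseline + contrast * green_dev,
        brown = cfg$baseline + contrast * brown_dev)
}

.patch_profile <- function(morph, patch) {
  switch(morph,
         green = , uniform_green = "green",
         brown = , pied = , uniform_brown = "brown",
         dorsal_green = if (patch == "dorsal") "green" else "brown",
         lateral_green = if (patch == "lateral") "green" else "brown",
         stop("unknown morph: ", morph, call. = FALSE))
}

#' Generate a synthetic reflectance spectra collection
#'
#' Draws the full replicated design from the configuration: per individual,
#' a log-normal amplitude multiplier on the morph-profile deviation; per
#' replicate, i.i.d. Gaussian measurement noise per wavelength. Bicolor
#' morphs (`dorsal_green`, `lateral_green`) receive the green profile on the
#' name-giving patch and the brown profile on the other. Deterministic under
#' `seed`.
#'
#' @param cfg a `spectra_gen_config`.
#' @param seed RNG seed; defaults to the config's.
#' @return a `spectra` object with full metadata.
#' @export
gen_morph_spectra <- function(cfg = spectra_gen_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "spectra_gen_config"))
  if (!length(cfg$species) || any(vapply(cfg$species, function(s) sum(s$n), 0) == 0))
    stop("each species block needs at least one individual", call. = FALSE)
  set.seed(seed)
  wl <- cfg$wl
  cols <- list(); meta <- list()
  for (sp in names(cfg$species)) {
    blk <- cfg$species[[sp]]
    prof <- morph_profiles(cfg, contrast = 1)
    ind_no <- 0L
    for (morph in names(blk$n)) {
      for (i in seq_len(blk$n[[morph]])) {
        ind_no <- ind_no + 1L
        ind_id <- sprintf("%s_%02d", substr(sp, 1, 3), ind_no)
        m <- exp(stats::rnorm(1, 0, blk$indiv_cv))
        for (patch in c("dorsal", "lateral")) {
          shape <- prof[, .patch_profile(morph, patch)]
          mu <- cfg$baseline + blk$contrast * m * (shape - cfg$baseline)
          for (rep in seq_len(cfg$n_replicates)) {
            y <- mu + stats::rnorm(length(wl), 0, cfg$noise_sd)
            id <- sprintf("%s_%s_r%d", ind_id, patch, rep)
            cols[[id]] <- y
            meta[[id]] <- data.frame(sample_id = id, species = sp,
                                     individual = ind_id, morph = morph,
                                     patch = patch, replicate = rep,
                                     stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  refl <- do.call(cbind, cols)
  colnames(refl) <- names(cols)
  spectra(wl, refl, do.call(rbind, meta))
}

#' Configuration for the synthetic RGB ontogeny generator
#'
#' Emulates the developmental chromaticity pattern: morph clouds coincident
#' at the first nymphal stage, partially separated at N2, clearly separated
#' from N3 onward, and a blue shift in imagoes. Centroids are given in
#' (r, g) ternary coordinates; the morph offsets are scaled by a per-stage
#' expression fraction (0 at N1, 0.5 at N2, 1 from N3).
#'
#' @param base_rg shared (r, g) centroid before morph expression.
#' @param green_offset,brown_offset full-expression (r, g) morph offsets.
#' @param stage_fraction named per-stage expression fractions.
#' @param blue_shift reduction applied to both r and g at the imago stage
#'   (mass moved to b).
#' @param sd within-group SD per ternary axis.
#' @param n_per individuals per morph per stage.
#' @param brightness_range range of total R+G+B drawn per measurement.
#' @param species species label stored in the output.
#' @param seed default RNG seed.
#' @return a list of class `rgb_gen_config`.
#' @export
rgb_gen_config <- function(base_rg = c(0.38, 0.34),
                           green_offset = c(-0.025, 0.045),
                           brown_offset = c(0.025, -0.015),
                           stage_fraction = c(N1 = 0, N2 = 0.5, N3 = 1,
                                              N4 = 1, imago = 1),
                           blue_shift = 0.02,
                           sd = 0.02, n_per = 10,
                           brightness_range = c(300, 480),
                           species = "sibiricus", seed = 1L) {
  stopifnot(sd > 0, n_per >= 1, all(stage_fraction >= 0))
  cen <- rbind(base_rg + green_offset, base_rg + brown_offset)
  if (any(cen < 0) || any(rowSums(cen) > 1))
    stop("morph centroids must stay on the simplex", call. = FALSE)
  structure(as.list(environment())[
    c("base_rg", "green_offset", "brown_offset", "stage_fraction",
      "blue_shift", "sd", "n_per", "brightness_range", "species", "seed")],
    class = "rgb_gen_config")
}

#' Generate a synthetic RGB ontogeny dataset
#'
#' One head-patch RGB measurement per individual per stage for a green and a
#' brown morph cohort, following the configured centroid trajectory.
#' Deterministic under `seed`.
#'
#' @param cfg an `rgb_gen_config`.
#' @param seed RNG seed; defaults to the config's.
#' @return an RGB measurement data frame (see [read_rgb()]).
#' @export
gen_rgb_ontogeny <- function(cfg = rgb_gen_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "rgb_gen_config"))
  set.seed(seed)
  rows <- list()
  stages <- names(cfg$stage_fraction)
  for (morph in c("green", "brown")) {
    off <- if (morph == "green") cfg$green_offset else cfg$brown_offset
    for (i in seq_len(cfg$n_per)) {
      ind <- sprintf("%s_%s_%02d", substr(cfg$species, 1, 3), morph, i)
      for (st in stages) {
        cen <- cfg$base_rg + cfg$stage_fraction[[st]] * off
        if (st == "imago") cen <- cen - cfg$blue_shift
        rg <- cen + stats::rnorm(2, 0, cfg$sd)
        rg <- pmin(pmax(rg, 0.01), 0.98)
        if (sum(rg) > 0.98) rg <- rg / sum(rg) * 0.98
        tern <- c(rg, 1 - sum(rg))
        tot <- stats::runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
        rows[[length(rows) + 1L]] <-
          data.frame(individual = ind, species = cfg$species, stage = st,
                     morph = morph, patch = "head",
                     R = tern[1] * tot, G = tern[2] * tot, B = tern[3] * tot,
                     stringsAsFactors = FALSE)
      }
    }
  }
  validate_rgb(do.call(rbind, rows))
}
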