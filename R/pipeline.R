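#' Default run configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed used by every stochastic stage.
#' @param spectra_path,metadata_path input spectra/metadata CSVs; when `NULL`
#'   synthetic spectra are generated.
#' @param rgb_path input RGB CSV; when `NULL` a synthetic ontogeny dataset is
#'   generated.
#' @param systems character vector of visual-system names (subset of the six
#'   built-in).
#' @param method group aggregation, `"pairwise_mean"` or `"centroid"`.
#' @param threshold discriminability cut in JND.
#' @param range,step modelling range (nm) and grid step (nm).
#' @param smooth_span loess span, or `NULL` to skip smoothing (the default).
#' @param artifact_window,artifact_flanks instrument-artifact repair
#'   settings, see [repair_artifact_window()].
#' @param divergence_threshold cut for [divergence_stage()].
#' @return a list of class `run_config`.
#' @export
run_config <- function(out_dir = "morphvision_out", seed = 1L,
                       spectra_path = NULL, metadata_path = NULL,
                       rgb_path = NULL,
                       systems = c("lizard", "spider", "bee", "fly",
                                   "starling", "peafowl"),
                       method = "pairwise_mean", threshold = 3,
                       range = c(300, 700), step = 1,
                       smooth_span = NULL,
                       artifact_window = c(653.5, 660.5),
                       artifact_flanks = list(c(650, 653), c(661, 664)),
                       divergence_threshold = 2) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in [run_config()].
#' @return a validated `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(vals$artifact_flanks))
    vals$artifact_flanks <- lapply(vals$artifact_flanks, as.numeric)
  do.call(run_config, vals)
}

.validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  unknown <- setdiff(cfg$systems,
                     c("lizard", "spider", "bee", "fly", "starling", "peafowl"))
  if (length(unknown))
    stop("unknown visual system(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!cfg$method %in% c("pairwise_mean", "centroid"))
    stop("method must be pairwise_mean or centroid", call. = FALSE)
  if (!is.null(cfg$spectra_path) && !file.exists(cfg$spectra_path))
    stop("spectra file not found: ", cfg$spectra_path, call. = FALSE)
  if (!is.null(cfg$rgb_path) && !file.exists(cfg$rgb_path))
    stop("RGB file not found: ", cfg$rgb_path, call. = FALSE)
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/read -> preprocess (artifact repair, replicate
#' averaging, optional smoothing, clip, 1-nm interpolation, non-negativity
#' offset) -> quantum catches -> pairwise distances -> group comparison
#' table, plus the RGB ontogeny stage. Writes `distances.csv`,
#' `comparisons.csv`, `ternary.csv`, `summary.json` and `run.log` to the
#' output directory. Deterministic given the configured seed.
#'
#' @param cfg a `run_config` (or path to a YAML config file).
#' @return invisibly, a list with the comparison table, the divergence-stage
#'   result and the output paths.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  .validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  log_lines <- c(sprintf("morphvision %s",
                         as.character(utils::packageVersion("morphvision"))),
                 paste0("config: ", jsonlite::toJSON(unclass(cfg),
                                                     auto_unbox = TRUE,
                                                     null = "null")))
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # -- spectra stage ---------------------------------------------------
  if (is.null(cfg$spectra_path)) {
    say("stage simulate-spectra: synthetic defaults, seed %d", cfg$seed)
    sp <- gen_morph_spectra(spectra_gen_config(seed = cfg$seed))
  } else {
    say("stage read-spectra: %s", cfg$spectra_path)
    sp <- read_spectra(cfg$spectra_path, cfg$metadata_path)
  }
  sp <- repair_artifact_window(sp, cfg$artifact_window, cfg$artifact_flanks)
  sp <- average_replicates(sp, by = c("species", "individual", "patch"))
  if (!is.null(cfg$smooth_span)) sp <- smooth_spectra(sp, cfg$smooth_span)
  say("stage preprocess: %d averaged spectra", n_spectra(sp))

  systems <- builtin_systems(wl = seq(cfg$range[1], cfg$range[2],
                                      by = cfg$step))[cfg$systems]
  spm <- offset_nonnegative(
    interpolate_to_grid(clip_range(sp, cfg$range[1], cfg$range[2]),
                        step = cfg$step, range = cfg$range))

  dist_rows <- list()
  for (sys in systems) {
    for (spc in unique(spm$meta$species)) {
      qc <- quantum_catch(filter_spectra(spm, species = spc), sys)
      dist_rows[[paste(sys$name, spc)]] <- pairwise_distances(qc, sys)
    }
  }
  distances <- do.call(rbind, dist_rows)
  rownames(distances) <- NULL
  dist_path <- file.path(cfg$out_dir, "distances.csv")
  utils::write.csv(distances, dist_path, row.names = FALSE)
  say("stage distances: %d pairs x %d systems", nrow(distances),
      length(systems))

  fit <- morph_discrimination(spm, systems = systems,
                              method = cfg$method, threshold = cfg$threshold,
                              range = cfg$range, step = cfg$step)
  comp_path <- file.path(cfg$out_dir, "comparisons.csv")
  render_report(fit$comparisons, comp_path, "csv", cfg$threshold)
  say("stage comparisons: %d rows", nrow(fit$comparisons))

  # -- RGB ontogeny stage ----------------------------------------------
  if (is.null(cfg$rgb_path)) {
    say("stage simulate-rgb: synthetic defaults, seed %d", cfg$seed)
    rgb <- gen_rgb_ontogeny(rgb_gen_config(seed = cfg$seed))
  } else {
    say("stage read-rgb: %s", cfg$rgb_path)
    rgb <- read_rgb(cfg$rgb_path)
  }
  tern_path <- file.path(cfg$out_dir, "ternary.csv")
  write_ternary(rgb, tern_path)
  div <- divergence_stage(rgb, threshold = cfg$divergence_threshold)
  say("stage ontogeny: divergence at stage %s", div$stage)

  summary_path <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(
    list(config = unclass(cfg),
         n_spectra = n_spectra(spm),
         comparisons = fit$comparisons,
         divergence_stage = div$stage,
         stage_separation = as.list(div$separation)),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, logf)
  invisible(list(comparisons = fit$comparisons, divergence = div,
                 paths = c(distances = dist_path, comparisons = comp_path,
                           ternary = tern_path, summary = summary_path,
                           log = logf)))
}
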