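#' Pool pied spectra with brown
#'
#' Pied individuals lack green coloration and are treated as brown sensu lato
#' in all group comparisons.
#'
#' @param x a `spectra` object.
#' @return `x` with metadata morph `"pied"` relabelled `"brown"`.
#' @export
pool_pied <- function(x) {
  stopifnot(inherits(x, "spectra"))
  x$meta$morph[x$meta$morph == "pied"] <- "brown"
  x
}

.select_group <- function(x, filter) {
  keep <- rep(TRUE, nrow(x$meta))
  for (f in names(filter)) {
    if (!f %in% names(x$meta))
      stop("unknown metadata field in group filter: ", f, call. = FALSE)
    keep <- keep & x$meta[[f]] %in% filter[[f]]
  }
  which(keep)
}

.cross_group_stats <- function(catches, ia, ib, system, e_achro = NULL) {
  nv <- noise_vector(system, e_achro)
  dS <- dL <- numeric(length(ia) * length(ib))
  k <- 0L
  for (i in ia) for (j in ib) {
    k <- k + 1L
    dS[k] <- chromatic_distance(catches$f[i, ], catches$f[j, ], nv$e)
    dL[k] <- achromatic_distance(catches$f_achro[i], catches$f_achro[j],
                                 nv$e_achro)
  }
  list(dS_mean = mean(dS), dL_mean = mean(dL), n_pairs = k)
}

#' Compare two morph/patch groups under one visual system
#'
#' Computes group-level chromatic and achromatic distances between two sets
#' of spectra selected by metadata filters, with a discriminability call: the
#' groups are deemed discriminable when both mean Delta S and mean Delta L
#' strictly exceed the threshold (3 JND by default, a conservative cut).
#'
#' @param x a `spectra` object on the system's modelling grid, non-negative.
#' @param group_a,group_b named lists of metadata filters (e.g.
#'   `list(morph = "green", patch = "dorsal")`); each must select at least
#'   one spectrum and the two selections must be disjoint.
#' @param system a `visual_system`.
#' @param method `"pairwise_mean"` (mean Delta S / Delta L over all
#'   between-group pairs; default) or `"centroid"` (distances between the
#'   pointwise-mean spectra of the two groups).
#' @param threshold discriminability cut in JND, strict inequality.
#' @param label optional row label.
#' @param illuminant optional illuminant passed to [quantum_catch()].
#' @return one-row data frame: `label`, `system`, `dS_mean`, `dL_mean`,
#'   `n_pairs`, `discriminable`.
#' @export
compare_groups <- function(x, group_a, group_b, system,
                           method = c("pairwise_mean", "centroid"),
                           threshold = 3, label = NULL, illuminant = NULL) {
  stopifnot(inherits(x, "spectra"), inherits(system, "visual_system"))
  method <- match.arg(method)
  ia <- .select_group(x, group_a)
  ib <- .select_group(x, group_b)
  if (!length(ia) || !length(ib))
    stop("empty group selection", call. = FALSE)
  if (length(intersect(ia, ib)))
    stop("group selections overlap", call. = FALSE)
  if (method == "centroid") {
    cen <- cbind(a = rowMeans(x$refl[, ia, drop = FALSE]),
                 b = rowMeans(x$refl[, ib, drop = FALSE]))
    qc <- quantum_catch(spectra(x$wl, cen), system, illuminant)
    st <- .cross_group_stats(qc, 1L, 2L, system)
    st$n_pairs <- 1L
  } else {
    qc <- quantum_catch(
      spectra(x$wl, x$refl[, c(ia, ib), drop = FALSE],
              x$meta[c(ia, ib), , drop = FALSE]),
      system, illuminant)
    st <- .cross_group_stats(qc, seq_along(ia),
                             length(ia) + seq_along(ib), system)
  }
  data.frame(label = if (is.null(label)) "group_a vs group_b" else label,
             system = system$name,
             dS_mean = st$dS_mean, dL_mean = st$dL_mean,
             n_pairs = st$n_pairs,
             discriminable = st$dS_mean > threshold & st$dL_mean > threshold,
             stringsAsFactors = FALSE)
}

#' Default group-comparison plans
#'
#' The comparison rows evaluated for each species. For the club-legged
#' grasshopper design (`"sibiricus"`) there are four rows: green vs brown
#' morphs in dorsal and in lateral view, and the lateral-vs-dorsal contrast
#' within each morph. For the steppe grasshopper design (`"dorsatus"`),
#' with its uniform brown and two bicolor morphs, there are ten rows covering
#' every brown-vs-green, brown-vs-brown and green-vs-green patch contrast.
#'
#' @param species `"sibiricus"`, `"dorsatus"`, or both.
#' @return data frame with columns `species`, `label`, `morph_a`, `patch_a`,
#'   `morph_b`, `patch_b`.
#' @export
default_plan <- function(species = c("sibiricus", "dorsatus")) {
  species <- match.arg(species, several.ok = TRUE)
  sib <- data.frame(
    species = "sibiricus",
    label = c("Green vs. brown morphs (dorsal view)",
              "Green vs. brown morphs (lateral view)",
              "Brown morphs (lateral vs. dorsal side)",
              "Green morphs (lateral vs. dorsal side)"),
    morph_a = c("green", "green", "brown", "green"),
    patch_a = c("dorsal", "lateral", "lateral", "lateral"),
    morph_b = c("brown", "brown", "brown", "green"),
    patch_b = c("dorsal", "lateral", "dorsal", "dorsal"),
    stringsAsFactors = FALSE)
  dor <- data.frame(
    species = "dorsatus",
    label = c("Brown vs. dorsal green morphs (dorsal view)",
              "Brown vs. lateral green morphs (lateral view)",
              "Lateral green vs. dorsal green morphs (dorsal view)",
              "Lateral green vs. dorsal green morphs (lateral view)",
              "Lateral green morphs (lateral vs. dorsal side)",
              "Dorsal green morphs (lateral vs. dorsal side)",
              "Lateral green vs. dorsal green morphs (green body parts)",
              "Brown vs. lateral green morphs (dorsal view)",
              "Brown vs. dorsal green morphs (lateral view)",
              "Brown morphs (lateral vs. dorsal side)"),
    morph_a = c("brown", "brown", "lateral_green", "lateral_green",
                "lateral_green", "dorsal_green", "lateral_green",
                "brown", "brown", "brown"),
    patch_a = c("dorsal", "lateral", "dorsal", "lateral",
                "lateral", "lateral", "lateral",
                "dorsal", "lateral", "lateral"),
    morph_b = c("dorsal_green", "lateral_green", "dorsal_green",
                "dorsal_green", "lateral_green", "dorsal_green",
                "dorsal_green", "lateral_green", "dorsal_green", "brown"),
    patch_b = c("dorsal", "lateral", "dorsal", "lateral",
                "dorsal", "dorsal", "dorsal",
                "dorsal", "lateral", "dorsal"),
    stringsAsFactors = FALSE)
  out <- rbind(if ("sibiricus" %in% species) sib,
               if ("dorsatus" %in% species) dor)
  rownames(out) <- NULL
  out
}

#' Run a full comparison table across visual systems
#'
#' Evaluates every plan row under every visual system (the full cross), on
#' spectra restricted to the plan row's species when a `species` column is
#' present in both plan and metadata.
#'
#' @param x a `spectra` object on the modelling grid, non-negative.
#' @param systems list of `visual_system` objects (default all six built-in).
#' @param plan a plan data frame as produced by [default_plan()].
#' @param method aggregation method, see [compare_groups()].
#' @param threshold discriminability cut in JND.
#' @return data frame of class `comparison_table`: one row per plan row x
#'   system with `species`, `label`, `system`, `dS_mean`, `dL_mean`,
#'   `n_pairs`, `discriminable`.
#' @export
run_comparison_table <- function(x, systems = builtin_systems(),
                                 plan = default_plan(),
                                 method = c("pairwise_mean", "centroid"),
                                 threshold = 3) {
  stopifnot(inherits(x, "spectra"))
  method <- match.arg(method)
  if (inherits(systems, "visual_system")) systems <- list(systems)
  if (nrow(plan) == 0 || !length(systems)) {
    out <- data.frame(species = character(), label = character(),
                      system = character(), dS_mean = numeric(),
                      dL_mean = numeric(), n_pairs = integer(),
                      discriminable = logical())
    class(out) <- c("comparison_table", "data.frame")
    return(out)
  }
  known <- unique(c(x$meta$morph, "unknown"))
  miss <- setdiff(unique(c(plan$morph_a, plan$morph_b)), known)
  if (length(miss))
    stop("plan references unknown morph label(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  rows <- list()
  for (sys in systems) {
    for (r in seq_len(nrow(plan))) {
      pr <- plan[r, ]
      xs <- x
      if (!is.null(pr$species) && "species" %in% names(x$meta) &&
          pr$species %in% x$meta$species)
        xs <- filter_spectra(x, species = pr$species)
      cmp <- compare_groups(
        xs,
        group_a = list(morph = pr$morph_a, patch = pr$patch_a),
        group_b = list(morph = pr$morph_b, patch = pr$patch_b),
        system = sys, method = method, threshold = threshold,
        label = pr$label)
      rows[[length(rows) + 1L]] <- cbind(species = pr$species, cmp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Write a comparison table as CSV, markdown or JSON
#'
#' Cells whose distance strictly exceeds the threshold are flagged: a
#' `dS_gt3`/`dL_gt3`-style logical pair of columns in CSV and JSON, bold
#' cells in markdown.
#'
#' @param results a `comparison_table` data frame.
#' @param path output file path.
#' @param format one of `"csv"`, `"markdown"`, `"json"`.
#' @param threshold flagging cut, strict inequality.
#' @return `path`, invisibly.
#' @export
render_report <- function(results, path, format = c("csv", "markdown", "json"),
                          threshold = 3) {
  format <- match.arg(format)
  res <- as.data.frame(results)
  res$dS_flag <- res$dS_mean > threshold
  res$dL_flag <- res$dL_mean > threshold
  if (format == "csv") {
    utils::write.csv(res, path, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(res, path, auto_unbox = FALSE, digits = NA)
  } else {
    fmt_cell <- function(v, flag)
      ifelse(flag, sprintf("**%.3g**", v), sprintf("%.3g", v))
    lines <- c("| Species | Comparison | System | dS | dL | n pairs |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s | %d |",
                       res$species, res$label, res$system,
                       fmt_cell(res$dS_mean, res$dS_flag),
                       fmt_cell(res$dL_mean, res$dL_flag),
                       res$n_pairs))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Morph discriminability analysis
#'
#' The top-level fit: harmonizes a spectra collection onto the modelling
#' grid (1-nm, 300--700 nm), applies the non-negativity offset, pools pied
#' with brown, and evaluates the group-comparison plan under each visual
#' system with the receptor-noise-limited model.
#'
#' @param x a `spectra` object; must cover the modelling range.
#' @param systems list of `visual_system` objects; default the six built-in
#'   predator systems.
#' @param plan comparison plan; default [default_plan()] restricted to the
#'   species present in the metadata (all rows when species are unknown).
#' @param method aggregation over between-group pairs, see [compare_groups()].
#' @param threshold discriminability cut in JND (strict `>`).
#' @param range,step modelling range (nm) and grid step.
#' @return an object of class `morph_discrim` with the comparison table and
#'   the call settings; has `print`, `summary`, `plot` and `as.data.frame`
#'   methods.
#' @examples
#' sp <- gen_morph_spectra(seed = 1)
#' fit <- morph_discrimination(sp)
#' summary(fit)
#' @export
morph_discrimination <- function(x, systems = builtin_systems(),
                                 plan = NULL,
                                 method = c("pairwise_mean", "centroid"),
                                 threshold = 3, range = c(300, 700), step = 1) {
  stopifnot(inherits(x, "spectra"))
  method <- match.arg(method)
  x <- pool_pied(x)
  x <- interpolate_to_grid(clip_range(x, range[1], range[2]), step = step,
                           range = range)
  x <- offset_nonnegative(x)
  if (is.null(plan)) {
    plan <- default_plan()
    present <- intersect(unique(plan$species), unique(x$meta$species))
    if (length(present)) plan <- plan[plan$species %in% present, , drop = FALSE]
  }
  tab <- run_comparison_table(x, systems, plan, method, threshold)
  structure(list(comparisons = tab, method = method, threshold = threshold,
                 systems = vapply(systems, `[[`, character(1), "name"),
                 n_spectra = n_spectra(x), range = range, step = step),
            class = "morph_discrim")
}

#' @export
print.morph_discrim <- function(x, ...) {
  cat(sprintf("Morph discriminability analysis (%s, threshold %g JND)\n",
              x$method, x$threshold))
  cat(sprintf("  %d spectra, %d comparisons x %d visual systems\n",
              x$n_spectra,
              nrow(unique(x$comparisons[c("species", "label")])),
              length(x$systems)))
  nd <- sum(x$comparisons$discriminable)
  cat(sprintf("  %d of %d cells discriminable (both dS and dL > %g)\n",
              nd, nrow(x$comparisons), x$threshold))
  invisible(x)
}

#' @export
summary.morph_discrim <- function(object, ...) {
  tab <- object$comparisons
  cat(sprintf("Group distances (JND, %s aggregation):\n\n", object$method))
  show <- tab
  show$dS_mean <- round(show$dS_mean, 2)
  show$dL_mean <- round(show$dL_mean, 2)
  print(show, row.names = FALSE)
  invisible(tab)
}

#' @export
as.data.frame.morph_discrim <- function(x, ...) as.data.frame(x$comparisons)

#' @export
plot.morph_discrim <- function(x, ...) {
  tab <- x$comparisons
  lab <- paste(substr(tab$species, 1, 3), tab$label)
  graphics::dotchart(tab$dS_mean, labels = lab,
                     groups = factor(tab$system),
                     xlab = "chromatic distance dS (JND)", pch = 19, ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}
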