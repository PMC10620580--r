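#' Reflectance spectrum collections
#'
#' A `spectra` object holds a set of reflectance measurements on a shared
#' wavelength grid: a numeric wavelength vector `wl` (nm), a reflectance
#' matrix `refl` (one column per measurement, percent units), and a metadata
#' data frame `meta` with one row per column of `refl`.
#'
#' @param wl numeric vector of wavelengths in nm; strictly increasing,
#'   finite, within 200--1000 nm.
#' @param refl numeric matrix with `length(wl)` rows; column names are the
#'   sample ids and must be unique.
#' @param meta optional data frame with columns `sample_id`, `species`,
#'   `individual`, `morph`, `patch`, `replicate`. Missing fields default to
#'   `"unknown"` (`replicate` to `NA`). Rows are matched to `refl` columns by
#'   `sample_id`; unmatched columns keep default metadata.
#'
#' @return an object of class `spectra`.
#' @export
spectra <- function(wl, refl, meta = NULL) {
  wl <- as.numeric(wl)
  if (anyNA(wl) || any(!is.finite(wl)))
    stop("wavelengths must be finite", call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(wl < 200) || any(wl > 1000))
    stop("wavelengths must lie within [200, 1000] nm", call. = FALSE)
  refl <- as.matrix(refl)
  if (nrow(refl) != length(wl))
    stop("reflectance matrix must have one row per wavelength", call. = FALSE)
  if (is.null(colnames(refl)) && ncol(refl) > 0)
    colnames(refl) <- paste0("s", seq_len(ncol(refl)))
  if (anyDuplicated(colnames(refl)))
    stop("duplicate sample ids", call. = FALSE)
  if (!is.numeric(refl) || anyNA(refl) || any(!is.finite(refl)))
    stop("reflectance values must be finite numbers", call. = FALSE)
  meta <- .complete_meta(meta, colnames(refl))
  structure(list(wl = wl, refl = refl, meta = meta), class = "spectra")
}

.meta_fields <- c("sample_id", "species", "individual", "morph", "patch",
                  "replicate")

.complete_meta <- function(meta, ids) {
  unk <- rep("unknown", length(ids))
  out <- data.frame(sample_id = ids,
                    species = unk, individual = unk,
                    morph = unk, patch = unk,
                    replicate = rep(NA_integer_, length(ids)),
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(meta))
      stop("metadata must contain a sample_id column", call. = FALSE)
    if (anyDuplicated(meta$sample_id))
      stop("duplicate sample_id in metadata", call. = FALSE)
    idx <- match(ids, meta$sample_id)
    unmatched <- ids[is.na(idx)]
    if (length(unmatched))
      warning("no metadata for sample(s): ",
              paste(unmatched, collapse = ", "),
              "; fields set to \"unknown\"", call. = FALSE)
    for (f in setdiff(.meta_fields, "sample_id"))
      if (f %in% names(meta))
        out[[f]][!is.na(idx)] <- meta[[f]][idx[!is.na(idx)]]
  }
  rownames(out) <- NULL
  out
}

#' @export
print.spectra <- function(x, ...) {
  cat(sprintf("Reflectance spectra: %d measurement(s), %d wavelengths (%g-%g nm)\n",
              ncol(x$refl), length(x$wl), min(x$wl), max(x$wl)))
  tab <- table(morph = x$meta$morph, patch = x$meta$patch)
  if (any(dimnames(tab)$morph != "unknown")) print(tab)
  invisible(x)
}

#' @export
as.data.frame.spectra <- function(x, ...) {
  data.frame(wl = x$wl, x$refl, check.names = FALSE)
}

#' Number of spectra in a collection
#' @param x a `spectra` object.
#' @return integer count of measurements.
#' @export
n_spectra <- function(x) ncol(x$refl)

#' Subset a spectra collection by metadata
#'
#' @param x a `spectra` object.
#' @param ... named filters on metadata fields, e.g. `morph = "green"`,
#'   `patch = c("dorsal", "lateral")`. A filter keeps rows whose field is in
#'   the supplied set.
#' @return a `spectra` object with the matching measurements.
#' @export
filter_spectra <- function(x, ...) {
  stopifnot(inherits(x, "spectra"))
  filt <- list(...)
  keep <- rep(TRUE, ncol(x$refl))
  for (f in names(filt)) {
    if (!f %in% names(x$meta))
      stop("unknown metadata field: ", f, call. = FALSE)
    keep <- keep & x$meta[[f]] %in% filt[[f]]
  }
  spectra(x$wl, x$refl[, keep, drop = FALSE], x$meta[keep, , drop = FALSE])
}

#' Read reflectance spectra from a wide CSV
#'
#' The first column is wavelength in nm; every remaining column is one
#' measurement. An optional metadata CSV (columns `sample_id`, `species`,
#' `individual`, `morph`, `patch`, `replicate`) is joined by sample id.
#'
#' @param path path to the wide spectra CSV.
#' @param metadata_path optional path to the metadata CSV.
#' @return a `spectra` object.
#' @export
read_spectra <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop("spectra file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("spectra CSV needs a wavelength column and at least one spectrum",
                         call. = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicate column names in ", path, call. = FALSE)
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s', row %d", names(df)[j], bad[1]),
           call. = FALSE)
    df[[j]] <- v
  }
  wl <- df[[1]]
  if (anyNA(wl) || any(diff(wl) <= 0))
    stop("wavelength column must be strictly increasing", call. = FALSE)
  meta <- NULL
  if (!is.null(metadata_path)) {
    if (!file.exists(metadata_path))
      stop("metadata file not found: ", metadata_path, call. = FALSE)
    meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  }
  spectra(wl, as.matrix(df[, -1, drop = FALSE]), meta)
}

#' Write a spectra collection to wide CSV (plus optional metadata CSV)
#' @param x a `spectra` object.
#' @param path output CSV path for the wide table.
#' @param metadata_path optional output path for the metadata table.
#' @return `x`, invisibly.
#' @export
write_spectra <- function(x, path, metadata_path = NULL) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.csv(x$meta, metadata_path, row.names = FALSE)
  invisible(x)
}

#' Restrict spectra to a wavelength range
#'
#' Keeps grid points in `[lo, hi]` inclusive. The modelling range used for
#' visual models is 300--700 nm.
#'
#' @param x a `spectra` object.
#' @param lo,hi range limits in nm, `lo < hi`.
#' @return a clipped `spectra` object.
#' @export
clip_range <- function(x, lo = 300, hi = 700) {
  stopifnot(inherits(x, "spectra"))
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  keep <- x$wl >= lo & x$wl <= hi
  if (!any(keep))
    stop(sprintf("no grid points in [%g, %g] nm", lo, hi), call. = FALSE)
  spectra(x$wl[keep], x$refl[keep, , drop = FALSE], x$meta)
}

#' Offset spectra to non-negative reflectance
#'
#' For each measurement whose minimum is below zero, adds the absolute value
#' of that minimum to the whole spectrum (per-spectrum offset, the `addmin`
#' correction). Spectra that are already non-negative are returned unchanged.
#'
#' @param x a `spectra` object.
#' @return a `spectra` object with all values >= 0.
#' @export
offset_nonnegative <- function(x) {
  stopifnot(inherits(x, "spectra"))
  mins <- apply(x$refl, 2, min)
  off <- pmax(0, -mins)
  x$refl <- sweep(x$refl, 2, off, "+")
  x
}

#' Repair a known instrument-artifact window
#'
#' Spectrometer readings can carry a sharp spurious peak between 653.5 and
#' 660.5 nm. Every value inside the window is replaced by the mean of the
#' values in the two flank ranges (650--653 and 661--664 nm by default);
#' everything outside the window is untouched.
#'
#' @param x a `spectra` object.
#' @param window numeric length-2, window limits in nm (inclusive).
#' @param flanks list of two numeric length-2 ranges used for the replacement
#'   mean; each must contain at least one grid point.
#' @return a repaired `spectra` object.
#' @export
repair_artifact_window <- function(x, window = c(653.5, 660.5),
                                   flanks = list(c(650, 653), c(661, 664))) {
  stopifnot(inherits(x, "spectra"), length(window) == 2, length(flanks) == 2)
  in_win <- x$wl >= window[1] & x$wl <= window[2]
  if (!any(in_win)) return(x)
  in_flank <- (x$wl >= flanks[[1]][1] & x$wl <= flanks[[1]][2]) |
              (x$wl >= flanks[[2]][1] & x$wl <= flanks[[2]][2])
  if (!any(x$wl >= flanks[[1]][1] & x$wl <= flanks[[1]][2]) ||
      !any(x$wl >= flanks[[2]][1] & x$wl <= flanks[[2]][2]))
    stop("each flank range must contain at least one grid point", call. = FALSE)
  repl <- colMeans(x$refl[in_flank, , drop = FALSE])
  x$refl[in_win, ] <- matrix(repl, nrow = sum(in_win), ncol = ncol(x$refl),
                             byrow = TRUE)
  x
}

#' Average replicate measurements
#'
#' Pointwise arithmetic mean over groups defined by metadata fields
#' (individual and patch by default, the per-patch-per-individual averaging
#' applied before visual modelling). The replicate index is cleared; the
#' group size is recorded in a `n_replicates` metadata column.
#'
#' @param x a `spectra` object.
#' @param by metadata fields defining the grouping.
#' @return a `spectra` object with one averaged measurement per group.
#' @export
average_replicates <- function(x, by = c("individual", "patch")) {
  stopifnot(inherits(x, "spectra"))
  if (!all(by %in% names(x$meta)))
    stop("unknown grouping field(s): ",
         paste(setdiff(by, names(x$meta)), collapse = ", "), call. = FALSE)
  key <- do.call(paste, c(x$meta[by], sep = "||"))
  groups <- split(seq_len(ncol(x$refl)), factor(key, levels = unique(key)))
  refl <- vapply(groups, function(ix) rowMeans(x$refl[, ix, drop = FALSE]),
                 numeric(length(x$wl)))
  meta <- x$meta[vapply(groups, `[`, integer(1), 1), , drop = FALSE]
  meta$replicate <- NA_integer_
  meta$n_replicates <- lengths(groups)
  ids <- vapply(strsplit(names(groups), "||", fixed = TRUE),
                paste, character(1), collapse = "_")
  meta$sample_id <- ids
  colnames(refl) <- ids
  out <- spectra(x$wl, refl, NULL)
  out$meta <- { rownames(meta) <- NULL; meta }
  out
}

#' Smooth spectra with a local quadratic fit
#'
#' Degree-2 loess smoothing per measurement at the given span. Smoothing is
#' not applied anywhere by default in the pipeline; this is an opt-in noise
#' filter.
#'
#' @param x a `spectra` object on a regular grid.
#' @param span smoothing span as a fraction of the grid, in (0, 1].
#' @return a smoothed `spectra` object on the same grid.
#' @export
smooth_spectra <- function(x, span = 0.2) {
  stopifnot(inherits(x, "spectra"))
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1)
    stop("span must lie in (0, 1]", call. = FALSE)
  x$refl <- apply(x$refl, 2, function(y) {
    stats::predict(stats::loess(y ~ x$wl, span = span, degree = 2,
                                family = "gaussian",
                                control = stats::loess.control(surface = "direct")))
  })
  x
}

#' Interpolate spectra onto a regular grid
#'
#' Linear interpolation onto a regular grid at the requested step, spanning
#' `range` (the spectrum's own range by default). Extrapolation is refused.
#'
#' @param x a `spectra` object.
#' @param step grid step in nm.
#' @param range optional numeric length-2 target range in nm; must be covered
#'   by the existing grid.
#' @return a `spectra` object on the regular grid.
#' @export
interpolate_to_grid <- function(x, step = 1, range = NULL) {
  stopifnot(inherits(x, "spectra"))
  if (is.null(range)) range <- c(min(x$wl), max(x$wl))
  if (range[1] < min(x$wl) || range[2] > max(x$wl))
    stop("requested grid extends beyond the measured range (extrapolation refused)",
         call. = FALSE)
  grid <- seq(range[1], range[2], by = step)
  refl <- apply(x$refl, 2, function(y)
    stats::approx(x$wl, y, xout = grid)$y)
  spectra(grid, refl, x$meta)
}

#' Locate reflectance peaks
#'
#' Finds interior local maxima with topographic prominence at or above a
#' threshold. Prominence of a peak is its height minus the higher of the two
#' lowest points separating it from higher terrain (or the grid edge).
#'
#' @param x a `spectra` object or a numeric vector (then `wl` is required).
#' @param min_prominence minimum prominence, percent reflectance.
#' @param wl wavelengths, only when `x` is a bare numeric vector.
#' @return for a numeric vector, a numeric vector of peak wavelengths in
#'   ascending order (possibly empty); for a `spectra` object, a named list
#'   of such vectors, one per measurement.
#' @export
find_peaks <- function(x, min_prominence = 1, wl = NULL) {
  if (inherits(x, "spectra"))
    return(lapply(stats::setNames(seq_len(ncol(x$refl)), colnames(x$refl)),
                  function(j) .peaks_1d(x$wl, x$refl[, j], min_prominence)))
  if (is.null(wl)) stop("wl required for a numeric vector", call. = FALSE)
  .peaks_1d(wl, x, min_prominence)
}

.peaks_1d <- function(wl, y, min_prom) {
  n <- length(y)
  if (n < 3) return(numeric(0))
  cand <- which(diff(sign(diff(y))) == -2) + 1L  # strict interior maxima
  if (!length(cand)) return(numeric(0))
  prom <- vapply(cand, function(i) {
    left <- if (any(y[seq_len(i - 1)] > y[i])) {
      j <- max(which(y[seq_len(i - 1)] > y[i]))
      min(y[j:i])
    } else min(y[1:i])
    right <- if (any(y[(i + 1):n] > y[i])) {
      j <- i + min(which(y[(i + 1):n] > y[i]))
      min(y[i:j])
    } else min(y[i:n])
    y[i] - max(left, right)
  }, numeric(1))
  sort(wl[cand[prom >= min_prom]])
}
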