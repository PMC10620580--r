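.stage_levels <- c("N1", "N2", "N3", "N4", "imago")

#' Read per-individual, per-stage RGB measurements
#'
#' @param path CSV with columns `individual`, `species`, `stage` (N1--N4 or
#'   imago), `morph`, `patch`, `R`, `G`, `B` (mean channel values, 0--255).
#' @return validated data frame of RGB measurements.
#' @export
read_rgb <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_rgb(df)
}

#' @noRd
validate_rgb <- function(df) {
  need <- c("individual", "species", "stage", "morph", "patch", "R", "G", "B")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("RGB table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$stage %in% .stage_levels))
    stop("stage must be one of ", paste(.stage_levels, collapse = ", "),
         call. = FALSE)
  tot <- df$R + df$G + df$B
  if (any(!is.finite(tot)) || any(tot <= 0))
    stop("R+G+B must be positive for every measurement", call. = FALSE)
  df$stage <- factor(df$stage, levels = .stage_levels)
  df
}

#' Ternary chromaticity of RGB measurements
#'
#' Normalizes RGB to proportions on the 2-simplex, `r = R/(R+G+B)` etc.,
#' removing brightness: only chromatic, not luminance, information remains,
#' so the coordinates are invariant to exposure scaling.
#'
#' @param df an RGB measurement data frame (see [read_rgb()]), or a numeric
#'   length-3 vector `c(R, G, B)`.
#' @return the data frame with added columns `r`, `g`, `b` (each in
#'   `[0, 1]`, summing to 1), or a named numeric vector for vector input.
#' @export
chromaticity <- function(df) {
  if (is.numeric(df) && length(df) == 3) {
    if (sum(df) <= 0) stop("degenerate RGB: R+G+B must be > 0", call. = FALSE)
    return(stats::setNames(df / sum(df), c("r", "g", "b")))
  }
  df <- validate_rgb(as.data.frame(df))
  tot <- df$R + df$G + df$B
  df$r <- df$R / tot
  df$g <- df$G / tot
  df$b <- df$B / tot
  df
}

#' Standardized morph separation at one developmental stage
#'
#' Quantifies how far apart the morph clouds sit in (r, g) chromaticity
#' space at a given stage: the Euclidean distance between the two morph
#' centroids divided by the pooled within-morph root-mean-square deviation.
#' Two dimensions suffice because b = 1 - r - g on the simplex. Values near
#' 0 mean coincident clouds; values above ~2 mean clearly separated clouds.
#'
#' @param df an RGB measurement data frame.
#' @param stage stage label (`"N1"` ... `"imago"`).
#' @param morphs optional pair of morph labels; default the two most
#'   frequent morphs at that stage.
#' @return list with `statistic`, `stage`, `morphs`, `n` (group sizes).
#' @export
stage_separation <- function(df, stage, morphs = NULL) {
  df <- chromaticity(df)
  sub <- df[df$stage == stage, , drop = FALSE]
  if (is.null(morphs)) {
    tab <- sort(table(sub$morph), decreasing = TRUE)
    if (length(tab) < 2)
      stop("need at least two morph groups at stage ", stage, call. = FALSE)
    morphs <- names(tab)[1:2]
  }
  a <- sub[sub$morph == morphs[1], c("r", "g"), drop = FALSE]
  b <- sub[sub$morph == morphs[2], c("r", "g"), drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need >= 2 measurements per morph at stage ", stage, call. = FALSE)
  ca <- colMeans(a); cb <- colMeans(b)
  d <- sqrt(sum((ca - cb)^2))
  dev2 <- c(rowSums(sweep(as.matrix(a), 2, ca)^2),
            rowSums(sweep(as.matrix(b), 2, cb)^2))
  rms <- sqrt(mean(dev2))
  list(statistic = if (rms > 0) d / rms else ifelse(d > 0, Inf, 0),
       stage = stage, morphs = morphs, n = c(nrow(a), nrow(b)))
}

#' Earliest stage at which morphs diverge in chromaticity
#'
#' Walks the stages in developmental order and returns the first whose
#' separation statistic strictly exceeds the threshold; `"none"` if no stage
#' does.
#'
#' @param df an RGB measurement data frame.
#' @param threshold separation cut; the default 2 is a convention, not a
#'   measured constant.
#' @param morphs optional morph pair passed to [stage_separation()].
#' @return list with `stage` (label or `"none"`) and `separation` (named
#'   vector of per-stage statistics).
#' @export
divergence_stage <- function(df, threshold = 2, morphs = NULL) {
  df <- chromaticity(df)
  stages <- intersect(.stage_levels, unique(as.character(df$stage)))
  if (length(stages) < 2)
    stop("need separation for at least two stages", call. = FALSE)
  sep <- vapply(stages, function(s)
    stage_separation(df, s, morphs)$statistic, numeric(1))
  hit <- which(sep > threshold)
  list(stage = if (length(hit)) stages[min(hit)] else "none",
       separation = sep)
}

#' Export ternary coordinates for plotting
#' @param df an RGB measurement data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ternary <- function(df, path) {
  utils::write.csv(chromaticity(df), path, row.names = FALSE)
  invisible(path)
}
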