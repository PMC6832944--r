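#' Signal magnitude vector
#'
#' Euclidean norm of the three acceleration axes, in g. Also called the
#' resultant acceleration.
#'
#' @param x,y,z Acceleration along each axis, in g (vectorised).
#' @return Non-negative magnitude in g.
#' @export
smv <- function(x, y, z) sqrt(x^2 + y^2 + z^2)

#' Euclidean Norm Minus One
#'
#' Acceleration magnitude with the 1 g gravity offset removed; negative
#' values are flattened to zero, so a device at rest reads exactly 0.
#'
#' @inheritParams smv
#' @return \code{max(0, smv - 1)} in g.
#' @export
enmo <- function(x, y, z) pmax(0, smv(x, y, z) - 1)

#' Per-axis orientation angles relative to the horizontal plane
#'
#' For each axis the angle between the acceleration vector's component along
#' that axis and the plane of the other two:
#' \code{angle_a = atan(a / sqrt(b^2 + c^2)) * 180 / pi}, in degrees within
#' [-90, 90]. When the device is static these estimate wrist posture. The
#' degenerate denominator (acceleration entirely along one axis) resolves to
#' +/-90 via the two-argument arctangent.
#'
#' @inheritParams smv
#' @return A list with components \code{angle_x}, \code{angle_y},
#'   \code{angle_z}, each in degrees (vectorised).
#' @export
orientation_angles <- function(x, y, z) {
  if (any(x == 0 & y == 0 & z == 0)) {
    stop("orientation angle undefined for zero acceleration vector",
         call. = FALSE)
  }
  r2d <- 180 / pi
  list(angle_x = atan2(x, sqrt(y^2 + z^2)) * r2d,
       angle_y = atan2(y, sqrt(x^2 + z^2)) * r2d,
       angle_z = atan2(z, sqrt(x^2 + y^2)) * r2d)
}

# population standard deviation: divide by n, not n-1
pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

axis_stats <- function(v, prefix) {
  q <- stats::quantile(v, c(0.10, 0.75, 0.90), names = FALSE, type = 7)
  s <- pop_sd(v)
  out <- c(max(v), min(v), mean(v), stats::median(v), q[1], q[2], q[3], s, s^2)
  names(out) <- paste0(prefix, "_",
                       c("max", "min", "mean", "median", "p10", "p75", "p90",
                         "sd", "var"))
  out
}

angle_stats <- function(v, prefix) {
  out <- c(min(v), max(v), mean(v), stats::median(v), pop_sd(v))
  names(out) <- paste0(prefix, "_", c("min", "max", "mean", "median", "sd"))
  out
}

#' Time-domain features of one window
#'
#' The full candidate set: nine order/dispersion statistics (max, min, mean,
#' median, 10th/75th/90th percentile, standard deviation, variance) per
#' acceleration axis; mean, max and median of per-sample ENMO; and min, max,
#' mean, median and standard deviation of the per-sample orientation angle of
#' each axis. Standard deviations and variances use the population convention
#' (divide by n); percentiles interpolate linearly between order statistics.
#'
#' @param w Numeric matrix of window samples, columns \code{x,y,z}, in g.
#' @return Named numeric vector of 45 features.
#' @export
time_features <- function(w) {
  stopifnot(is.matrix(w), ncol(w) == 3L, nrow(w) >= 1L)
  e <- enmo(w[, 1], w[, 2], w[, 3])
  ang <- orientation_angles(w[, 1], w[, 2], w[, 3])
  c(axis_stats(w[, 1], "acc_x"),
    axis_stats(w[, 2], "acc_y"),
    axis_stats(w[, 3], "acc_z"),
    enmo_mean = mean(e), enmo_max = max(e), enmo_median = stats::median(e),
    angle_stats(ang$angle_x, "angle_x"),
    angle_stats(ang$angle_y, "angle_y"),
    angle_stats(ang$angle_z, "angle_z"))
}

#' Frequency-domain features of one window
#'
#' Plain (untapered) periodogram of the window's per-sample ENMO series with
#' the zero-frequency bin excluded; dominant frequency is the frequency of
#' the maximal bin and dominant power that bin's value (\code{|FFT|^2 / n}).
#' Frequency resolution is 1 / window width. A constant (e.g. all-zero ENMO)
#' window reports (0, 0) by convention.
#'
#' @inheritParams time_features
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector \code{dominant_freq} (Hz),
#'   \code{dominant_power}.
#' @export
frequency_features <- function(w, fs) {
  stopifnot(is.matrix(w), ncol(w) == 3L, nrow(w) >= 2L)
  e <- enmo(w[, 1], w[, 2], w[, 3])
  n <- length(e)
  p <- Mod(stats::fft(e))^2 / n
  kmax <- n %/% 2
  if (kmax < 1L) return(c(dominant_freq = 0, dominant_power = 0))
  bins <- p[2:(kmax + 1L)]          # DC excluded
  if (max(bins) <= .Machine$double.eps * n) {
    return(c(dominant_freq = 0, dominant_power = 0))
  }
  k <- which.max(bins)
  c(dominant_freq = k * fs / n, dominant_power = bins[k])
}

#' Names of the full candidate feature set
#' @return Character vector of the 47 feature names produced by
#'   [extract_features()].
#' @export
all_feature_names <- function() {
  c(paste0(rep(c("acc_x", "acc_y", "acc_z"), each = 9), "_",
           c("max", "min", "mean", "median", "p10", "p75", "p90", "sd", "var")),
    "enmo_mean", "enmo_max", "enmo_median",
    paste0(rep(c("angle_x", "angle_y", "angle_z"), each = 5), "_",
           c("min", "max", "mean", "median", "sd")),
    "dominant_freq", "dominant_power")
}

#' Extract a window-level feature matrix from a recording
#'
#' Trims transitions from the supplied bouts, cuts the recording into
#' tumbling windows and computes the full time- and frequency-domain feature
#' set for every window.
#'
#' @param rec A \code{raw_recording}.
#' @param bouts Optional labelled bouts; trimmed by \code{trim} seconds
#'   before labelling windows.
#' @param width Window width in seconds (default 10).
#' @param trim Transition margin in seconds (default 30).
#' @return A \code{feature_matrix}: numeric matrix (one row per window) with
#'   attributes \code{labels} (character per row, \code{NA} when unlabelled),
#'   \code{window_index} and \code{normalized = FALSE}.
#' @export
extract_features <- function(rec, bouts = NULL, width = 10, trim = 30) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!is.null(bouts)) bouts <- trim_transitions(bouts, trim)
  wins <- make_windows(rec, bouts, width)
  xyz <- as.matrix(rec$samples[, c("x", "y", "z")])
  rows <- lapply(seq_len(nrow(wins)), function(i) {
    w <- xyz[(wins$start_sample[i] + 1L):wins$end_sample[i], , drop = FALSE]
    c(time_features(w), frequency_features(w, rec$fs))
  })
  m <- do.call(rbind, rows)
  feature_matrix(m, labels = wins$label, window_index = wins$window_index)
}

#' Construct a feature matrix
#'
#' @param m Numeric matrix, one row per window, named feature columns.
#' @param labels Optional character vector of class labels per row.
#' @param window_index Optional integer window indices.
#' @param normalized Whether values are already MinMax-normalised.
#' @return A \code{feature_matrix} object.
#' @export
feature_matrix <- function(m, labels = NULL, window_index = NULL,
                           normalized = FALSE) {
  m <- as.matrix(m)
  stopifnot(!is.null(colnames(m)), !anyDuplicated(colnames(m)))
  if (anyNA(m)) stop("feature matrix contains missing values", call. = FALSE)
  if (!is.null(labels)) stopifnot(length(labels) == nrow(m))
  if (is.null(window_index)) window_index <- seq_len(nrow(m)) - 1L
  structure(m, labels = labels, window_index = window_index,
            normalized = normalized,
            class = c("feature_matrix", class(m)))
}

#' @export
print.feature_matrix <- function(x, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("feature_matrix: %d windows x %d features (%s)%s\n",
              nrow(x), ncol(x),
              if (attr(x, "normalized")) "normalized" else "raw units",
              if (!is.null(lab))
                sprintf(", %d labelled", sum(!is.na(lab))) else ""))
  invisible(x)
}

#' Subset the feature columns of a feature matrix
#' @param fm A \code{feature_matrix}.
#' @param names Feature names to keep, in order.
#' @return A \code{feature_matrix} with the selected columns.
#' @export
select_columns <- function(fm, names) {
  missing <- setdiff(names, colnames(fm))
  if (length(missing)) {
    stop("feature columns not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  feature_matrix(unclass(fm)[, names, drop = FALSE],
                 labels = attr(fm, "labels"),
                 window_index = attr(fm, "window_index"),
                 normalized = attr(fm, "normalized"))
}

#' Feature specification
#'
#' An ordered list of feature names with the correlation threshold used for
#' selection and the ordered class encoding mapping activity labels to
#' integer codes 0..k-1.
#'
#' @param names Ordered feature names.
#' @param selection_threshold Minimum absolute Pearson correlation with the
#'   encoded class for a feature to be retained (default 0.12).
#' @param class_encoding Ordered character vector of activity labels; the
#'   position (minus one) is the integer code. Default is the laboratory
#'   label set ranked by typical intensity.
#' @param loadings Optional named numeric vector of correlations.
#' @return A \code{feature_spec} object.
#' @export
feature_spec <- function(names,
                         selection_threshold = 0.12,
                         class_encoding = default_class_encoding(),
                         loadings = NULL) {
  stopifnot(!anyDuplicated(names),
            selection_threshold >= 0, selection_threshold <= 1)
  structure(list(names = names,
                 selection_threshold = selection_threshold,
                 class_encoding = class_encoding,
                 loadings = loadings),
            class = "feature_spec")
}

#' Default intensity-ranked class encoding
#' @return Character vector of the nine laboratory activity labels in
#'   ascending typical intensity.
#' @export
default_class_encoding <- function() {
  c("lying", "seated", "standing", "household", "indoor walking",
    "treadmill walking", "brisk outdoor walk", "stairs", "running")
}

#' The canonical 24-feature specification
#'
#' The published model's feature vector: dominant frequency, eleven
#' magnitude statistics and twelve orientation-angle statistics, shipped with
#' their development-sample class loadings. This list is fixed data, not
#' recomputed, so downstream models do not depend on the selection step.
#'
#' @return A \code{feature_spec} with 24 names and their loadings.
#' @export
canonical_feature_spec <- function() {
  path <- system.file("extdata", "canonical_features.csv",
                      package = "wristclust", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feature_spec(df$feature,
               loadings = stats::setNames(df$loading, df$feature))
}

#' Correlation-based feature selection
#'
#' Retains candidate features whose absolute Pearson correlation with the
#' integer-encoded class vector meets the threshold; correlations below it
#' are considered weak. A constant feature has its correlation defined as 0
#' and is never selected.
#'
#' @param fm A labelled \code{feature_matrix} (raw units).
#' @param spec A \code{feature_spec} carrying the threshold and class
#'   encoding. Defaults to all columns of \code{fm}.
#' @return A new \code{feature_spec} with the retained names and computed
#'   loadings (for all candidates, as attribute \code{all_loadings}).
#' @export
select_features <- function(fm, spec = NULL) {
  labels <- attr(fm, "labels")
  if (is.null(labels)) stop("feature matrix has no labels", call. = FALSE)
  keep <- !is.na(labels)
  if (!any(keep)) stop("no labelled windows", call. = FALSE)
  if (is.null(spec)) spec <- feature_spec(colnames(fm))
  enc <- spec$class_encoding
  unknown <- setdiff(unique(labels[keep]), enc)
  if (length(unknown)) {
    stop("labels not in class encoding: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cls <- match(labels[keep], enc) - 1L
  m <- unclass(fm)[keep, spec$names, drop = FALSE]
  r <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    if (pop_sd(v) == 0 || pop_sd(cls) == 0) return(0)
    stats::cor(v, cls)
  }, numeric(1))
  names(r) <- colnames(m)
  sel <- names(r)[abs(r) >= spec$selection_threshold]
  out <- feature_spec(sel, spec$selection_threshold, enc,
                      loadings = r[sel])
  attr(out, "all_loadings") <- r
  out
}

#' Fit MinMax normalisation parameters
#'
#' Records the per-feature minimum and maximum of the training matrix.
#'
#' @param fm A \code{feature_matrix} (raw units).
#' @return A \code{minmax_params} object with \code{min} and \code{max}
#'   named vectors.
#' @export
minmax_fit <- function(fm) {
  m <- unclass(fm)
  structure(list(min = apply(m, 2, min), max = apply(m, 2, max),
                 features = colnames(m)),
            class = "minmax_params")
}

#' Apply MinMax normalisation
#'
#' \code{x' = (x - min) / (max - min)} per feature, with training-set
#' parameters. A constant training column maps to 0. Values outside the
#' training range are NOT clipped, so new data may fall outside [0, 1]:
#' clipping would distort distances to the stored centroids.
#'
#' @param fm A \code{feature_matrix} whose columns match \code{params}.
#' @param params A \code{minmax_params} from [minmax_fit()].
#' @return A normalised \code{feature_matrix}.
#' @export
minmax_apply <- function(fm, params) {
  stopifnot(inherits(params, "minmax_params"))
  if (!identical(colnames(fm), params$features)) {
    stop("feature columns do not match normalization parameters",
         call. = FALSE)
  }
  m <- unclass(fm)
  rng <- params$max - params$min
  out <- sweep(m, 2, params$min)
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  feature_matrix(out, labels = attr(fm, "labels"),
                 window_index = attr(fm, "window_index"), normalized = TRUE)
}

#' Write a feature matrix to delimited text
#' @param fm A \code{feature_matrix}.
#' @param path Output path.
#' @export
write_features <- function(fm, path) {
  df <- as.data.frame(unclass(fm))
  df$window_index <- attr(fm, "window_index")
  lab <- attr(fm, "labels")
  if (!is.null(lab)) df$label <- lab
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix from delimited text
#' @param path Path written by [write_features()].
#' @param normalized Whether the stored values are normalised.
#' @return A \code{feature_matrix}.
#' @export
read_features <- function(path, normalized = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lab <- if ("label" %in% names(df)) as.character(df$label) else NULL
  if (!is.null(lab)) lab[lab == "" | lab == "NA"] <- NA_character_
  wi <- if ("window_index" %in% names(df)) df$window_index else NULL
  keep <- setdiff(names(df), c("label", "window_index"))
  feature_matrix(as.matrix(df[, keep, drop = FALSE]), labels = lab,
                 window_index = wi, normalized = normalized)
}
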