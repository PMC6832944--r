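#' Read a raw triaxial acceleration signal
#'
#' Reads a delimited text file with columns \code{time,x,y,z} (header row
#' required): time in seconds from the start of the recording, axes in g.
#' Values are assumed already calibrated to gravitational units; no
#' autocalibration is applied.
#'
#' @param path Path to the signal file.
#' @param fs Sampling rate in Hz. Must lie in [10, 160] and agree with the
#'   timestamps to within half a sample interval.
#' @param wrist Wrist of wear: \code{"left"}, \code{"right"} or
#'   \code{"unknown"}.
#' @param sep Field separator, default comma.
#' @return A \code{raw_recording} object: list with \code{samples}
#'   (data.frame \code{time,x,y,z}), \code{fs} and \code{wrist}.
#' @seealso [simulate_recording()], [make_windows()]
#' @export
read_raw_signal <- function(path, fs, wrist = c("unknown", "left", "right"),
                            sep = ",") {
  wrist <- match.arg(wrist)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c("time", "x", "y", "z")) {
    if (!col %in% names(df)) {
      stop("missing column ", col, call. = FALSE)
    }
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop("non-numeric value in column '", col, "' at row ",
           if (is.na(bad)) "?" else bad, call. = FALSE)
    }
  }
  raw_recording(df[, c("time", "x", "y", "z")], fs = fs, wrist = wrist)
}

#' Construct a raw recording
#'
#' Validates sampling-rate range, timestamp uniformity and finiteness of the
#' axes. Timestamps must be strictly increasing and uniform to within half a
#' sample interval; irregular sampling is a hard error, never resampled.
#'
#' @param samples data.frame with columns \code{time,x,y,z}.
#' @inheritParams read_raw_signal
#' @return A \code{raw_recording} object.
#' @export
raw_recording <- function(samples, fs, wrist = "unknown") {
  stopifnot(is.data.frame(samples),
            all(c("time", "x", "y", "z") %in% names(samples)))
  if (!is.numeric(fs) || length(fs) != 1L || fs < 10 || fs > 160) {
    stop("fs must be a single value in [10, 160] Hz", call. = FALSE)
  }
  if (!wrist %in% c("left", "right", "unknown")) {
    stop("wrist must be one of left, right, unknown", call. = FALSE)
  }
  axes <- as.matrix(samples[, c("x", "y", "z")])
  if (!all(is.finite(axes))) {
    bad <- which(!stats::complete.cases(axes) | rowSums(!is.finite(axes)) > 0)[1]
    stop("non-finite acceleration value at row ", bad, call. = FALSE)
  }
  t <- samples$time
  if (nrow(samples) > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) {
      stop("non-monotone time at row ", which(dt <= 0)[1] + 1L, call. = FALSE)
    }
    tol <- 1 / (2 * fs)
    off <- abs(dt - 1 / fs)
    if (any(off > tol)) {
      stop("non-uniform sampling at row ", which(off > tol)[1] + 1L,
           ": interval deviates from 1/fs by more than half a sample",
           call. = FALSE)
    }
  }
  structure(list(samples = samples[, c("time", "x", "y", "z")],
                 fs = fs, wrist = wrist),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  n <- nrow(x$samples)
  dur <- if (n > 1) n / x$fs else 0
  cat(sprintf("raw_recording: %d samples at %g Hz (%.1f s), wrist: %s\n",
              n, x$fs, dur, x$wrist))
  invisible(x)
}

#' Write a raw signal to delimited text
#'
#' Inverse of [read_raw_signal()]; full-precision decimal output so that
#' write-then-read round-trips are lossless.
#'
#' @param rec A \code{raw_recording}.
#' @param path Output path.
#' @export
write_raw_signal <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  df <- rec$samples
  df[] <- lapply(df, function(v) format(v, digits = 17, scientific = FALSE,
                                        trim = TRUE))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read labelled activity bouts
#'
#' Reads a delimited text file with columns \code{start,end,label} (seconds
#' from the start of the matching recording). Bouts are sorted by start and
#' must not overlap.
#'
#' @param path Path to the label file.
#' @param sep Field separator, default comma.
#' @return data.frame with columns \code{start,end,label}, sorted by start.
#' @export
read_labels <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c("start", "end", "label")) {
    if (!col %in% names(df)) stop("missing column ", col, call. = FALSE)
  }
  label_bouts(df)
}

#' Validate and sort activity bouts
#'
#' @param df data.frame with columns \code{start,end,label}.
#' @return The sorted, validated data.frame.
#' @export
label_bouts <- function(df) {
  stopifnot(all(c("start", "end", "label") %in% names(df)))
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1]
    stop("bout ", bad, " has end <= start", call. = FALSE)
  }
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L) {
    ov <- which(df$start[-1] < df$end[-nrow(df)])
    if (length(ov)) {
      stop(sprintf("overlapping bouts: (%g, %g, %s) and (%g, %g, %s)",
                   df$start[ov[1]], df$end[ov[1]], df$label[ov[1]],
                   df$start[ov[1] + 1], df$end[ov[1] + 1],
                   df$label[ov[1] + 1]), call. = FALSE)
    }
  }
  df
}

#' Write activity bouts to delimited text
#' @param bouts data.frame with columns \code{start,end,label}.
#' @param path Output path.
#' @export
write_labels <- function(bouts, path) {
  utils::write.table(bouts[, c("start", "end", "label")], path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trim transition periods from labelled bouts
#'
#' Discards \code{margin} seconds from the beginning and before the end of
#' each labelled activity, removing the transitional movement between
#' activities. Bouts shorter than twice the margin are dropped entirely.
#'
#' @param bouts data.frame of bouts (\code{start,end,label}).
#' @param margin Seconds trimmed from each end of every bout (default 30).
#' @return Trimmed bouts, same columns.
#' @export
trim_transitions <- function(bouts, margin = 30) {
  stopifnot(is.numeric(margin), length(margin) == 1L, margin >= 0)
  if (margin == 0) return(bouts)
  out <- bouts
  out$start <- out$start + margin
  out$end <- out$end - margin
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cut a recording into fixed non-overlapping windows
#'
#' Slices the recording into consecutive tumbling windows of
#' \code{round(width * fs)} samples. The trailing partial window is dropped.
#' When bouts are supplied a window receives a label only if it lies entirely
#' inside one bout; windows straddling a bout boundary or outside every bout
#' are unlabelled (\code{NA}).
#'
#' @param rec A \code{raw_recording}.
#' @param bouts Optional data.frame of (trimmed) bouts.
#' @param width Window width in seconds (default 10). \code{width * fs} must
#'   be a whole number of samples.
#' @return data.frame with columns \code{window_index} (0-based),
#'   \code{start_sample}, \code{end_sample} (0-based half-open sample range)
#'   and \code{label} (character, \code{NA} when unlabelled).
#' @export
make_windows <- function(rec, bouts = NULL, width = 10) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    stop("width must be a positive number of seconds", call. = FALSE)
  }
  nper <- width * rec$fs
  if (abs(nper - round(nper)) > 1e-9) {
    stop("width * fs must be a whole number of samples", call. = FALSE)
  }
  nper <- as.integer(round(nper))
  total <- nrow(rec$samples)
  nwin <- total %/% nper
  if (nwin == 0L) {
    return(data.frame(window_index = integer(), start_sample = integer(),
                      end_sample = integer(), label = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- seq_len(nwin) - 1L
  start <- idx * nper
  end <- start + nper
  label <- rep(NA_character_, nwin)
  if (!is.null(bouts) && nrow(bouts)) {
    t <- rec$samples$time
    t0 <- t[start + 1L]
    t1 <- t[end]            # last sample of the window
    for (b in seq_len(nrow(bouts))) {
      inside <- t0 >= bouts$start[b] & t1 <= bouts$end[b]
      label[inside] <- bouts$label[b]
    }
  }
  data.frame(window_index = idx, start_sample = start, end_sample = end,
             label = label, stringsAsFactors = FALSE)
}
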