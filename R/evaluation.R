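#' Class-by-cluster contingency table
#'
#' Counts windows by (cluster, ground-truth class). All purity statistics are
#' derived from these counts: n_ij is the count for cluster i and class j,
#' with cluster totals n_ci, class totals n_ej and grand total N.
#'
#' @param labels Ground-truth class per window (character/factor).
#' @param clusters Cluster identifier per window (character/factor/integer).
#' @return A \code{contingency_table}: list with \code{n} (matrix, clusters
#'   as rows, classes as columns), \code{cluster_totals}, \code{class_totals}
#'   and \code{N}.
#' @export
contingency <- function(labels, clusters) {
  if (length(labels) != length(clusters)) {
    stop("labels and clusters must have equal length", call. = FALSE)
  }
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(labels) || anyNA(clusters)) {
    stop("missing entries in labels or clusters", call. = FALSE)
  }
  n <- table(cluster = as.character(clusters), class = as.character(labels))
  n <- unclass(n)
  structure(list(n = n,
                 cluster_totals = rowSums(n),
                 class_totals = colSums(n),
                 N = sum(n)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table: %d clusters x %d classes, N = %d\n",
              nrow(x$n), ncol(x$n), x$N))
  print(x$n)
  invisible(x)
}

#' Purity matrix
#'
#' For each ground-truth class, the percentage of its windows falling in each
#' cluster (rows sum to 100), plus each cluster's share of total time.
#' Classes with zero windows are excluded with a warning.
#'
#' @param ct A \code{contingency_table}.
#' @return A \code{purity_matrix}: list with \code{P} (classes x clusters,
#'   row percentages) and \code{cluster_share} (percent of all windows per
#'   cluster).
#' @export
purity_matrix <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  n <- ct$n
  keep <- ct$class_totals > 0
  if (!all(keep)) {
    warning("classes with zero windows excluded: ",
            paste(colnames(n)[!keep], collapse = ", "), call. = FALSE)
    n <- n[, keep, drop = FALSE]
  }
  P <- t(n) / colSums(n) * 100          # rows = classes
  new_purity_matrix(P, ct$cluster_totals / ct$N * 100)
}

#' Construct a purity matrix from percentage values
#'
#' For entering externally reported purity matrices (e.g. published tables)
#' so the category-capture arithmetic can be run on them.
#'
#' @param P Numeric matrix, classes as rows, clusters as columns, row
#'   percentages.
#' @param cluster_share Percent of total windows per cluster.
#' @return A \code{purity_matrix}.
#' @export
new_purity_matrix <- function(P, cluster_share = NULL) {
  P <- as.matrix(P)
  structure(list(P = P, cluster_share = cluster_share),
            class = "purity_matrix")
}

#' @export
print.purity_matrix <- function(x, digits = 1, ...) {
  out <- round(x$P, digits)
  if (!is.null(x$cluster_share)) {
    out <- rbind(`% of total time` = round(x$cluster_share, digits), out)
  }
  print(out)
  invisible(x)
}

#' Write a purity matrix as delimited text
#'
#' Clusters as columns, classes as rows, cluster-share row first, one
#' decimal place.
#'
#' @param pm A \code{purity_matrix}.
#' @param path Output path.
#' @export
write_purity <- function(pm, path) {
  df <- data.frame(class = c(if (!is.null(pm$cluster_share)) "share",
                             rownames(pm$P)),
                   rbind(if (!is.null(pm$cluster_share))
                     round(pm$cluster_share, 1), round(pm$P, 1)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a purity matrix written by [write_purity()]
#' @param path Path to the delimited file.
#' @return A \code{purity_matrix}.
#' @export
read_purity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cls <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  share <- NULL
  if (cls[1] == "share") {
    share <- stats::setNames(m[1, ], colnames(m))
    m <- m[-1, , drop = FALSE]
    cls <- cls[-1]
  }
  rownames(m) <- cls
  new_purity_matrix(m, share)
}

#' Ordered map from behaviour categories to cluster letters
#'
#' Categories must be disjoint; together they should cover all clusters.
#' The default is the published four-category split of the ten clusters.
#'
#' @param ... Named character vectors of cluster letters, e.g.
#'   \code{sedentary = c("A","B")}.
#' @return A named list of class \code{category_map}.
#' @export
category_map <- function(...) {
  cm <- list(...)
  if (length(cm) == 1L && is.list(cm[[1]]) && is.null(names(cm))) cm <- cm[[1]]
  stopifnot(length(names(cm)) == length(cm), all(nzchar(names(cm))))
  all_letters <- unlist(cm, use.names = FALSE)
  if (anyDuplicated(all_letters)) {
    stop("categories must be disjoint; duplicated cluster: ",
         all_letters[duplicated(all_letters)][1], call. = FALSE)
  }
  structure(cm, class = "category_map")
}

#' @describeIn category_map The published default: sedentary A-E,
#'   standing/mixed/slow ambulatory F-H, brisk ambulatory I, running J.
#' @export
default_category_map <- function() {
  category_map(sedentary = c("A", "B", "C", "D", "E"),
               standing_mixed_slow = c("F", "G", "H"),
               brisk = "I",
               running = "J")
}

#' Category capture percentages
#'
#' Percentage of each class's windows falling in each named group of
#' clusters: the sum over the group's columns of the class's purity-matrix
#' row.
#'
#' @param pm A \code{purity_matrix}.
#' @param cm A \code{category_map} whose cluster letters all appear among
#'   \code{pm}'s columns.
#' @return Numeric matrix, classes as rows, categories as columns.
#' @export
category_capture <- function(pm, cm) {
  stopifnot(inherits(pm, "purity_matrix"))
  unknown <- setdiff(unlist(cm), colnames(pm$P))
  if (length(unknown)) {
    stop("unknown cluster letter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- vapply(cm, function(cl)
    rowSums(pm$P[, cl, drop = FALSE]), numeric(nrow(pm$P)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(pm$P),
                                                       names(cm)))
  out
}

#' Average cluster purity
#'
#' The extent to which each cluster contains a single dominant class:
#' \code{ACP = (1/N) * sum_i sum_j n_ij^2 / n_ci}. Empty clusters
#' contribute 0.
#'
#' @param ct A \code{contingency_table}.
#' @return A fraction in (0, 1]; 1 iff every cluster is single-class.
#' @export
acp <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  nc <- ct$cluster_totals
  keep <- nc > 0
  sum(rowSums(ct$n[keep, , drop = FALSE]^2) / nc[keep]) / ct$N
}

#' Average event purity
#'
#' The extent to which each class is concentrated in a single cluster:
#' \code{AEP = (1/N) * sum_j sum_i n_ij^2 / n_ej}.
#'
#' @inheritParams acp
#' @return A fraction in (0, 1]; 1 iff every class is single-cluster.
#' @export
aep <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  ne <- ct$class_totals
  keep <- ne > 0
  sum(colSums(ct$n[, keep, drop = FALSE]^2) / ne[keep]) / ct$N
}

#' Combined average cluster and event purity
#'
#' Combines [acp()] and [aep()]. The default is their literal product; the
#' speaker-diarization literature from which these statistics derive instead
#' combines them as a geometric mean \code{sqrt(ACP * AEP)}, available via
#' \code{method = "geometric"}. Both are kept because the two conventions
#' coexist; see the methods vignette.
#'
#' @inheritParams acp
#' @param method \code{"product"} (default) or \code{"geometric"}.
#' @return A fraction in (0, 1].
#' @export
acep <- function(ct, method = c("product", "geometric")) {
  method <- match.arg(method)
  v <- acp(ct) * aep(ct)
  if (method == "geometric") sqrt(v) else v
}

#' Daily minutes per behaviour category
#'
#' Converts window counts to minutes (\code{count * window_seconds / 60})
#' summed per category, plus each cluster's percentage of total time.
#'
#' @param clusters Cluster letter per window, from one recording
#'   (typically 24 h).
#' @param cm A \code{category_map}.
#' @param window_seconds Window width in seconds (default 10).
#' @return List with \code{category_minutes} (named numeric) and
#'   \code{cluster_percent} (percent of windows per cluster).
#' @export
daily_minutes <- function(clusters, cm, window_seconds = 10) {
  clusters <- as.character(clusters)
  counts <- table(clusters)
  mins <- vapply(cm, function(cl)
    sum(counts[names(counts) %in% cl]) * window_seconds / 60, numeric(1))
  pct <- as.numeric(counts) / length(clusters) * 100
  names(pct) <- names(counts)
  list(category_minutes = mins, cluster_percent = pct)
}

#' Bland-Altman agreement between paired daily-minutes measurements
#'
#' Bias is the mean of the paired differences (model minus criterion); the
#' 95% limits of agreement half-width is 1.96 times the sample standard
#' deviation (n - 1) of those differences.
#'
#' @param model Numeric vector of per-subject minutes from the clustering
#'   model, or a matrix/data.frame with one column per category.
#' @param criterion Matching criterion-method minutes (same shape).
#' @return For vectors, a list of class \code{bland_altman} with
#'   \code{mean_model}, \code{mean_criterion}, \code{bias},
#'   \code{loa_halfwidth} and \code{n}; for matrices, a data.frame with one
#'   row per category.
#' @export
bland_altman <- function(model, criterion) {
  if (is.matrix(model) || is.data.frame(model)) {
    model <- as.matrix(model); criterion <- as.matrix(criterion)
    stopifnot(identical(dim(model), dim(criterion)))
    rows <- lapply(seq_len(ncol(model)), function(j) {
      ba <- bland_altman(model[, j], criterion[, j])
      data.frame(category = colnames(model)[j],
                 mean_model = ba$mean_model,
                 mean_criterion = ba$mean_criterion,
                 bias = ba$bias, loa_halfwidth = ba$loa_halfwidth,
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  if (length(model) != length(criterion)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(model) < 2L) stop("need at least 2 paired measurements",
                               call. = FALSE)
  d <- model - criterion
  structure(list(mean_model = mean(model),
                 mean_criterion = mean(criterion),
                 bias = mean(d),
                 loa_halfwidth = 1.96 * stats::sd(d),
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f, 95%% LoA +/- %.2f\n",
              x$n, x$bias, x$loa_halfwidth))
  cat(sprintf("  means: model %.2f, criterion %.2f\n",
              x$mean_model, x$mean_criterion))
  invisible(x)
}

#' Per-cluster feature profile
#'
#' Mean of each model feature over the windows assigned to each cluster, in
#' raw (denormalised) units, for comparing cluster content across samples.
#' On the training data this equals the denormalised centroids (the Lloyd
#' fixed point).
#'
#' @param model An \code{activity_kmeans} model.
#' @param fm The feature matrix of the assigned windows.
#' @param clusters Cluster letters or indices per row of \code{fm};
#'   defaults to \code{predict(model, fm)}.
#' @param denormalize Report raw units (default TRUE) or normalised units.
#' @return Numeric matrix, clusters as rows (letters), model features as
#'   columns; clusters with no members are all-NA rows.
#' @export
feature_profile <- function(model, fm, clusters = NULL, denormalize = TRUE) {
  stopifnot(inherits(model, "activity_kmeans"))
  if (is.null(clusters)) clusters <- predict(model, fm)
  if (is.numeric(clusters)) clusters <- model$cluster_names[clusters]
  sub <- select_columns(fm, model$feature_names)
  if (isTRUE(attr(sub, "normalized")) && denormalize) {
    rng <- model$norm$max - model$norm$min
    m <- sweep(sweep(unclass(sub), 2, rng, "*"), 2, model$norm$min, "+")
  } else if (!isTRUE(attr(sub, "normalized")) && !denormalize) {
    m <- unclass(minmax_apply(sub, model$norm))
  } else {
    m <- unclass(sub)
  }
  out <- matrix(NA_real_, model$K, length(model$feature_names),
                dimnames = list(model$cluster_names, model$feature_names))
  for (k in model$cluster_names) {
    if (any(clusters == k)) {
      out[k, ] <- colMeans(m[clusters == k, , drop = FALSE])
    }
  }
  out
}

#' Collapse clusters into intensity categories
#'
#' Maps each cluster to one of four behaviour categories (sedentary, slow
#' ambulatory/mixed, brisk ambulatory, running) by its mean per-window ENMO,
#' using fixed cuts in g. The default breaks (0.04, 0.12, 0.20) place the
#' standard 40 mg sedentary boundary first and split slow walking, brisk
#' walking and running intensities; see the methods vignette for how they
#' relate to the synthetic archetypes.
#'
#' @param intensity Named vector of per-cluster mean ENMO (g), e.g. from
#'   [cluster_intensity()]. Clusters with NA intensity (no members) go to
#'   the sedentary category.
#' @param breaks Three increasing cut points in g.
#' @return A \code{category_map} with categories \code{sedentary},
#'   \code{ambulatory_slow}, \code{ambulatory_brisk}, \code{running} (empty
#'   categories are dropped).
#' @export
collapse_by_intensity <- function(intensity, breaks = c(0.04, 0.12, 0.20)) {
  stopifnot(length(breaks) == 3L, !is.unsorted(breaks))
  v <- intensity
  v[is.na(v)] <- 0
  cat_idx <- findInterval(v, breaks) + 1L
  cats <- c("sedentary", "ambulatory_slow", "ambulatory_brisk", "running")
  cm <- lapply(seq_along(cats), function(i) names(v)[cat_idx == i])
  names(cm) <- cats
  category_map(cm[lengths(cm) > 0])
}

#' Published reference purity matrices
#'
#' The reported purity matrices for the wrist-accelerometer clustering
#' model, shipped as data: the combined adult development sample and the
#' three independent validation samples (child laboratory, adult laboratory,
#' adult free-living). Rows are ground-truth classes, columns clusters A-J,
#' entries the percentage of each class's windows in each cluster; the
#' cluster-share row gives percent of total time per cluster.
#'
#' @param sample One of \code{"development"}, \code{"child"},
#'   \code{"adult_lab"}, \code{"free_living"}.
#' @return A \code{purity_matrix}.
#' @export
reference_purity <- function(sample = c("development", "child", "adult_lab",
                                        "free_living")) {
  sample <- match.arg(sample)
  path <- system.file("extdata", paste0("purity_", sample, ".csv"),
                      package = "wristclust", mustWork = TRUE)
  read_purity(path)
}

#' Published daily-minutes agreement summary
#'
#' Reported per-category means, SDs, bias and 95% limits of agreement for
#' total daily minutes from the clustering model versus the thigh-worn
#' posture-monitor criterion (free-living sample, n = 8): sedentary
#' (clusters A-F), standing/stepping (G-H) and high-frequency stepping
#' (I-J).
#'
#' @return data.frame with columns \code{category}, \code{clusters},
#'   \code{model_mean}, \code{model_sd}, \code{criterion_mean},
#'   \code{criterion_sd}, \code{bias}, \code{loa_halfwidth}, \code{n}.
#' @export
reference_daily_minutes <- function() {
  path <- system.file("extdata", "daily_minutes_reference.csv",
                      package = "wristclust", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
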