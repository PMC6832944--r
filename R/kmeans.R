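# squared Euclidean distances, n x K
dist2_matrix <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding (D^2 sampling); assumes the RNG is already seeded
kpp_init <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (k in seq_len(K - 1L) + 1L) {
    i <- if (all(d2 <= 0)) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2)
    centers[k, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[k, ])^2))
  }
  centers
}

# one Lloyd run from given initial centers; returns assignments, centers,
# objective trace
lloyd <- function(x, centers, max_iter) {
  n <- nrow(x)
  K <- nrow(centers)
  assign_prev <- rep(0L, n)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_matrix(x, centers)
    a <- max.col(-d2, ties.method = "first")   # lowest index wins ties
    trace <- c(trace, sum(d2[cbind(seq_len(n), a)]))
    if (identical(a, assign_prev)) {
      return(list(cluster = a, centers = centers, trace = trace, iter = iter))
    }
    assign_prev <- a
    for (k in seq_len(K)) {
      members <- a == k
      if (any(members)) {
        centers[k, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    # empty clusters: reseed to the point currently farthest from its centroid
    empty <- setdiff(seq_len(K), unique(a))
    if (length(empty)) {
      d2 <- dist2_matrix(x, centers)
      resid <- d2[cbind(seq_len(n), a)]
      for (k in empty) {
        far <- which.max(resid)
        centers[k, ] <- x[far, ]
        resid[far] <- 0
      }
    }
  }
  d2 <- dist2_matrix(x, centers)
  a <- max.col(-d2, ties.method = "first")
  trace <- c(trace, sum(d2[cbind(seq_len(n), a)]))
  list(cluster = a, centers = centers, trace = trace, iter = max_iter)
}

#' Fit a portable over-clustered k-means activity model
#'
#' Lloyd's algorithm on a normalised feature matrix: points are assigned to
#' the nearest centroid by squared Euclidean distance (ties to the lowest
#' cluster index) and centroids updated to their members' mean, until the
#' assignment stabilises or \code{max_iter} is reached. Centroids are
#' initialised by k-means++ D-squared sampling (or uniformly at random) and
#' the best of \code{n_restarts} runs by total within-cluster sum of squares
#' is kept. A cluster emptied during iteration is reseeded to the point
#' farthest from its current centroid. The default K = 10 over-clusters the
#' nine expected laboratory activity types so heterogeneous behaviours can
#' split across clusters. Everything needed to reapply the model blind to an
#' independent recording (K, feature list, normalisation parameters,
#' centroids, seed) is carried in the returned object and serialisable with
#' [write_model()].
#'
#' @param x A normalised \code{feature_matrix} (or plain numeric matrix with
#'   column names).
#' @param K Number of clusters (default 10).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param n_restarts Number of independent initialisations (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @param init Initialisation: \code{"kpp"} (k-means++) or \code{"random"}.
#' @param norm Optional \code{minmax_params} to store for blind reapplication.
#' @param window_seconds,trim_seconds Windowing metadata stored in the model.
#' @return An object of class \code{activity_kmeans}: list with elements
#'   \code{K}, \code{centroids} (K x p), \code{feature_names},
#'   \code{norm} (\code{minmax_params} or NULL), \code{cluster} (training
#'   assignments), \code{cluster_names}, \code{tot_withinss},
#'   \code{obj_trace}, \code{seed}, \code{init}, \code{n_restarts},
#'   \code{window_seconds}, \code{trim_seconds}, \code{version}. The file
#'   format carries no timestamps, so refitting and re-serialising with the
#'   same inputs and seed reproduces the file byte for byte.
#' @seealso [predict.activity_kmeans()], [order_clusters()], [write_model()]
#' @export
activity_kmeans <- function(x, K = 10, seed = 1L, n_restarts = 10,
                            max_iter = 300, init = c("kpp", "random"),
                            norm = NULL, window_seconds = 10,
                            trim_seconds = 30) {
  init <- match.arg(init)
  m <- unclass(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  if (nrow(m) < K) {
    stop("fewer rows (", nrow(m), ") than clusters (", K, ")", call. = FALSE)
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers0 <- if (init == "kpp") kpp_init(m, K) else
      m[sample.int(nrow(m), K), , drop = FALSE]
    run <- lloyd(m, centers0, max_iter)
    obj <- run$trace[length(run$trace)]
    if (is.null(best) || obj < best$obj) {
      best <- list(obj = obj, run = run)
    }
  }
  run <- best$run
  centroids <- run$centers
  colnames(centroids) <- colnames(m)
  structure(list(K = as.integer(K),
                 centroids = centroids,
                 feature_names = colnames(m),
                 norm = norm,
                 cluster = run$cluster,
                 cluster_names = as.character(seq_len(K)),
                 tot_withinss = best$obj,
                 obj_trace = run$trace,
                 seed = as.integer(seed),
                 init = init,
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter),
                 window_seconds = window_seconds,
                 trim_seconds = trim_seconds,
                 version = "1.0"),
            class = "activity_kmeans")
}

#' Assign windows to the stored centroids
#'
#' Nearest-centroid assignment by squared Euclidean distance, ties broken by
#' the lowest cluster index. This is the blind-reapplication step: the model
#' is never refitted on new data.
#'
#' @param fm A \code{feature_matrix} whose columns match the model's feature
#'   list. If unnormalised and the model stores normalisation parameters, it
#'   is normalised first.
#' @param model An \code{activity_kmeans} model.
#' @return Integer cluster index per row (positions in the model's current
#'   cluster order).
#' @export
assign_clusters <- function(fm, model) {
  stopifnot(inherits(model, "activity_kmeans"))
  m <- unclass(fm)
  if (is.null(colnames(m)) ||
      !all(model$feature_names %in% colnames(m))) {
    stop("feature columns do not match the model's feature list",
         call. = FALSE)
  }
  if (inherits(fm, "feature_matrix") && !isTRUE(attr(fm, "normalized"))) {
    if (is.null(model$norm)) {
      stop("feature matrix is unnormalised and the model stores no ",
           "normalization parameters", call. = FALSE)
    }
    fm <- minmax_apply(select_columns(fm, model$norm$features), model$norm)
    m <- unclass(fm)
  }
  m <- m[, model$feature_names, drop = FALSE]
  d2 <- dist2_matrix(m, model$centroids)
  max.col(-d2, ties.method = "first")
}

#' @describeIn activity_kmeans Predict cluster membership of new windows;
#'   returns cluster letters (see [order_clusters()]) as a character vector.
#' @param object An \code{activity_kmeans} model.
#' @param newdata A \code{feature_matrix}; defaults to returning the training
#'   assignments.
#' @param type \code{"name"} for cluster letters, \code{"index"} for integer
#'   indices.
#' @param ... Unused.
#' @export
predict.activity_kmeans <- function(object, newdata = NULL,
                                    type = c("name", "index"), ...) {
  type <- match.arg(type)
  idx <- if (is.null(newdata)) object$cluster else
    assign_clusters(newdata, object)
  if (type == "index") idx else object$cluster_names[idx]
}

#' @export
fitted.activity_kmeans <- function(object, ...) {
  object$cluster_names[object$cluster]
}

#' @export
coef.activity_kmeans <- function(object, denormalize = FALSE, ...) {
  cc <- object$centroids
  if (denormalize) {
    if (is.null(object$norm)) stop("model stores no normalization parameters",
                                   call. = FALSE)
    rng <- object$norm$max - object$norm$min
    cc <- sweep(sweep(cc, 2, rng, "*"), 2, object$norm$min, "+")
  }
  rownames(cc) <- object$cluster_names
  cc
}

#' @export
print.activity_kmeans <- function(x, ...) {
  cat(sprintf("activity_kmeans: K = %d clusters over %d features\n",
              x$K, length(x$feature_names)))
  cat(sprintf("  init: %s, restarts: %d, seed: %d\n",
              x$init, x$n_restarts, x$seed))
  cat(sprintf("  total within-cluster SS: %.6g (converged in %d iterations)\n",
              x$tot_withinss, length(x$obj_trace)))
  cat("  clusters:", paste(x$cluster_names, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.activity_kmeans <- function(object, ...) {
  sizes <- tabulate(object$cluster, nbins = object$K)
  out <- data.frame(cluster = object$cluster_names, size = sizes,
                    stringsAsFactors = FALSE)
  cat(sprintf("Portable k-means activity model (K = %d, %d features)\n",
              object$K, length(object$feature_names)))
  cat(sprintf("Total within-cluster SS: %.6g\n", object$tot_withinss))
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
plot.activity_kmeans <- function(x, features = NULL, ...) {
  cc <- x$centroids
  if (!is.null(features)) cc <- cc[, features, drop = FALSE]
  graphics::matplot(t(cc), type = "b", pch = 1, lty = 1,
                    xlab = "feature", ylab = "centroid value (normalized)",
                    xaxt = "n", ...)
  graphics::axis(1, at = seq_len(ncol(cc)), labels = colnames(cc),
                 las = 2, cex.axis = 0.6)
  graphics::legend("topright", legend = x$cluster_names,
                   col = seq_len(x$K), lty = 1, cex = 0.7)
  invisible(x)
}

#' Name clusters by ascending activity intensity
#'
#' Renames clusters A, B, C, ... in ascending order of the mean per-window
#' ENMO of their member windows, so that the most sedentary cluster is
#' always A and the most intense the last letter, making purity matrices
#' comparable across runs. Ties keep the original index order. Centroids,
#' training assignments and cluster names are permuted consistently.
#'
#' @param model An \code{activity_kmeans} model.
#' @param fm The feature matrix the model was fitted on, in raw units, with
#'   an \code{enmo_mean} column.
#' @param clusters Optional integer assignments of \code{fm}'s rows
#'   (defaults to the training assignments).
#' @return The model with reordered centroids and \code{cluster_names}
#'   A..LETTERS[K]; attribute \code{perm} gives old index -> new position.
#' @export
order_clusters <- function(model, fm, clusters = NULL) {
  stopifnot(inherits(model, "activity_kmeans"))
  if (model$K > 26L) stop("letter naming supports at most 26 clusters",
                          call. = FALSE)
  if (is.null(clusters)) clusters <- model$cluster
  if (!"enmo_mean" %in% colnames(fm)) {
    stop("feature matrix must carry an enmo_mean column (raw units)",
         call. = FALSE)
  }
  e <- unclass(fm)[, "enmo_mean"]
  if (isTRUE(attr(fm, "normalized"))) {
    if (is.null(model$norm)) stop("cannot denormalize enmo_mean",
                                  call. = FALSE)
    i <- match("enmo_mean", model$norm$features)
    e <- e * (model$norm$max[i] - model$norm$min[i]) + model$norm$min[i]
  }
  means <- vapply(seq_len(model$K), function(k) {
    if (any(clusters == k)) mean(e[clusters == k]) else Inf
  }, numeric(1))
  ord <- order(means, seq_len(model$K))   # stable: ties by original index
  perm <- match(seq_len(model$K), ord)    # old index -> new position
  model$centroids <- model$centroids[ord, , drop = FALSE]
  model$cluster <- perm[model$cluster]
  model$cluster_names <- LETTERS[seq_len(model$K)]
  attr(model, "perm") <- perm
  model
}

#' Mean cluster intensity
#'
#' Denormalised mean per-window ENMO (g) of each cluster's member windows;
#' the quantity [order_clusters()] sorts on and the basis for collapsing
#' clusters into intensity categories.
#'
#' @inheritParams order_clusters
#' @return Named numeric vector, one mean ENMO value (g) per cluster.
#' @export
cluster_intensity <- function(model, fm, clusters = NULL) {
  if (is.null(clusters)) clusters <- model$cluster
  e <- unclass(fm)[, "enmo_mean"]
  if (isTRUE(attr(fm, "normalized"))) {
    i <- match("enmo_mean", model$norm$features)
    e <- e * (model$norm$max[i] - model$norm$min[i]) + model$norm$min[i]
  }
  out <- vapply(seq_len(model$K), function(k) {
    if (any(clusters == k)) mean(e[clusters == k]) else NA_real_
  }, numeric(1))
  names(out) <- model$cluster_names
  out
}

#' Fit the full portable model from a raw feature matrix
#'
#' Convenience wrapper over the pipeline: select the feature set (the
#' canonical 24 by default, or correlation-based selection when
#' \code{features = "select"}), fit MinMax normalisation, run
#' [activity_kmeans()], and name clusters by ascending intensity.
#'
#' @param fm A raw-unit \code{feature_matrix} containing the full candidate
#'   feature set (labels required only for \code{features = "select"}).
#' @param K,seed,n_restarts,max_iter,init Passed to [activity_kmeans()].
#' @param features \code{"canonical"} (default) for the fixed 24-feature
#'   specification, \code{"select"} to re-run correlation selection, or a
#'   \code{feature_spec}.
#' @param window_seconds,trim_seconds Windowing metadata stored in the model.
#' @return An intensity-ordered \code{activity_kmeans} model carrying the
#'   normalisation parameters.
#' @export
fit_portable_model <- function(fm, K = 10, seed = 1L, n_restarts = 10,
                               max_iter = 300, init = "kpp",
                               features = c("canonical", "select"),
                               window_seconds = 10, trim_seconds = 30) {
  spec <- if (inherits(features, "feature_spec")) features
  else switch(match.arg(features),
              canonical = canonical_feature_spec(),
              select = select_features(fm))
  sub <- select_columns(fm, spec$names)
  norm <- minmax_fit(sub)
  normed <- minmax_apply(sub, norm)
  model <- activity_kmeans(normed, K = K, seed = seed,
                           n_restarts = n_restarts, max_iter = max_iter,
                           init = init, norm = norm,
                           window_seconds = window_seconds,
                           trim_seconds = trim_seconds)
  order_clusters(model, fm)
}

#' Serialise a portable model to JSON
#'
#' Self-describing JSON with full-precision decimal floats, so the model can
#' be stored, versioned and reapplied bit-identically on any machine --
#' unlike language-specific binary pickles.
#'
#' @param model An \code{activity_kmeans} model.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "activity_kmeans"))
  obj <- list(version = model$version,
              K = model$K,
              feature_names = model$feature_names,
              norm_min = if (!is.null(model$norm))
                unname(model$norm$min) else NULL,
              norm_max = if (!is.null(model$norm))
                unname(model$norm$max) else NULL,
              centroids = unname(lapply(seq_len(model$K), function(i)
                unname(model$centroids[i, ]))),
              cluster_names = model$cluster_names,
              seed = model$seed,
              init = model$init,
              n_restarts = model$n_restarts,
              max_iter = model$max_iter,
              window_seconds = model$window_seconds,
              trim_seconds = model$trim_seconds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a portable model from JSON
#'
#' Validates the schema (required fields, centroid dimensionality, K) and
#' reconstructs the \code{activity_kmeans} object.
#'
#' @param path Path to a file written by [write_model()].
#' @return An \code{activity_kmeans} model (without training assignments).
#' @export
read_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("model file is not valid JSON: ",
                                           conditionMessage(e), call. = FALSE))
  required <- c("version", "K", "feature_names", "centroids", "seed", "init")
  for (f in required) {
    if (is.null(obj[[f]])) stop("model file missing field '", f, "'",
                                call. = FALSE)
  }
  K <- as.integer(obj$K)
  if (K < 1L) stop("model field 'K' must be >= 1", call. = FALSE)
  cc <- obj$centroids
  if (is.list(cc)) cc <- do.call(rbind, cc)
  cc <- matrix(as.numeric(cc), nrow = K)
  if (ncol(cc) != length(obj$feature_names)) {
    stop("model field 'centroids' dimensionality does not match ",
         "'feature_names'", call. = FALSE)
  }
  colnames(cc) <- obj$feature_names
  norm <- NULL
  if (!is.null(obj$norm_min)) {
    if (length(obj$norm_min) != length(obj$feature_names) ||
        length(obj$norm_max) != length(obj$feature_names)) {
      stop("model field 'norm_min'/'norm_max' length mismatch", call. = FALSE)
    }
    norm <- structure(list(
      min = stats::setNames(as.numeric(obj$norm_min), obj$feature_names),
      max = stats::setNames(as.numeric(obj$norm_max), obj$feature_names),
      features = obj$feature_names), class = "minmax_params")
  }
  structure(list(K = K,
                 centroids = cc,
                 feature_names = obj$feature_names,
                 norm = norm,
                 cluster = NULL,
                 cluster_names = if (!is.null(obj$cluster_names))
                   obj$cluster_names else as.character(seq_len(K)),
                 tot_withinss = NA_real_,
                 obj_trace = numeric(0),
                 seed = as.integer(obj$seed),
                 init = obj$init,
                 n_restarts = if (!is.null(obj$n_restarts))
                   as.integer(obj$n_restarts) else NA_integer_,
                 max_iter = if (!is.null(obj$max_iter))
                   as.integer(obj$max_iter) else NA_integer_,
                 window_seconds = obj$window_seconds,
                 trim_seconds = obj$trim_seconds,
                 version = obj$version),
            class = "activity_kmeans")
}
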