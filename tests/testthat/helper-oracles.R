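# Independent oracles used by the property and acceptance tests. These stay
# deliberately naive (explicit loops, exhaustive enumeration) and share no
# code with the package internals they check.

# build a contingency_table from a counts matrix by expanding it back into
# per-window label/cluster vectors
ct_from <- function(m) {
  labels <- rep(rep(colnames(m), each = nrow(m)), as.vector(m))
  clusters <- rep(rep(rownames(m), ncol(m)), as.vector(m))
  contingency(labels, clusters)
}

# average cluster purity by explicit double loop over a counts matrix
# (clusters as rows, classes as columns)
acp_oracle <- function(n) {
  N <- sum(n)
  total <- 0
  for (i in seq_len(nrow(n))) {
    nci <- sum(n[i, ])
    if (nci == 0) next
    for (j in seq_len(ncol(n))) {
      total <- total + n[i, j]^2 / nci
    }
  }
  total / N
}

aep_oracle <- function(n) {
  N <- sum(n)
  total <- 0
  for (j in seq_len(ncol(n))) {
    nej <- sum(n[, j])
    if (nej == 0) next
    for (i in seq_len(nrow(n))) {
      total <- total + n[i, j]^2 / nej
    }
  }
  total / N
}

# exhaustive optimum of 2-means on a tiny point set: minimum over all
# assignments of points to two non-empty groups of the total within-group
# sum of squared distances to the group mean
brute_2means <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    wss <- 0
    for (grp in list(x[g, , drop = FALSE], x[!g, , drop = FALSE])) {
      mu <- colMeans(grp)
      wss <- wss + sum(sweep(grp, 2, mu)^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# fit the full pipeline on one simulated laboratory protocol and return the
# pieces the recovery tests need
run_sim_pipeline <- function(seed, fs = 100, K = 10) {
  sim <- simulate_recording(default_protocol(seed = seed, fs = fs))
  fm <- extract_features(sim$recording, sim$bouts)
  model <- fit_portable_model(fm, K = K, seed = seed)
  cl <- predict(model, fm)
  list(sim = sim, fm = fm, model = model, clusters = cl,
       labels = attr(fm, "labels"))
}
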