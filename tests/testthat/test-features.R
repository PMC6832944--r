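test_that("magnitude metrics follow their closed forms", {
  expect_equal(smv(0.6, 0.8, 0), 1.0)
  expect_equal(smv(0, 0, 0), 0)
  expect_equal(smv(1, 1, 1), sqrt(3))
  expect_equal(enmo(0, 0, 1), 0)          # resting gravity
  expect_equal(enmo(0, 0, 2), 1)
  expect_equal(enmo(0.3, 0, 0.4), 0)      # SMV 0.5, flattened to zero
})

test_that("ENMO is zero below 1 g and non-decreasing in magnitude", {
  set.seed(1)
  v <- matrix(rnorm(300), ncol = 3)
  s <- smv(v[, 1], v[, 2], v[, 3])
  e <- enmo(v[, 1], v[, 2], v[, 3])
  expect_true(all(e[s <= 1] == 0))
  ord <- order(s)
  expect_true(all(diff(e[ord]) >= 0))
})

test_that("orientation angles match hand-derived values and resolve the
           degenerate denominator as +/-90", {
  a <- orientation_angles(0, 0, 1)
  expect_equal(c(a$angle_x, a$angle_y, a$angle_z), c(0, 0, 90))
  a <- orientation_angles(1, 0, 0)
  expect_equal(c(a$angle_x, a$angle_y, a$angle_z), c(90, 0, 0))
  a <- orientation_angles(1, 1, sqrt(2))
  expect_equal(a$angle_z, 45)
  a <- orientation_angles(0, 0, -1)
  expect_equal(a$angle_z, -90)
  expect_error(orientation_angles(0, 0, 0), "zero")
})

test_that("orientation angles are scale-invariant and their sines recover
           unit-vector components on a brute-force grid", {
  grid <- expand.grid(x = seq(-1, 1, 0.25), y = seq(-1, 1, 0.25),
                      z = seq(-1, 1, 0.25))
  grid <- grid[rowSums(grid^2) > 0, ]
  u <- grid / sqrt(rowSums(grid^2))
  a <- orientation_angles(grid$x, grid$y, grid$z)
  a4 <- orientation_angles(4 * grid$x, 4 * grid$y, 4 * grid$z)
  expect_equal(a, a4)
  expect_equal(sin(a$angle_x * pi / 180), u$x, tolerance = 1e-12)
  expect_equal(sin(a$angle_y * pi / 180), u$y, tolerance = 1e-12)
  expect_equal(sin(a$angle_z * pi / 180), u$z, tolerance = 1e-12)
})

test_that("time-domain window statistics match hand computations", {
  w <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1), ncol = 3)
  f <- time_features(w)
  expect_equal(unname(f[c("acc_z_sd", "acc_z_var", "acc_x_sd")]), c(0, 0, 0))
  expect_equal(unname(f[c("enmo_mean", "enmo_max", "enmo_median")]),
               c(0, 0, 0))
  expect_equal(unname(f[c("angle_z_min", "angle_z_max", "angle_z_mean",
                          "angle_z_median", "angle_z_sd")]),
               c(90, 90, 90, 90, 0))

  w <- cbind(x = rep(0.1, 4), y = rep(0.1, 4), z = c(0, 1, 0, 1))
  f <- time_features(w)
  expect_equal(unname(f["acc_z_mean"]), 0.5)
  expect_equal(unname(f["acc_z_sd"]), 0.5)   # population convention
  expect_equal(unname(f["acc_z_var"]), 0.25)

  # sinusoid of amplitude a: max - min recovers 2a (2.5 Hz at 100 Hz puts
  # sample points exactly on the extrema)
  t <- (0:999) / 100
  a <- 0.37
  w <- cbind(x = 0, y = 0, z = 1 + a * sin(2 * pi * 2.5 * t))
  f <- time_features(w)
  expect_equal(unname(f["acc_z_max"] - f["acc_z_min"]), 2 * a)
})

test_that("time features are permutation-invariant but frequency features
           are not", {
  set.seed(42)
  t <- (0:999) / 100
  w <- cbind(x = rnorm(1000, 0, 0.1), y = rnorm(1000, 0, 0.1),
             z = 1 + 0.4 * sin(2 * pi * 2 * t))
  perm <- sample(nrow(w))
  expect_equal(time_features(w[perm, ]), time_features(w))
  f1 <- frequency_features(w, 100)
  f2 <- frequency_features(w[perm, ], 100)
  expect_false(isTRUE(all.equal(f1, f2)))
})

test_that("dominant frequency finds the driving tone", {
  t <- (0:999) / 100
  w <- cbind(x = 0, y = 0, z = 1 + 0.3 * sin(2 * pi * 2 * t))
  f <- frequency_features(w, 100)
  expect_lt(abs(f[["dominant_freq"]] - 2.0), 0.1 + 1e-12)
  expect_gt(f[["dominant_power"]], 0)

  # larger-amplitude tone wins
  w <- cbind(x = 0, y = 0,
             z = 1 + 0.1 * sin(2 * pi * 1 * t) + 0.3 * sin(2 * pi * 3 * t))
  f <- frequency_features(w, 100)
  expect_equal(f[["dominant_freq"]], 3.0, tolerance = 0.1)

  # constant window reports (0, 0) by convention
  w <- cbind(x = 0, y = 0, z = rep(1, 1000))
  expect_equal(unname(frequency_features(w, 100)), c(0, 0))
})

test_that("correlation-based selection keeps informative features and
           defines constant features as uncorrelated", {
  set.seed(7)
  n <- 5000
  enc <- default_class_encoding()
  labels <- sample(enc, n, replace = TRUE)
  cls <- match(labels, enc) - 1
  m <- cbind(perfect = cls,
             noise = rnorm(n),
             flat = rep(2, n))
  fm <- feature_matrix(m, labels = labels)
  spec <- select_features(fm)
  expect_true("perfect" %in% spec$names)
  expect_false("noise" %in% spec$names)   # |r| < 0.12 w.h.p. at n = 5000
  expect_false("flat" %in% spec$names)
  r <- attr(spec, "all_loadings")
  expect_equal(unname(r["perfect"]), 1)
  expect_equal(unname(r["flat"]), 0)
})

test_that("the canonical specification lists 24 uniquely named features", {
  spec <- canonical_feature_spec()
  expect_length(spec$names, 24L)
  expect_false(anyDuplicated(spec$names) > 0)
  expect_true(all(spec$names %in% all_feature_names()))
  expect_equal(unname(spec$loadings["acc_z_sd"]), 0.440)
  expect_equal(unname(spec$loadings["angle_z_sd"]), 0.526)
})

test_that("MinMax normalisation maps training data to [0,1] and leaves new
           data unclipped", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 1, 1))
  fm <- feature_matrix(m)
  p <- minmax_fit(fm)
  out <- minmax_apply(fm, p)
  expect_equal(unname(unclass(out)[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(unclass(out)[, "b"]), c(0, 0, 0))  # constant column

  new <- feature_matrix(cbind(a = 10, b = 5))
  expect_equal(unname(unclass(minmax_apply(new, p))[, "a"]), 2)  # unclipped

  expect_error(minmax_apply(feature_matrix(cbind(c = 1)), p), "match")

  set.seed(3)
  fm <- feature_matrix(matrix(rnorm(200), 50, 4,
                              dimnames = list(NULL, letters[1:4])))
  z <- unclass(minmax_apply(fm, minmax_fit(fm)))
  expect_equal(unname(apply(z, 2, min)), rep(0, 4))
  expect_equal(unname(apply(z, 2, max)), rep(1, 4))
})

test_that("feature matrices survive a text round-trip with labels", {
  sim <- simulate_recording(default_protocol(seed = 9))
  fm <- extract_features(sim$recording, sim$bouts)
  path <- tempfile(fileext = ".csv")
  write_features(fm, path)
  back <- read_features(path)
  expect_equal(colnames(back), colnames(fm))
  expect_equal(unclass(back), unclass(fm), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(attr(back, "labels"), attr(fm, "labels"))
})

test_that("angle dispersion features are wrist-agnostic: X/Z mirroring with
           time reversal leaves them unchanged on a simulated swing", {
  t <- (0:999) / 100
  set.seed(11)
  w <- cbind(x = 0.3 * sin(2 * pi * 2 * t),
             y = -1 + 0.4 * sin(2 * pi * 2 * t + 1),
             z = 0.2 * cos(2 * pi * 2 * t))
  mirrored <- cbind(x = -w[rev(seq_len(nrow(w))), "x"],
                    y = w[rev(seq_len(nrow(w))), "y"],
                    z = -w[rev(seq_len(nrow(w))), "z"])
  f1 <- time_features(w)
  f2 <- time_features(mirrored)
  sds <- c("angle_x_sd", "angle_y_sd", "angle_z_sd")
  expect_equal(f1[sds], f2[sds])
})
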