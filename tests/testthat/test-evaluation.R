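test_that("contingency counts are exact and marginals consistent", {
  ct <- contingency(c("a", "a", "b"), c(1, 1, 2))
  expect_equal(unname(ct$n), matrix(c(2, 0, 0, 1), 2))
  expect_equal(ct$N, 3)
  expect_error(contingency(character(0), integer(0)), "empty")
  expect_error(contingency(c("a", "b"), 1), "equal length")
  expect_error(contingency(c("a", NA), c(1, 2)), "missing")

  set.seed(6)
  for (i in 1:10) {
    lab <- sample(letters[1:4], 200, replace = TRUE)
    cl <- sample(LETTERS[1:6], 200, replace = TRUE)
    ct <- contingency(lab, cl)
    expect_equal(sum(ct$cluster_totals), ct$N)
    expect_equal(sum(ct$class_totals), ct$N)
    expect_equal(ct$N, 200)
  }
})

test_that("purity rows are class percentages summing to 100", {
  ct <- ct_from(matrix(c(3, 0, 0, 5), 2, dimnames = list(c("X", "Y"),
                                                         c("a", "b"))))
  pm <- purity_matrix(ct)
  expect_equal(unname(pm$P), matrix(c(100, 0, 0, 100), 2))

  ct <- ct_from(matrix(c(5, 5), 1, dimnames = list("X", c("a", "b"))))
  pm <- purity_matrix(ct)
  expect_equal(unname(pm$P[, "X"]), c(100, 100))
  expect_equal(unname(pm$cluster_share), 100)

  set.seed(2)
  lab <- sample(letters[1:5], 500, replace = TRUE)
  cl <- sample(LETTERS[1:10], 500, replace = TRUE)
  pm <- purity_matrix(contingency(lab, cl))
  expect_equal(unname(rowSums(pm$P)), rep(100, 5))
  expect_equal(sum(pm$cluster_share), 100)
})

test_that("category capture sums the right purity columns and validates
           letters", {
  pm <- new_purity_matrix(matrix(c(60, 10, 30, 20, 10, 70), 2, byrow = TRUE,
                                 dimnames = list(c("sit", "walk"),
                                                 c("A", "B", "C"))))
  cap <- category_capture(pm, category_map(sed = c("A", "B"), amb = "C"))
  expect_equal(unname(cap["sit", ]), c(70, 30))
  expect_equal(unname(cap["walk", ]), c(30, 70))
  expect_error(category_capture(pm, category_map(sed = "Z")), "unknown")

  # capture over a full cluster partition recovers each row total
  full <- category_capture(pm, category_map(all = c("A", "B", "C")))
  expect_equal(unname(full[, "all"]), c(100, 100))

  for (s in c("development", "child", "adult_lab", "free_living")) {
    rp <- reference_purity(s)
    full <- category_capture(rp, category_map(all = colnames(rp$P)))
    expect_true(all(abs(full[, "all"] - 100) <= 0.2))  # rounded inputs
  }
})

test_that("category maps reject overlapping categories", {
  expect_error(category_map(a = c("A", "B"), b = c("B", "C")), "disjoint")
})

test_that("ACP and AEP follow the closed forms and the brute-force oracle", {
  # diagonal: every cluster pure, every class concentrated
  ct <- ct_from(diag_ct <- matrix(c(4, 0, 0, 6), 2,
                                  dimnames = list(c("1", "2"),
                                                  c("a", "b"))))
  expect_equal(acp(ct), 1)
  expect_equal(aep(ct), 1)
  expect_equal(acep(ct), 1)

  ct <- ct_from(matrix(c(5, 5), 1, dimnames = list("1", c("a", "b"))))
  expect_equal(acp(ct), 0.5)
  expect_equal(aep(ct), 1.0)

  ct <- ct_from(matrix(c(4, 1, 1, 4), 2, dimnames = list(c("1", "2"),
                                                         c("a", "b"))))
  expect_equal(acp(ct), 0.68)
  expect_equal(aep(ct), 0.68)
  expect_equal(acep(ct), 0.68^2)
  expect_equal(acep(ct, "geometric"), 0.68)

  set.seed(10)
  for (i in 1:25) {
    m <- matrix(rpois(12, 5), 3, 4,
                dimnames = list(as.character(1:3), letters[1:4]))
    m[1, 1] <- m[1, 1] + 1    # guarantee N > 0
    ct <- ct_from(m)
    expect_equal(acp(ct), acp_oracle(ct$n), tolerance = 1e-12)
    expect_equal(aep(ct), aep_oracle(ct$n), tolerance = 1e-12)
    expect_true(acp(ct) > 0 && acp(ct) <= 1)
    expect_true(aep(ct) > 0 && aep(ct) <= 1)
  }
})

test_that("purity statistics are invariant to relabelling and to uniform
           scaling of the counts", {
  set.seed(12)
  m <- matrix(rpois(12, 6) + 1, 3, 4,
              dimnames = list(c("1", "2", "3"), letters[1:4]))
  ct <- ct_from(m)
  m2 <- m[c(3, 1, 2), c(2, 4, 1, 3)]
  ct2 <- ct_from(m2)
  expect_equal(acp(ct2), acp(ct))
  expect_equal(aep(ct2), aep(ct))
  ct3 <- ct_from(m * 3)
  expect_equal(acp(ct3), acp(ct))
  expect_equal(aep(ct3), aep(ct))
})

test_that("daily minutes convert window counts per category and percentages
           sum to 100", {
  cl <- rep("A", 8640)                    # a full day of 10-s windows
  dm <- daily_minutes(cl, category_map(sedentary = "A", running = "J"))
  expect_equal(unname(dm$category_minutes["sedentary"]), 1440)
  expect_equal(unname(dm$category_minutes["running"]), 0)
  set.seed(4)
  cl <- sample(LETTERS[1:10], 1000, replace = TRUE)
  dm <- daily_minutes(cl, default_category_map())
  expect_equal(sum(dm$cluster_percent), 100)
  expect_equal(sum(dm$category_minutes), 1000 * 10 / 60)
})

test_that("Bland-Altman recovers a known offset and noise level", {
  x <- c(100, 200, 300)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_halfwidth, 0)
  expect_error(bland_altman(1, 2), "at least 2")
  expect_error(bland_altman(1:3, 1:4), "equal length")

  set.seed(15)
  n <- 20000
  crit <- runif(n, 500, 1500)
  model <- crit + 5 + rnorm(n, 0, 3)
  ba <- bland_altman(model, crit)
  expect_equal(ba$bias, 5, tolerance = 0.05)
  expect_equal(ba$loa_halfwidth, 1.96 * 3, tolerance = 0.1)
})

test_that("feature profiles of training data equal the denormalised
           centroids", {
  sim <- simulate_recording(default_protocol(seed = 19))
  fm <- extract_features(sim$recording, sim$bouts)
  model <- fit_portable_model(fm, seed = 19)
  prof <- feature_profile(model, fm, clusters = fitted(model))
  cc <- coef(model, denormalize = TRUE)
  populated <- !is.na(prof[, 1])
  expect_equal(prof[populated, ], cc[populated, ], tolerance = 1e-9)

  # single-cluster data: profile is just the column means
  sub <- select_columns(fm, model$feature_names)
  one <- feature_profile(model, sub,
                         clusters = rep(model$cluster_names[1], nrow(sub)))
  expect_equal(one[1, ], colMeans(unclass(sub)))
})

test_that("reference purity matrices load with the published layout", {
  rp <- reference_purity("development")
  expect_equal(colnames(rp$P), LETTERS[1:10])
  expect_equal(nrow(rp$P), 9)
  expect_equal(rp$P["running", "J"], 95.7)
  expect_equal(unname(rp$cluster_share["I"]), 24.2)
  ref <- reference_daily_minutes()
  expect_equal(nrow(ref), 3)
  expect_equal(ref$model_mean[1], 1024.90)
})

test_that("intensity collapse maps clusters through the fixed ENMO cuts", {
  intens <- c(A = 0.01, B = 0.03, C = 0.05, D = 0.15, E = 0.30, F = NA)
  cm <- collapse_by_intensity(intens)
  expect_equal(cm$sedentary, c("A", "B", "F"))
  expect_equal(cm$ambulatory_slow, "C")
  expect_equal(cm$ambulatory_brisk, "D")
  expect_equal(cm$running, "E")
})
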