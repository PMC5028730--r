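test_that("main frequency and phase match a from-definition DFT oracle", {
  # frozen analytic case: sin at 1 Hz sampled 2 s at 30 Hz lands on bin 2
  t <- (0:59) / 30
  fp <- main_frequency_and_phase(sin(2 * pi * 1.0 * t), 30)
  expect_equal(fp[["freq"]], 1.0)
  expect_equal(fp[["phase"]], -pi / 2, tolerance = 1e-9)

  # random signals of assorted lengths against the dense DFT oracle
  set.seed(21)
  for (n in c(5L, 17L, 64L, 101L, 256L)) {
    x <- rnorm(n) + sin(2 * pi * runif(1, 0.5, 5) * (0:(n - 1)) / 30)
    expect_equal(main_frequency_and_phase(x, 30), oracle_main_freq(x, 30),
                 tolerance = 1e-9)
  }
})

test_that("the dominant component wins and degenerate signals map to (0, 0)", {
  t <- (0:119) / 30
  x <- 2 * sin(2 * pi * 1.0 * t) + 1 * sin(2 * pi * 3.0 * t)
  expect_equal(main_frequency_and_phase(x, 30)[["freq"]], 1.0)
  expect_identical(main_frequency_and_phase(rep(0, 50), 30),
                   c(freq = 0, phase = 0))
  expect_identical(main_frequency_and_phase(rep(4.2, 50), 30),
                   c(freq = 0, phase = 0))
  expect_error(main_frequency_and_phase(1.0, 30), "at least 2")
})

test_that("frequency and phase are invariant to positive amplitude scaling", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(80) + sin(2 * pi * 1.2 * (0:79) / 30 + runif(1, -pi, pi))
    a <- main_frequency_and_phase(x, 30)
    b <- main_frequency_and_phase(runif(1, 0.1, 50) * x, 30)
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("a pure sinusoid is recovered within one FFT bin at any length", {
  set.seed(41)
  for (i in 1:8) {
    n <- sample(40:250, 1)
    f <- runif(1, 0.6, 3)
    x <- sin(2 * pi * f * (0:(n - 1)) / 30)
    got <- main_frequency_and_phase(x, 30)[["freq"]]
    expect_lte(abs(got - f), 30 / n)
  }
})

test_that("segment features carry 42 frequencies, 42 phases and orientation", {
  z <- seq(7, by = -1 / 30, length.out = 120)
  m <- matrix_from_track(z)
  m$values[, 4:42] <- sin(2 * pi * 1.1 * (seq_len(nrow(m$values)) - 1) / 30)
  seg <- segment_record(m)[[1]]
  sf <- segment_features(seg)
  expect_length(sf$main_freqs, 42L)
  expect_length(sf$phases, 42L)
  expect_identical(sf$orientation, "front")
  expect_true(all(sf$main_freqs >= 0 & sf$main_freqs <= 15))
  expect_true(all(sf$phases > -pi & sf$phases <= pi))
  # determinism
  expect_identical(sf, segment_features(seg))
})

test_that("record aggregation produces the fixed 168-value layout", {
  f1 <- structure(list(main_freqs = setNames(rep(1, 42), motion_columns()),
                       phases = setNames(rep(0.5, 42), motion_columns()),
                       orientation = "front"), class = "segment_features")
  b1 <- structure(list(main_freqs = setNames(rep(2, 42), motion_columns()),
                       phases = setNames(rep(-0.5, 42), motion_columns()),
                       orientation = "back"), class = "segment_features")
  fv <- aggregate_record(list(f1, b1))
  expect_length(fv, 168L)
  expect_identical(names(fv), record_feature_names())
  expect_equal(unname(fv[1:42]), rep(1, 42))
  expect_equal(unname(fv[43:84]), rep(0.5, 42))
  expect_equal(unname(fv[85:126]), rep(2, 42))
  expect_equal(unname(fv[127:168]), rep(-0.5, 42))
  # averaging identical segments is idempotent
  fv2 <- aggregate_record(list(f1, f1, b1))
  expect_equal(as.numeric(fv2), as.numeric(fv))
  # a missing orientation is a typed error naming the record
  expect_error(aggregate_record(list(f1, f1), record_id = "S9/angry/K1"),
               class = "emogait_missing_orientation")
  expect_error(aggregate_record(list(f1, f1), record_id = "S9/angry/K1"),
               "S9/angry/K1")
})

test_that("z-score normalization standardizes columns and zeroes constants", {
  set.seed(51)
  vals <- cbind(a = c(1, 3), b = rnorm(2), const = c(7, 7))
  tab <- feature_table(vals, data.frame(subject_id = c("S1", "S2"),
                                        condition = "x", camera_id = "K1"))
  zs <- zscore_fit(tab)
  z <- zscore_apply(tab, zs)
  expect_equal(unname(z$values[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_true(all(z$values[, "const"] == 0))

  big <- feature_table(matrix(rnorm(300), 20, 15),
                       data.frame(subject_id = sprintf("S%d", 1:20),
                                  condition = "x", camera_id = "K1"))
  bz <- zscore_apply(big, zscore_fit(big))
  expect_true(all(abs(colMeans(bz$values)) < 1e-9))
  expect_true(all(abs(apply(bz$values, 2, sd) - 1) < 1e-9))
  expect_error(zscore_fit(feature_table(matrix(1, 1, 2),
                                        data.frame(subject_id = "S1",
                                                   condition = "x",
                                                   camera_id = "K1"))),
               "at least 2")
})

test_that("PCA matches the covariance eigendecomposition oracle", {
  set.seed(61)
  x <- matrix(rnorm(20 * 168), 20, 168)
  colnames(x) <- record_feature_names()
  tab <- feature_table(x, data.frame(subject_id = sprintf("S%d", 1:20),
                                     condition = "x", camera_id = "K1"))
  tab <- zscore_apply(tab, zscore_fit(tab))
  model <- pca_fit(tab, 0.95)
  # oracle: eigendecomposition of the sample covariance matrix
  eig <- eigen(cov(tab$values), symmetric = TRUE)
  frac <- eig$values / sum(eig$values)
  k <- which(cumsum(frac) >= 0.95 - 1e-12)[1]
  expect_equal(ncol(model$components), k)
  expect_equal(model$explained_var, frac[seq_len(k)], tolerance = 1e-8)
  # component subspace agreement: |cos angle| of matched vectors == 1
  cosines <- abs(colSums(model$components * eig$vectors[, seq_len(k)]))
  expect_equal(cosines, rep(1, k), tolerance = 1e-8, ignore_attr = TRUE)
  # orthonormal loadings, non-increasing explained variance
  expect_equal(crossprod(model$components), diag(k),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(model$explained_var) <= 1e-12))
  expect_lte(sum(model$explained_var), 1 + 1e-12)
})

test_that("PCA keeps one component for rank-1 data and spans data at threshold 1", {
  set.seed(71)
  v <- rnorm(30)
  x <- outer(rnorm(25, sd = 3), v) + matrix(rnorm(25 * 30, sd = 1e-4), 25, 30)
  tab <- feature_table(x, data.frame(subject_id = sprintf("S%d", 1:25),
                                     condition = "x", camera_id = "K1"))
  model <- pca_fit(tab, 0.95)
  expect_equal(ncol(model$components), 1L)

  full <- pca_fit(tab, 1.0)
  proj <- pca_apply(tab, full)
  recon <- proj$values %*% t(full$components)
  centered <- sweep(tab$values, 2, full$center)
  expect_equal(recon, centered, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_fit(tab, 1.5), "\\(0, 1\\]")
  expect_error(pca_fit(tab, 0), "\\(0, 1\\]")
})

test_that("reconstruction error is bounded by the discarded variance", {
  set.seed(81)
  x <- matrix(rnorm(40 * 12), 40, 12) %*% diag(c(8:1, rep(0.1, 4)))
  tab <- feature_table(x, data.frame(subject_id = sprintf("S%d", 1:40),
                                     condition = "x", camera_id = "K1"))
  model <- pca_fit(tab, 0.9)
  proj <- pca_apply(tab, model)
  recon <- proj$values %*% t(model$components)
  centered <- sweep(tab$values, 2, model$center)
  resid_var <- sum((centered - recon)^2) / (nrow(x) - 1)
  eig <- eigen(cov(tab$values), symmetric = TRUE)$values
  discarded <- sum(eig[-seq_len(ncol(model$components))])
  expect_equal(resid_var, discarded, tolerance = 1e-8)
})

test_that("a complete record yields 168 features regardless of segment counts", {
  p <- gait_params(noise_sd = 0.003, duration = 40, seed = 5L)
  rec <- simulate_record(p, emotion_effect("neutral"))
  fv <- extract_record_features(rec)
  expect_length(fv, 168L)
  expect_identical(names(fv), record_feature_names())
  expect_gte(attr(fv, "n_front"), 1L)
  expect_gte(attr(fv, "n_back"), 1L)
})
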