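test_that("hand-computed slope and area features match on the toy cycle", {
  fv <- compute_features(toy_cycle())
  # explicit arithmetic on the printed samples (fs = 10 Hz, dt = 0.1 s)
  expect_equal(fv[["AS"]], (1.00 - 0.10) / 0.7, tolerance = 1e-9)
  expect_equal(fv[["S1"]],
               0.1 * ((0.10 + 0.15) / 2 + (0.15 + 0.25) / 2 +
                      (0.25 + 0.45) / 2), tolerance = 1e-9)
  expect_equal(fv[["S2"]],
               0.1 * ((0.45 + 0.70) / 2 + (0.70 + 0.85) / 2 +
                      (0.85 + 0.95) / 2 + (0.95 + 1.00) / 2),
               tolerance = 1e-9)
  expect_equal(fv[["AA"]], fv[["S1"]] + fv[["S2"]], tolerance = 1e-9)
  expect_equal(fv[["DA"]],
               0.1 * sum((c(1.00, 0.90, 0.80, 0.70, 0.62, 0.55, 0.60, 0.58,
                            0.50, 0.40, 0.30, 0.22, 0.15) +
                          c(0.90, 0.80, 0.70, 0.62, 0.55, 0.60, 0.58, 0.50,
                            0.40, 0.30, 0.22, 0.15, 0.10)) / 2),
               tolerance = 1e-9)
  # duration 2.0 s -> 30 bpm; intensity reads
  expect_equal(fv[["hr"]], 30)
  expect_equal(fv[["PI"]], 1.00)
  expect_equal(fv[["NI"]], 0.55)
  expect_equal(fv[["Slope_a"]], (0.55 - 1.00) / 0.5, tolerance = 1e-9)
})

test_that("a one-second cycle gives heart rate 60", {
  rec <- clean_record(heart_rate_bpm = 60, seed = 3)
  seg <- segment_record(preprocess_record(rec))
  fv <- compute_features(seg$segments[[2]])
  expect_equal(fv[["hr"]], 60, tolerance = 1)
})

test_that("augmentation and duration-ratio identities hold on every cycle", {
  rec <- clean_record(seed = 17)
  seg <- segment_record(preprocess_record(rec))
  fm <- compute_feature_matrix(seg$segments)
  X <- fm$features
  expect_true(all(is.finite(X[, "AI"])))
  expect_equal(unname(X[, "AI"] + X[, "AI1"]), rep(1, nrow(X)),
               tolerance = 1e-9)
  expect_equal(unname(X[, "RSC"] + X[, "RDC"]), rep(1, nrow(X)),
               tolerance = 1e-9)
  expect_equal(unname(X[, "RAAD"]), unname(X[, "AA"] / X[, "DA"]),
               tolerance = 1e-9)
  expect_equal(unname(X[, "RtArea"]),
               unname((X[, "S1"] + X[, "S2"] + X[, "S3"]) / X[, "S4"]),
               tolerance = 1e-9)
  expect_equal(unname(X[, "hr"]),
               60 / (X[, "t1"] + X[, "t2"] + X[, "t3"] + X[, "t4"]),
               tolerance = 1e-9)
  expect_true(all(X[, "PIR"] >= 1 | is.na(X[, "PIR"])))
})

test_that("a stronger dicrotic wave raises NI and AI and lowers AI1", {
  ni <- ai <- ai1 <- numeric(0)
  for (ri in c(0.30, 0.40, 0.50, 0.60)) {
    rec <- generate_record(synth_config(notch_relative_intensity = ri,
                                        seed = 50))
    seg <- segment_record(preprocess_record(rec))
    fm <- compute_feature_matrix(seg$segments)
    ni <- c(ni, mean(fm$features[, "NI"]))
    ai <- c(ai, mean(fm$features[, "AI"]))
    ai1 <- c(ai1, mean(fm$features[, "AI1"]))
  }
  expect_true(all(diff(ni) > 0))
  expect_true(all(diff(ai) > 0))
  expect_true(all(diff(ai1) < 0))
})

test_that("derivative-signal features equal direct recomputation", {
  rec <- clean_record(seed = 19)
  seg <- segment_record(preprocess_record(rec))
  for (s in seg$segments[1:3]) {
    fv <- compute_features(s)
    d <- s$dppg_fragment
    fs <- s$sampling_rate_hz
    dpk <- which.max(d); dvl <- which.min(d)
    o <- s$fiducials$onset_idx; off <- s$fiducials$offset_idx
    expect_equal(fv[["dPI"]], d[dpk])
    expect_equal(fv[["dVI"]], d[dvl])
    expect_equal(fv[["dAID"]], d[dpk] - d[o])
    expect_equal(fv[["dDID"]], d[off] - d[dpk])
    expect_equal(fv[["dAT"]], (dpk - o) / fs)
    expect_equal(fv[["dAS"]], (d[dpk] - d[o]) / ((dpk - o) / fs))
    expect_equal(fv[["dAA"]],
                 sum((d[o:(dpk - 1)] + d[(o + 1):dpk]) / 2) / fs)
    expect_equal(fv[["dRIPV"]], d[dpk] / d[dvl])
  }
})

test_that("notch-dependent features are NA when the notch is absent", {
  rec <- generate_record(synth_config(notch_relative_intensity = 0, seed = 8))
  seg <- segment_record(preprocess_record(rec),
                        criteria = abnormal_criteria(require_fiducials = FALSE))
  fv <- compute_features(seg$segments[[2]])
  for (nm in c("t3", "t4", "S3", "S4", "Slope_a", "RtArea", "NI", "AI",
               "AI1", "RSD", "RSC", "RDC"))
    expect_true(is.na(fv[[nm]]), label = paste(nm, "is NA"))
  expect_false(anyNA(fv[c("hr", "AS", "AA", "DA", "PI")]))
})

test_that("standardization has zero mean, unit sd, and exact inverse", {
  expect_equal(unname(standardize_features(cbind(a = c(1, 3)))$x[, 1]),
               c(-1, 1))
  set.seed(2)
  X <- cbind(a = rnorm(100, 5, 2), b = runif(100), c = rnorm(100, -3, 10))
  std <- standardize_features(X)
  expect_lt(max(abs(colMeans(std$x))), 1e-9)
  popsd <- apply(std$x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(popsd - 1)), 1e-9)
  expect_equal(unstandardize_features(std), X, tolerance = 1e-12)
  # location invariance
  std2 <- standardize_features(X + 100)
  expect_equal(std$x, std2$x, tolerance = 1e-9)
  Xz <- cbind(ok = rnorm(10), flat = rep(2, 10))
  expect_error(standardize_features(Xz), "flat")
})
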