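test_that("z-score normalisation centres and scales with the population convention", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
  # idempotence on already-standardised input
  expect_equal(zscore(z), z, tolerance = 1e-10)
  expect_error(zscore(c(5, 5, 5)), "zero-variance")
  expect_error(zscore(c(5, 5, 5), context = "channel Cz, trial t1"),
               "channel Cz, trial t1")
})

test_that("wavelet variance averages squared non-boundary coefficients", {
  # zero series decomposes to zero everywhere
  d0 <- modwt(rep(0, 31), "haar", n.levels = 2)
  expect_identical(wave_variance(d0, 1), 0)
  expect_identical(wave_variance(d0, 2), 0)
  # d4 at level 2: L_j = 10, so exactly M_j = N - 9 coefficients are used
  set.seed(5)
  x <- rnorm(100)
  d <- modwt(x, "d4", n.levels = 2)
  expect_equal(d$Lj[2], 10)
  w <- d$W[[2]][10:100]  # 91 non-boundary coefficients
  expect_length(w, 91)
  expect_equal(wave_variance(d, 2), mean(w^2))
  expect_error(wave_variance(d, 3), "level must be in")
})

test_that("white-noise Haar level-1 wavelet variance is close to 1/2", {
  # W_1t = (x_t - x_{t-1})/2 for unit-variance noise has variance 2/4
  set.seed(8)
  x <- rnorm(10000)
  d <- modwt(x, "haar", n.levels = 1)
  expect_equal(wave_variance(d, 1), 0.5, tolerance = 0.05)
})

test_that("wavelet correlation is a bounded Pearson correlation of detail coefficients", {
  set.seed(13)
  x <- rnorm(300)
  dx <- modwt(x, "d4", n.levels = 4)
  dneg <- modwt(-x, "d4", n.levels = 4)
  for (j in 1:4) {
    expect_equal(wave_correlation(dx, dx, j), 1)
    expect_equal(wave_correlation(dx, dneg, j), -1)
  }
  # independent channels: correlations within the 4/sqrt(M_j) null band
  set.seed(14)
  a <- modwt(rnorm(2000), "haar", n.levels = 5)
  b <- modwt(rnorm(2000), "haar", n.levels = 5)
  for (j in 1:5) {
    Mj <- 2000 - a$Lj[j] + 1
    expect_lt(abs(wave_correlation(a, b, j)), 4 / sqrt(Mj))
  }
  dy <- modwt(rnorm(100), "d4", n.levels = 2)
  expect_error(wave_correlation(dx, dy, 1), "not comparable")
})

test_that("the feature catalog enumerates variances then correlations deterministically", {
  expect_equal(nrow(feature_catalog(63, 11, "both")), 22176)
  expect_equal(nrow(feature_catalog(2, 1, "both")), 3)
  expect_equal(nrow(feature_catalog(3, 2, "cor")), 6)
  cat_df <- feature_catalog(c("Cz", "T8", "P7"), 2, "both")
  # count law J * (P + P(P-1)/2)
  expect_equal(nrow(cat_df), 2 * (3 + 3))
  # variances channel-major then correlations level-major
  expect_equal(cat_df$type, rep(c("var", "cor"), each = 6))
  expect_equal(cat_df$feature[1:2], c("var_l1_Cz", "var_l2_Cz"))
  expect_equal(cat_df$feature[7:9],
               c("cor_l1_Cz_T8", "cor_l1_Cz_P7", "cor_l1_T8_P7"))
  # unordered pairs stored once, chan_a before chan_b in channel order
  expect_true(all(is.na(cat_df$chan_b[cat_df$type == "var"])))
  expect_error(feature_catalog(1, 2, "cor"), "at least 2 channels")
})

test_that("extracted features are consistent with the catalog and bounded", {
  set.seed(17)
  trial <- matrix(rnorm(4 * 128), nrow = 4,
                  dimnames = list(c("c1", "c2", "c3", "c4"), NULL))
  v <- extract_features(trial, "d4", n.levels = 3, type = "both")
  cat_df <- feature_catalog(rownames(trial), 3, "both")
  expect_equal(names(v), cat_df$feature)
  expect_true(all(v[cat_df$type == "var"] >= 0))
  expect_true(all(abs(v[cat_df$type == "cor"]) <= 1))
})

test_that("identical channels yield unit correlation features", {
  set.seed(18)
  x <- rnorm(128)
  trial <- rbind(a = x, b = x)
  v <- extract_features(trial, "haar", n.levels = 3, type = "cor")
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-12)
})

test_that("features are invariant to per-channel gain", {
  set.seed(19)
  trial <- matrix(rnorm(3 * 128), nrow = 3)
  scaled <- trial * c(5, 0.2, 17)  # different positive gain per channel
  v1 <- extract_features(trial, "d6", n.levels = 2)
  v2 <- extract_features(scaled, "d6", n.levels = 2)
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("a coupled pair correlates most strongly at the matching octave level", {
  ds <- synth_dataset(coupled_cfg(n_per = 1, c0 = 0.9, c1 = 0.9, seed = 99))
  # band 60-120 Hz at fs = 1000 overlaps level 3 ([62.5, 125] Hz)
  expect_true(3 %in% band_levels(60, 120, 1000, 8))
  v <- extract_features(ds$trials[[1]], "d4", n.levels = 6, type = "cor")
  coupled_at <- function(j) v[sprintf("cor_l%d_ch01_ch02", j)]
  expect_gt(coupled_at(3), coupled_at(1))
  expect_gt(coupled_at(3), coupled_at(6))
})

test_that("feature matrix extraction stacks trials in catalog order", {
  ds <- synth_dataset(null_cfg(n_per = 3, channels = 3, n_samples = 64))
  fm <- extract_feature_matrix(ds$trials, "haar", n.levels = 2, type = "both")
  expect_equal(dim(fm$X), c(6, nrow(fm$catalog)))
  expect_equal(colnames(fm$X), fm$catalog$feature)
  expect_equal(rownames(fm$X), names(ds$trials))
  # row i equals a direct single-trial extraction
  expect_equal(fm$X[4, ], extract_features(ds$trials[[4]], "haar", 2, "both"))
})
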