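test_that("within-groups SSCP matches hand sums and the brute-force double loop", {
  # one feature, groups {0,1} and {3,4}: squared deviations sum to 1
  X <- matrix(c(0, 1, 3, 4), ncol = 1)
  g <- c("a", "a", "b", "b")
  expect_equal(within_group_sscp(X, g), matrix(1))
  # a column constant within every group contributes a zero row/column
  X2 <- cbind(X, c(7, 7, 2, 2))
  W2 <- within_group_sscp(X2, g)
  expect_equal(W2[2, ], c(0, 0))
  expect_equal(W2[, 2], c(0, 0))
  # random instances: centred cross-product equals the explicit double loop
  set.seed(3)
  for (r in 1:5) {
    Xr <- matrix(rnorm(24), nrow = 8)
    gr <- rep(c("u", "v"), each = 4)
    Wfast <- within_group_sscp(Xr, gr)
    Wslow <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) for (k in c("u", "v")) {
      rows <- which(gr == k)
      mi <- mean(Xr[rows, i]); mj <- mean(Xr[rows, j])
      for (m in rows)
        Wslow[i, j] <- Wslow[i, j] + (Xr[m, i] - mi) * (Xr[m, j] - mj)
    }
    expect_equal(Wfast, Wslow, tolerance = 1e-10)
    expect_equal(Wfast, t(Wfast))
    expect_true(all(eigen(Wfast, only.values = TRUE)$values > -1e-10))
  }
})

test_that("the Lawley-Hotelling trace reproduces hand-evaluated cases", {
  X <- matrix(c(0, 1, 3, 4), ncol = 1)
  g <- c("a", "a", "b", "b")
  # (n - g) * B / W = 2 * 9 / 1
  expect_equal(lawley_hotelling(X, g), 18)
  # identical group means: between-group term vanishes (within-group
  # scatter kept non-degenerate so W is invertible)
  Xeq <- rbind(c(1, 0), c(3, 2), c(2, 1), c(0, 1), c(4, 1), c(2, 1))
  expect_equal(lawley_hotelling(Xeq, rep(c("a", "b"), each = 3)), 0)
})

test_that("the trace agrees with a term-by-term brute-force evaluation", {
  set.seed(41)
  for (r in 1:8) {
    q <- sample(1:3, 1)
    n <- sample(c(8, 12), 1)
    X <- matrix(rnorm(n * q), nrow = n)
    g <- rep(c("a", "b"), length.out = n)
    expect_equal(lawley_hotelling(X, g), brute_force_V(X, g),
                 tolerance = 1e-8)
    # scalar two-group case: V = (n-2) * B / W11
    if (q == 1) {
      W11 <- within_group_sscp(X, g)[1, 1]
      grand <- mean(X)
      B <- sum(table(g) * (tapply(X[, 1], g, mean) - grand)^2)
      expect_equal(lawley_hotelling(X, g), (n - 2) * B / W11,
                   tolerance = 1e-10)
    }
  }
})

test_that("singular within-groups matrices raise a typed condition", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  Xdup <- cbind(X, X)  # exactly collinear
  expect_error(lawley_hotelling(Xdup, c("a", "a", "b", "b")),
               class = "wavediscr_singular")
  expect_error(lawley_hotelling(X[1:3, , drop = FALSE], c("a", "a", "b")),
               "at least 2 observations")
})

test_that("stepwise selection matches the exhaustive greedy oracle on small instances", {
  set.seed(53)
  for (r in 1:20) {
    p <- sample(3:6, 1)
    n <- sample(c(16, 24, 40), 1)
    X <- matrix(rnorm(n * p), nrow = n)
    g <- rep(c("a", "b"), length.out = n)
    # plant a weak effect in a random column so instances are not all-null
    j0 <- sample(p, 1)
    X[g == "b", j0] <- X[g == "b", j0] + rnorm(1)
    k <- sample(1:3, 1)
    sel <- stepwise_select(X, g, n_select = k)
    expect_identical(sel$selected, greedy_oracle(X, g, k))
    expect_true(all(diff(sel$v_trajectory) >= -1e-9 * abs(sel$v_trajectory[-1])))
    expect_identical(anyDuplicated(sel$selected), 0L)
  }
})

test_that("a single candidate is selected and strong separators beat noise", {
  X1 <- matrix(rnorm(10), ncol = 1)
  g <- rep(c("a", "b"), 5)
  expect_identical(stepwise_select(X1, g, 1)$selected, 1L)
  set.seed(61)
  noise <- rnorm(20)
  separating <- rep(c(0, 10), each = 10) + rnorm(20)
  X <- cbind(noise = noise, sep = separating)
  sel <- stepwise_select(X, rep(c("a", "b"), each = 10), 2)
  expect_identical(sel$features[1], "sep")
})

test_that("column permutation changes only the labels of the selection", {
  set.seed(67)
  X <- matrix(rnorm(30 * 5), nrow = 30)
  colnames(X) <- paste0("f", 1:5)
  g <- rep(c("a", "b"), 15)
  X[g == "b", 2] <- X[g == "b", 2] + 2
  perm <- c(4, 2, 5, 1, 3)
  sel1 <- stepwise_select(X, g, 3)
  sel2 <- stepwise_select(X[, perm], g, 3)
  expect_setequal(sel1$features, sel2$features)
  expect_identical(sel1$features, sel2$features)
})

test_that("collinear candidates are skipped and recorded", {
  set.seed(71)
  g <- rep(c("a", "b"), 6)
  strong <- rnorm(12) + 3 * (g == "b")
  X <- cbind(f1 = strong, f2 = strong, f3 = rnorm(12))
  sel <- stepwise_select(X, g, 2)
  # f1 wins the first step; its exact duplicate f2 is singular thereafter
  expect_identical(sel$features, c("f1", "f3"))
  expect_true("f2" %in% sel$skipped)
  expect_error(stepwise_select(X, g, 9), "n_select must be between")
})
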