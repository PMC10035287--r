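test_that("well-separated clouds are classified perfectly by both discriminants", {
  set.seed(81)
  n <- 30
  X <- rbind(matrix(rnorm(n * 2, mean = -10), ncol = 2),
             matrix(rnorm(n * 2, mean = 10), ncol = 2))
  g <- rep(c("a", "b"), each = n)
  for (kind in c("linear", "quadratic")) {
    fit <- fit_discriminant(X, g, kind)
    expect_equal(as.character(predict(fit, X)), g)
    cm <- loocv(X, g, kind)
    expect_equal(cm$TP + cm$TN, 2 * n)
    expect_equal(cm$FP + cm$FN, 0)
  }
})

test_that("the linear decision boundary matches the pooled-covariance closed form", {
  # for equal-covariance Gaussians with equal priors the LDA rule is
  # sign(w'x - w'(mu1+mu2)/2) with w = S^-1 (mu1 - mu2)
  set.seed(83)
  n <- 200
  S <- matrix(c(2, 0.8, 0.8, 1), 2)
  R <- chol(S)
  mu1 <- c(1, 0); mu2 <- c(-1, 0.5)
  X <- rbind(sweep(matrix(rnorm(n * 2), ncol = 2) %*% R, 2, mu1, "+"),
             sweep(matrix(rnorm(n * 2), ncol = 2) %*% R, 2, mu2, "+"))
  g <- rep(c("a", "b"), each = n)
  fit <- fit_discriminant(X, g, "linear", shrinkage = 0)
  Sp <- ((n - 1) * cov(X[1:n, ]) + (n - 1) * cov(X[-(1:n), ])) / (2 * n - 2)
  w <- solve(Sp, colMeans(X[1:n, ]) - colMeans(X[-(1:n), ]))
  m <- (colMeans(X[1:n, ]) + colMeans(X[-(1:n), ])) / 2
  grid <- as.matrix(expand.grid(seq(-3, 3, 0.5), seq(-3, 3, 0.5)))
  closed <- ifelse(as.numeric((grid - rep(1, nrow(grid)) %o% m) %*% w) > 0,
                   "a", "b")
  expect_equal(as.character(predict(fit, grid)), closed)
})

test_that("linear predictions agree with an independent reference LDA", {
  skip_if_not_installed("MASS")
  set.seed(87)
  X <- matrix(rnorm(60 * 3), ncol = 3)
  g <- rep(c("a", "b"), 30)
  X[g == "b", 1] <- X[g == "b", 1] + 1.5
  fit <- fit_discriminant(X, g, "linear", shrinkage = 0)
  ref <- MASS::lda(X, grouping = g, prior = c(0.5, 0.5))
  Xnew <- matrix(rnorm(40 * 3), ncol = 3)
  expect_equal(as.character(predict(fit, Xnew)),
               as.character(predict(ref, Xnew)$class))
})

test_that("scalar quadratic discriminant matches the two-Gaussian closed form", {
  set.seed(89)
  x1 <- rnorm(100, 0, 1)
  x2 <- rnorm(100, 3, 4)
  X <- matrix(c(x1, x2), ncol = 1)
  g <- rep(c("a", "b"), each = 100)
  fit <- fit_discriminant(X, g, "quadratic", shrinkage = 0)
  m1 <- mean(x1); v1 <- var(x1); m2 <- mean(x2); v2 <- var(x2)
  score <- function(x, m, v) -0.5 * log(v) - (x - m)^2 / (2 * v)
  xs <- seq(-6, 12, 0.25)
  closed <- ifelse(score(xs, m1, v1) > score(xs, m2, v2), "a", "b")
  expect_equal(as.character(predict(fit, matrix(xs, ncol = 1))), closed)
})

test_that("LOOCV on a hand-built six-trial dataset matches fold-by-fold predictions", {
  # single feature; with a pooled variance and equal priors each fold
  # predicts the nearer training-class mean, so every fold can be done by
  # hand: class a at {0, 1, 7}, class b at {4, 5, 6}
  X <- matrix(c(0, 1, 7, 4, 5, 6), ncol = 1)
  g <- rep(c("a", "b"), each = 3)
  cm <- loocv(X, g, "linear", shrinkage = 0, positive = "a")
  # fold 1 (0): means a = 4,   b = 5   -> a (TP)
  # fold 2 (1): means a = 3.5, b = 5   -> a (TP)
  # fold 3 (7): means a = 0.5, b = 5   -> b (FN)
  # fold 4 (4): means a = 8/3, b = 5.5 -> a (FP)
  # fold 5 (5): means a = 8/3, b = 5   -> b (TN)
  # fold 6 (6): means a = 8/3, b = 4.5 -> b (TN)
  expect_equal(cm$TP, 2)
  expect_equal(cm$FN, 1)
  expect_equal(cm$FP, 1)
  expect_equal(cm$TN, 2)
})

test_that("LOOCV accuracy on structureless data stays near chance", {
  set.seed(97)
  n <- 200
  X <- matrix(rnorm(n * 2), ncol = 2)
  g <- sample(rep(c("a", "b"), each = n / 2))
  cm <- loocv(X, g, "linear")
  acc <- classification_metrics(cm)["accuracy"]
  half_width <- qnorm(0.995) * sqrt(0.25 / n)
  expect_gt(acc, 0.5 - half_width)
  expect_lt(acc, 0.5 + half_width)
})

test_that("LOOCV validates its inputs", {
  X <- matrix(rnorm(6), ncol = 1)
  expect_error(loocv(X[1:3, , drop = FALSE], c("a", "a", "b")),
               "at least 2 observations")
  expect_error(loocv(X, rep(c("a", "b", "c"), 2)), "exactly 2 classes")
  expect_error(loocv(X, rep("a", 6)), "exactly 2 classes")
})

test_that("metric formulas reproduce hand arithmetic", {
  m <- classification_metrics(TP = 3, FN = 1, FP = 2, TN = 4)
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 2 / 3)
  expect_equal(unname(m["precision"]), 0.6)
  expect_equal(unname(m["f_measure"]), 2 * 0.6 * 0.75 / (0.6 + 0.75))
  perfect <- classification_metrics(TP = 5, FN = 0, FP = 0, TN = 5)
  expect_equal(unname(perfect), rep(1, 5))
  # accuracy is the prevalence-weighted blend of sensitivity and specificity
  n <- 10
  expect_equal(unname(m["accuracy"]),
               unname(m["sensitivity"]) * 4 / n + unname(m["specificity"]) * 6 / n)
})

test_that("undefined metrics are NA, never zero-filled", {
  m <- classification_metrics(TP = 0, FN = 3, FP = 0, TN = 5)
  expect_equal(unname(m["sensitivity"]), 0)
  expect_true(is.na(m["precision"]))
  expect_true(is.na(m["f_measure"]))
  expect_error(classification_metrics(TP = 0, FN = 0, FP = 0, TN = 0),
               "empty")
  expect_error(classification_metrics(TP = -1, FN = 0, FP = 0, TN = 2),
               "non-negative")
})

test_that("full shrinkage keeps only the diagonal of the covariance", {
  set.seed(101)
  X <- matrix(rnorm(40 * 2), ncol = 2)
  X[, 2] <- X[, 1] + 0.01 * X[, 2]  # nearly collinear
  g <- rep(c("a", "b"), 20)
  # a zero-variance feature defeats any diagonal shrinkage
  expect_error(fit_discriminant(cbind(X[, 1], 0), g, "linear"), "singular")
  fit <- fit_discriminant(X, g, "linear", shrinkage = 1)
  S <- fit$chol[["a"]]
  expect_equal(S[1, 2], 0)  # off-diagonal gone after lambda = 1
})
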