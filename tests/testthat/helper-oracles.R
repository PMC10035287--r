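# Independent oracles used across the suite.  These deliberately avoid the
# package's pyramid/recursive code paths: filters are cascaded explicitly
# and statistics evaluated by brute-force loops.

# level-j equivalent DWT filter pair by the explicit cascade:
#   g_j = g_{j-1} (*) up(g, 2^{j-1}),  h_j = g_{j-1} (*) up(h, 2^{j-1})
# where up(f, s) inserts s-1 zeros between taps and (*) is full convolution.
cascade_filters <- function(g, h, J) {
  upsample <- function(f, s) {
    if (s == 1) return(f)
    out <- numeric((length(f) - 1) * s + 1)
    out[seq(1, length(out), by = s)] <- f
    out
  }
  conv_full <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) {
      idx <- i + seq_along(b) - 1
      out[idx] <- out[idx] + a[i] * b
    }
    out
  }
  gj <- g
  hj <- h
  if (J >= 2) for (j in 2:J) {
    s <- 2^(j - 1)
    hj <- conv_full(gj, upsample(h, s))
    gj <- conv_full(gj, upsample(g, s))
  }
  list(g = gj, h = hj)
}

# direct evaluation of the non-decimated transform: circular convolution of
# the input with the MODWT-rescaled level-j equivalent filters
direct_modwt <- function(x, filter_name, J) {
  f <- wavelet_filter(filter_name)
  N <- length(x)
  W <- vector("list", J)
  V <- NULL
  for (j in seq_len(J)) {
    cf <- cascade_filters(f$g, f$h, j)
    ht <- cf$h / 2^(j / 2)
    gt <- cf$g / 2^(j / 2)
    conv_circ <- function(coefs) {
      sapply(seq_len(N) - 1L, function(t)
        sum(coefs * x[((t - (seq_along(coefs) - 1L)) %% N) + 1L]))
    }
    W[[j]] <- conv_circ(ht)
    if (j == J) V <- conv_circ(gt)
  }
  list(W = W, V = V)
}

# Lawley-Hotelling trace evaluated term by term with explicit double sums
brute_force_V <- function(X, groups) {
  X <- as.matrix(X)
  groups <- as.factor(groups)
  lv <- levels(groups)
  n <- nrow(X)
  g <- length(lv)
  q <- ncol(X)
  W <- matrix(0, q, q)
  for (i in seq_len(q)) for (j in seq_len(q))
    for (k in lv) {
      rows <- which(groups == k)
      mi <- mean(X[rows, i]); mj <- mean(X[rows, j])
      for (m in rows) W[i, j] <- W[i, j] + (X[m, i] - mi) * (X[m, j] - mj)
    }
  a <- solve(W)
  grand <- colMeans(X)
  V <- 0
  for (i in seq_len(q)) for (j in seq_len(q)) {
    s <- 0
    for (k in lv) {
      rows <- which(groups == k)
      s <- s + length(rows) * (mean(X[rows, i]) - grand[i]) *
        (mean(X[rows, j]) - grand[j])
    }
    V <- V + a[i, j] * s
  }
  (n - g) * V
}

# exhaustive greedy selection: at each step evaluate brute_force_V for every
# augmented candidate set and take the argmax (first index on ties)
greedy_oracle <- function(X, groups, n_select) {
  chosen <- integer(0)
  remaining <- seq_len(ncol(X))
  for (s in seq_len(n_select)) {
    vals <- sapply(remaining, function(j)
      tryCatch(brute_force_V(X[, c(chosen, j), drop = FALSE], groups),
               error = function(e) NA_real_))
    if (all(is.na(vals))) break
    best <- remaining[which.max(vals)]
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
  }
  chosen
}

# small coupled-pair / null synthetic configurations shared by tests
coupled_cfg <- function(n_per = 40, channels = 8, n_samples = 512,
                        c0 = 0.9, c1 = 0, seed = 42) {
  synth_config("test", n_trials_per_class = n_per, channels = channels,
               n_samples = n_samples,
               coupled_pairs = data.frame(chan_a = 1, chan_b = 2,
                                          band_low = 60, band_high = 120,
                                          coupling_class0 = c0,
                                          coupling_class1 = c1),
               seed = seed)
}

null_cfg <- function(n_per = 50, channels = 8, n_samples = 512, seed = 42)
  synth_config("test", n_trials_per_class = n_per, channels = channels,
               n_samples = n_samples, seed = seed)
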