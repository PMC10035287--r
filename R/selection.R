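check_groups <- function(X, groups) {
  X <- as.matrix(X)
  groups <- as.factor(groups)
  if (length(groups) != nrow(X))
    stop("length of group labels (", length(groups),
         ") does not match the number of rows (", nrow(X), ")", call. = FALSE)
  tab <- table(groups)
  if (any(tab < 2))
    stop("every group needs at least 2 observations; group(s) ",
         paste(names(tab)[tab < 2], collapse = ", "), " too small",
         call. = FALSE)
  list(X = X, groups = droplevels(groups))
}

#' Within-groups sum of cross-products matrix
#'
#' The pooled matrix of cross-products of deviations from the group
#' means, \eqn{W_{ij} = \sum_k \sum_{m \in k} (X_{ikm} - \bar X_{ik})
#' (X_{jkm} - \bar X_{jk})}.  Symmetric and positive semidefinite; the
#' within-group counterpart of the between-group scatter used by the
#' Lawley-Hotelling trace.
#'
#' @param X numeric matrix, observations in rows, variables in columns.
#' @param groups group label per row (coerced to factor).
#' @return Symmetric \eqn{q \times q} matrix.
#' @export
within_group_sscp <- function(X, groups) {
  cg <- check_groups(X, groups)
  Xc <- cg$X
  for (g in levels(cg$groups)) {
    rows <- cg$groups == g
    Xc[rows, ] <- sweep(Xc[rows, , drop = FALSE], 2,
                        colMeans(Xc[rows, , drop = FALSE]))
  }
  crossprod(Xc)
}

between_group_sscp <- function(X, groups) {
  cg <- check_groups(X, groups)
  grand <- colMeans(cg$X)
  B <- matrix(0, ncol(cg$X), ncol(cg$X))
  for (g in levels(cg$groups)) {
    rows <- cg$groups == g
    d <- colMeans(cg$X[rows, , drop = FALSE]) - grand
    B <- B + sum(rows) * tcrossprod(d)
  }
  B
}

#' Lawley-Hotelling trace
#'
#' The multivariate between-group separation statistic
#' \deqn{V = (n - g)\, \mathrm{tr}(W^{-1} B),}
#' where \eqn{W} is the within-groups sum-of-cross-products matrix and
#' \eqn{B = \sum_k n_k (\bar X_k - \bar X)(\bar X_k - \bar X)^\top} the
#' between-groups counterpart.  Larger values mean the group centroids
#' are further apart relative to the within-group scatter; it is the
#' criterion maximised by the stepwise feature selection.
#'
#' @inheritParams within_group_sscp
#' @param rcond_tol reciprocal-condition-number threshold below which
#'   \eqn{W} is declared singular.
#' @return Non-negative number, or an error of class
#'   \code{"wavediscr_singular"} when \eqn{W} is numerically singular
#'   (the stepwise loop catches this and skips the candidate).
#' @export
lawley_hotelling <- function(X, groups, rcond_tol = 1e-12) {
  cg <- check_groups(X, groups)
  W <- within_group_sscp(cg$X, cg$groups)
  rc <- tryCatch(rcond(W), error = function(e) 0)
  if (!is.finite(rc) || rc < rcond_tol)
    stop(errorCondition(
      paste0("within-groups SSCP matrix is numerically singular (rcond = ",
             format(rc, digits = 3), ")"),
      class = "wavediscr_singular"))
  B <- between_group_sscp(cg$X, cg$groups)
  n <- nrow(cg$X)
  g <- nlevels(cg$groups)
  V <- (n - g) * sum(diag(solve(W, B)))
  max(V, 0)
}

#' Greedy forward stepwise feature selection
#'
#' Starting from the empty set, repeatedly adds the candidate feature
#' whose inclusion maximises the Lawley-Hotelling trace of the augmented
#' set, until \code{n_select} features have been chosen.  Candidates that
#' make the within-groups matrix numerically singular at a given step are
#' skipped at that step (and recorded); exact ties are broken towards the
#' lower column index, making the procedure deterministic.
#'
#' @param X numeric feature matrix, trials in rows, candidate features in
#'   columns (column names are feature names).
#' @param groups class label per trial.
#' @param n_select number of features to select (1..ncol(X)).
#' @param rcond_tol singularity threshold passed to [lawley_hotelling()].
#' @return An object of class \code{"stepwise_selection"}: list with
#'   \code{selected} (integer column indices in selection order),
#'   \code{features} (their names), \code{v_trajectory} (Lawley-Hotelling
#'   trace after each addition, non-decreasing), and \code{skipped}
#'   (names of candidates ever skipped for singularity).
#' @export
stepwise_select <- function(X, groups, n_select, rcond_tol = 1e-12) {
  cg <- check_groups(X, groups)
  X <- cg$X
  p <- ncol(X)
  n_select <- as.integer(n_select)
  if (is.na(n_select) || n_select < 1L || n_select > p)
    stop("n_select must be between 1 and the number of candidate features (",
         p, ")", call. = FALSE)
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("f", seq_len(p))
  # W and B for any feature subset are the corresponding submatrices of the
  # full within- and between-groups SSCP matrices, so both are computed once
  # and every candidate evaluation reduces to a small solve
  W_full <- within_group_sscp(X, cg$groups)
  B_full <- between_group_sscp(X, cg$groups)
  n <- nrow(X)
  ng <- nlevels(cg$groups)
  selected <- integer(0)
  v_traj <- numeric(0)
  skipped <- character(0)
  remaining <- seq_len(p)
  for (step in seq_len(n_select)) {
    best_v <- -Inf
    best_j <- NA_integer_
    for (j in remaining) {
      idx <- c(selected, j)
      Ws <- W_full[idx, idx, drop = FALSE]
      rc <- tryCatch(rcond(Ws), error = function(e) 0)
      v <- if (!is.finite(rc) || rc < rcond_tol) NA_real_
           else max((n - ng) * sum(diag(solve(Ws, B_full[idx, idx,
                                                          drop = FALSE]))), 0)
      if (is.na(v)) {
        skipped <- union(skipped, cn[j])
        next
      }
      # ties within relative 1e-9 resolve to the lower column index,
      # which is the first one seen
      if (is.infinite(best_v) || v > best_v * (1 + 1e-9)) {
        best_v <- v
        best_j <- j
      }
    }
    if (is.na(best_j)) {
      warning("stepwise selection stopped early at ", length(selected),
              " features: all remaining candidates are singular",
              call. = FALSE)
      break
    }
    selected <- c(selected, best_j)
    remaining <- setdiff(remaining, best_j)
    v_traj <- c(v_traj, best_v)
  }
  structure(list(selected = selected, features = cn[selected],
                 v_trajectory = v_traj, skipped = skipped),
            class = "stepwise_selection")
}

#' @export
print.stepwise_selection <- function(x, ...) {
  cat("Stepwise selection of", length(x$selected), "features\n")
  df <- data.frame(rank = seq_along(x$selected), feature = x$features,
                   V = x$v_trajectory)
  print(df, row.names = FALSE)
  if (length(x$skipped))
    cat("Skipped for singularity:", length(x$skipped), "candidate(s)\n")
  invisible(x)
}
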