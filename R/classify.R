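#' Gaussian discriminant classifier
#'
#' Fits a linear (pooled within-group covariance) or quadratic (per-group
#' covariance) Gaussian discriminant with equal class priors.  Each
#' covariance estimate is regularised towards its own diagonal,
#' \eqn{(1-\lambda) S + \lambda\, \mathrm{diag}(S)}, which keeps the fit
#' stable when the number of features approaches the number of trials.
#' Prediction assigns the class with the largest Gaussian log-density.
#'
#' @param X numeric matrix, trials in rows, features in columns.
#' @param groups class label per trial (2 or more classes, each with at
#'   least 2 trials).
#' @param kind \code{"linear"} or \code{"quadratic"}.
#' @param shrinkage diagonal shrinkage weight \eqn{\lambda \in [0, 1]}
#'   (default \code{1e-4}; \code{0} disables regularisation).
#' @return An object of class \code{"gaussian_da"} with per-class means,
#'   covariance factor(s) and metadata; supports [predict()].
#' @seealso [loocv()] for leave-one-out evaluation.
#' @export
fit_discriminant <- function(X, groups, kind = c("linear", "quadratic"),
                             shrinkage = 1e-4) {
  kind <- match.arg(kind)
  cg <- check_groups(X, groups)
  X <- cg$X
  groups <- cg$groups
  if (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1)
    stop("shrinkage must be in [0, 1]", call. = FALSE)
  q <- ncol(X)
  lv <- levels(groups)
  means <- lapply(lv, function(g) colMeans(X[groups == g, , drop = FALSE]))
  names(means) <- lv
  shrink <- function(S) (1 - shrinkage) * S + shrinkage * diag(diag(S), q)
  covs <- lapply(lv, function(g) {
    Xg <- X[groups == g, , drop = FALSE]
    shrink(stats::cov(Xg))
  })
  names(covs) <- lv
  if (kind == "linear") {
    n <- nrow(X)
    ng <- table(groups)
    # pooled: weighted by within-group degrees of freedom
    Sp <- Reduce(`+`, Map(function(S, nk) (nk - 1) * S,
                          covs, as.list(as.numeric(ng)))) / (n - length(lv))
    covs <- stats::setNames(rep(list(Sp), length(lv)), lv)
  }
  chols <- lapply(covs, function(S) {
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R))
      stop("covariance matrix is singular even after shrinkage; ",
           "increase `shrinkage` or select fewer features", call. = FALSE)
    R
  })
  structure(list(kind = kind, levels = lv, means = means, chol = chols,
                 shrinkage = shrinkage, q = q,
                 features = colnames(X)),
            class = "gaussian_da")
}

#' @rdname fit_discriminant
#' @param object fitted \code{"gaussian_da"} classifier.
#' @param newdata matrix (or vector for a single trial) of feature values.
#' @param type \code{"class"} for predicted labels, \code{"score"} for the
#'   matrix of per-class discriminant scores (Gaussian log-densities up to
#'   a shared constant).
#' @param ... unused.
#' @export
predict.gaussian_da <- function(object, newdata, type = c("class", "score"),
                                ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$q)
    stop("newdata has ", ncol(newdata), " features; classifier expects ",
         object$q, call. = FALSE)
  scores <- sapply(object$levels, function(g) {
    R <- object$chol[[g]]
    d <- sweep(newdata, 2, object$means[[g]])
    # log N(x; mu, S) up to constant: -0.5 log|S| - 0.5 (x-mu)' S^-1 (x-mu)
    z <- backsolve(R, t(d), transpose = TRUE)
    -sum(log(diag(R))) - 0.5 * colSums(z^2)
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(NULL, object$levels))
  if (type == "score") return(scores)
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.gaussian_da <- function(x, ...) {
  cat("Gaussian", x$kind, "discriminant:", length(x$levels), "classes,",
      x$q, "features, shrinkage =", x$shrinkage, "\n")
  invisible(x)
}

#' Leave-one-out cross-validation of a discriminant classifier
#'
#' For each trial in turn, fits the discriminant on the remaining
#' \eqn{n-1} trials and predicts the held-out one; predictions are
#' tallied into a 2-class confusion matrix against the declared positive
#' class.
#'
#' @inheritParams fit_discriminant
#' @param positive label of the positive class (default: first factor
#'   level).
#' @param select_fn optional function \code{(X, groups) -> column
#'   indices}; when supplied, feature selection is re-run inside every
#'   fold on the training rows only, giving a selection-bias-free
#'   accuracy estimate.
#' @return A \code{"confusion_matrix"} object: named counts \code{TP},
#'   \code{FN}, \code{FP}, \code{TN} plus the positive-class label.
#' @export
loocv <- function(X, groups, kind = c("linear", "quadratic"),
                  shrinkage = 1e-4, positive = NULL, select_fn = NULL) {
  kind <- match.arg(kind)
  cg <- check_groups(X, groups)
  X <- cg$X
  groups <- cg$groups
  n <- nrow(X)
  if (n < 4) stop("leave-one-out needs at least 4 trials", call. = FALSE)
  if (nlevels(groups) != 2)
    stop("confusion-matrix evaluation requires exactly 2 classes",
         call. = FALSE)
  if (is.null(positive)) positive <- levels(groups)[1]
  if (!positive %in% levels(groups))
    stop("positive class '", positive, "' is not a label", call. = FALSE)
  pred <- factor(rep(NA_character_, n), levels = levels(groups))
  for (i in seq_len(n)) {
    tr_rows <- setdiff(seq_len(n), i)
    g_tr <- groups[tr_rows]
    if (any(table(g_tr) < 2))
      stop("fold ", i, ": a training group has fewer than 2 trials",
           call. = FALSE)
    cols <- if (is.null(select_fn)) seq_len(ncol(X))
            else select_fn(X[tr_rows, , drop = FALSE], g_tr)
    fit <- tryCatch(
      fit_discriminant(X[tr_rows, cols, drop = FALSE], g_tr, kind, shrinkage),
      error = function(e)
        stop("fold ", i, ": ", conditionMessage(e), call. = FALSE))
    pred[i] <- predict(fit, X[i, cols, drop = FALSE])
  }
  confusion_matrix(truth = groups, predicted = pred, positive = positive)
}

#' Confusion matrix for a two-class problem
#'
#' @param truth,predicted factors of true and predicted labels.
#' @param positive label of the positive class.
#' @return A \code{"confusion_matrix"} object: list with counts
#'   \code{TP}, \code{FN}, \code{FP}, \code{TN} and the \code{positive}
#'   label.
#' @export
confusion_matrix <- function(truth, predicted, positive) {
  truth <- as.factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  stopifnot(length(truth) == length(predicted))
  is_pos <- truth == positive
  pred_pos <- predicted == positive
  structure(list(TP = sum(is_pos & pred_pos),
                 FN = sum(is_pos & !pred_pos),
                 FP = sum(!is_pos & pred_pos),
                 TN = sum(!is_pos & !pred_pos),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  cat("Confusion matrix (positive class: ", x$positive, ")\n", sep = "")
  print(m)
  invisible(x)
}

#' Classification performance metrics
#'
#' Derives the standard two-class rates from a confusion matrix:
#' accuracy \eqn{(TP+TN)/n}, sensitivity \eqn{TP/(TP+FN)}, specificity
#' \eqn{TN/(FP+TN)}, precision \eqn{TP/(TP+FP)} and the F-measure
#' \eqn{2\,\mathrm{prec}\cdot\mathrm{sens}/(\mathrm{prec}+\mathrm{sens})}.
#' A metric whose denominator is zero is reported as \code{NA}
#' (undefined), never as 0.
#'
#' @param cm a \code{"confusion_matrix"}, or the four counts given as
#'   \code{TP}, \code{FN}, \code{FP}, \code{TN}.
#' @param TP,FN,FP,TN counts, used when \code{cm} is missing.
#' @return Named numeric vector with elements \code{accuracy},
#'   \code{sensitivity}, \code{specificity}, \code{precision},
#'   \code{f_measure}.
#' @examples
#' classification_metrics(TP = 3, FN = 1, FP = 2, TN = 4)
#' @export
classification_metrics <- function(cm = NULL, TP, FN, FP, TN) {
  if (!is.null(cm)) {
    stopifnot(inherits(cm, "confusion_matrix"))
    TP <- cm$TP; FN <- cm$FN; FP <- cm$FP; TN <- cm$TN
  }
  counts <- c(TP, FN, FP, TN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion-matrix counts must be non-negative integers",
         call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rate(TP, TP + FN)
  prec <- rate(TP, TP + FP)
  fmeas <- if (is.na(sens) || is.na(prec) || (sens + prec) == 0) NA_real_
           else 2 * prec * sens / (prec + sens)
  c(accuracy = (TP + TN) / n,
    sensitivity = sens,
    specificity = rate(TN, FP + TN),
    precision = prec,
    f_measure = fmeas)
}
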