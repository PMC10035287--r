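#' Fit a wavelet-feature discriminant classifier to multichannel trials
#'
#' The full classification pipeline as one model fit.  Every channel of
#' every trial is z-normalised and decomposed with the MODWT; per-level
#' wavelet variances and same-level cross-channel wavelet correlations
#' form the candidate feature set; a greedy forward stepwise procedure
#' selects the \code{n_variables} features maximising the
#' Lawley-Hotelling trace; and a linear or quadratic Gaussian
#' discriminant on the selected features is evaluated by leave-one-out
#' cross-validation.  The fit is fully deterministic given the data and
#' configuration.
#'
#' By default the stepwise selection is run once on the whole dataset and
#' LOOCV evaluates only the classifier (\code{selection = "whole"}); with
#' \code{selection = "within_folds"} the selection is re-run inside every
#' fold on the training trials only, which removes selection bias from
#' the accuracy estimate at the price of \eqn{n} selection runs.
#'
#' @param trials named list of channel-by-time matrices (identical
#'   channel sets and lengths), or a \code{"synth_dataset"} (in which
#'   case \code{labels} is taken from it).
#' @param labels class label per trial (two classes).
#' @param filter wavelet filter name; see [wavelet_filter()].
#' @param n.levels number of MODWT levels (default: the maximum safe
#'   level for the trial length and filter).
#' @param type candidate feature types: \code{"both"}, \code{"var"} or
#'   \code{"cor"}.
#' @param n_variables number of features the stepwise procedure selects.
#' @param kind discriminant kind, \code{"linear"} or \code{"quadratic"}.
#' @param shrinkage diagonal covariance shrinkage; see
#'   [fit_discriminant()].
#' @param selection \code{"whole"} (select once on all trials, then
#'   cross-validate the classifier) or \code{"within_folds"}
#'   (selection-bias-free; re-select inside each fold).
#' @param positive positive-class label for the confusion matrix
#'   (default: first factor level).
#' @return An object of class \code{"wavediscr"} with components
#'   \code{selection} (the [stepwise_select()] result), \code{confusion},
#'   \code{metrics}, \code{fit} (final discriminant trained on all
#'   trials with the selected features), \code{catalog},
#'   \code{selected_features} (catalog rows of the selected features, in
#'   selection order), \code{features} (the full candidate feature
#'   matrix) and \code{config}.
#' @examples
#' cfg <- synth_config("test", n_trials_per_class = 10,
#'   coupled_pairs = data.frame(chan_a = 1, chan_b = 2,
#'     band_low = 60, band_high = 120,
#'     coupling_class0 = 0.9, coupling_class1 = 0),
#'   seed = 7)
#' ds <- synth_dataset(cfg)
#' fit <- wavediscr(ds, filter = "haar", type = "cor", n_variables = 2)
#' fit
#' @export
wavediscr <- function(trials, labels = NULL, filter = "d6", n.levels = NULL,
                      type = c("both", "var", "cor"), n_variables = 20,
                      kind = c("linear", "quadratic"), shrinkage = 1e-4,
                      selection = c("whole", "within_folds"),
                      positive = NULL) {
  cl <- match.call()
  type <- match.arg(type)
  kind <- match.arg(kind)
  selection <- match.arg(selection)
  if (inherits(trials, "synth_dataset")) {
    if (is.null(labels)) labels <- trials$labels
    trials <- trials$trials
  }
  labels <- as.factor(labels)
  fm <- extract_feature_matrix(trials, filter = filter, n.levels = n.levels,
                               type = type)
  fit_obj <- wavediscr_fit(fm$X, labels, fm$catalog,
                           n_variables = n_variables, kind = kind,
                           shrinkage = shrinkage, selection = selection,
                           positive = positive)
  fit_obj$config <- c(fit_obj$config,
                      list(filter = as_wavelet_filter(filter)$name,
                           n.levels = max(fm$catalog$level), type = type))
  fit_obj$call <- cl
  fit_obj
}

# pipeline from a precomputed feature matrix (shared by wavediscr and the
# parameter sweep, where features are extracted once and reused)
wavediscr_fit <- function(X, labels, catalog, n_variables, kind, shrinkage,
                          selection = "whole", positive = NULL) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[1]
  sel <- stepwise_select(X, labels, n_select = n_variables)
  if (selection == "whole") {
    cm <- loocv(X[, sel$selected, drop = FALSE], labels, kind = kind,
                shrinkage = shrinkage, positive = positive)
  } else {
    sel_fn <- function(Xtr, gtr)
      stepwise_select(Xtr, gtr, n_select = n_variables)$selected
    cm <- loocv(X, labels, kind = kind, shrinkage = shrinkage,
                positive = positive, select_fn = sel_fn)
  }
  final <- fit_discriminant(X[, sel$selected, drop = FALSE], labels,
                            kind = kind, shrinkage = shrinkage)
  structure(list(
    selection = sel,
    confusion = cm,
    metrics = classification_metrics(cm),
    fit = final,
    catalog = catalog,
    selected_features = catalog[sel$selected, , drop = FALSE],
    features = X,
    labels = labels,
    config = list(n_variables = n_variables, kind = kind,
                  shrinkage = shrinkage, selection = selection,
                  positive = positive)),
    class = "wavediscr")
}

#' @export
print.wavediscr <- function(x, digits = 4, ...) {
  cat("Wavelet-feature discriminant classifier\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cfg <- x$config
  cat(sprintf("Filter: %s | levels: %s | features: %s | selected: %d | %s discriminant\n",
              cfg$filter %||% "?", cfg$n.levels %||% "?", cfg$type %||% "?",
              length(x$selection$selected), cfg$kind))
  cat(sprintf("Candidate features: %d | trials: %d | selection: %s\n",
              ncol(x$features), nrow(x$features), cfg$selection))
  cat(sprintf("LOOCV accuracy: %.*f\n", digits, x$metrics["accuracy"]))
  invisible(x)
}

#' @export
summary.wavediscr <- function(object, ...) {
  structure(list(object = object), class = "summary.wavediscr")
}

#' @export
print.summary.wavediscr <- function(x, digits = 4, ...) {
  object <- x$object
  print(object)
  cat("\nSelected features (in selection order):\n")
  print(coef(object), row.names = FALSE)
  cat("\n")
  print(object$confusion)
  cat("\nLOOCV metrics:\n")
  print(round(object$metrics, digits))
  invisible(x)
}

#' @export
#' @describeIn wavediscr table of selected features with the
#'   Lawley-Hotelling trace after each inclusion.
#' @param object,x a fitted \code{"wavediscr"} object.
#' @param ... passed on.
coef.wavediscr <- function(object, ...) {
  sf <- object$selected_features
  data.frame(rank = seq_len(nrow(sf)), sf,
             V = object$selection$v_trajectory,
             row.names = NULL)
}

#' @export
#' @describeIn wavediscr predict class labels for new trials (a list of
#'   channel-by-time matrices) from the final discriminant fitted on all
#'   training trials.
#' @param newdata list of channel-by-time matrices.
predict.wavediscr <- function(object, newdata, ...) {
  if (inherits(newdata, "synth_dataset")) newdata <- newdata$trials
  if (is.matrix(newdata)) newdata <- list(newdata)
  cfg <- object$config
  fm <- extract_feature_matrix(newdata, filter = cfg$filter,
                               n.levels = cfg$n.levels, type = cfg$type)
  cols <- match(object$selected_features$feature, fm$catalog$feature)
  predict(object$fit, fm$X[, cols, drop = FALSE], ...)
}

#' @export
#' @describeIn wavediscr plot the Lawley-Hotelling trace trajectory over
#'   selection steps.
plot.wavediscr <- function(x, ...) {
  v <- x$selection$v_trajectory
  graphics::plot(seq_along(v), v, type = "b", pch = 16,
                 xlab = "selection step", ylab = "Lawley-Hotelling trace",
                 main = "Stepwise selection trajectory", ...)
  invisible(x)
}
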