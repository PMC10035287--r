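#' Sweep the classification pipeline over a parameter grid
#'
#' Runs the full pipeline for every combination of filter, feature type,
#' number of selected variables and discriminant kind, returning one row
#' of performance metrics per combination — the layout used for
#' accuracy-versus-model-size curves and size-stratified summary tables.
#' Features are extracted once per filter and the greedy selection is run
#' once per (filter, type) to the largest requested size; smaller sizes
#' reuse its prefix (the greedy forward path is nested by construction).
#'
#' @param trials named list of channel-by-time matrices, or a
#'   \code{"synth_dataset"}.
#' @param labels class label per trial (taken from the dataset when
#'   omitted).
#' @param filters character vector of wavelet filter names.
#' @param types feature-type sets, subset of \code{c("var", "cor",
#'   "both")}.
#' @param sizes integer vector of numbers of selected variables.
#' @param kinds discriminant kinds, subset of \code{c("linear",
#'   "quadratic")}.
#' @param n.levels MODWT levels (default: maximum safe level per filter).
#' @param shrinkage,selection,positive passed to the pipeline; see
#'   [wavediscr()].
#' @return Data frame with one row per combination: \code{filter},
#'   \code{type}, \code{size}, \code{kind}, the five metrics of
#'   [classification_metrics()], \code{error} (message for failed
#'   combinations, else \code{NA}), and \code{first_feature}.
#' @export
param_sweep <- function(trials, labels = NULL,
                        filters = wavelet_filter_names(),
                        types = c("var", "both", "cor"),
                        sizes = c(20, 40, 60),
                        kinds = c("linear", "quadratic"),
                        n.levels = NULL, shrinkage = 1e-4,
                        selection = "whole", positive = NULL) {
  if (inherits(trials, "synth_dataset")) {
    if (is.null(labels)) labels <- trials$labels
    trials <- trials$trials
  }
  labels <- as.factor(labels)
  stopifnot(length(filters) > 0, length(types) > 0, length(sizes) > 0,
            length(kinds) > 0)
  types <- match.arg(types, c("var", "cor", "both"), several.ok = TRUE)
  sizes <- sort(unique(as.integer(sizes)))
  out <- list()
  for (flt in filters) {
    fm <- tryCatch(
      extract_feature_matrix(trials, filter = flt, n.levels = n.levels,
                             type = "both"),
      error = function(e) e)
    for (tp in types) {
      if (inherits(fm, "error")) {
        for (sz in sizes) for (kd in kinds)
          out[[length(out) + 1L]] <- .sweep_row(flt, tp, sz, kd,
                                                err = conditionMessage(fm))
        next
      }
      keep <- if (tp == "both") seq_len(nrow(fm$catalog))
              else which(fm$catalog$type == tp)
      X <- fm$X[, keep, drop = FALSE]
      cat_t <- fm$catalog[keep, , drop = FALSE]
      smax <- min(max(sizes), ncol(X))
      sel <- tryCatch(stepwise_select(X, labels, n_select = smax),
                      error = function(e) e)
      for (sz in sizes) for (kd in kinds) {
        if (inherits(sel, "error")) {
          out[[length(out) + 1L]] <- .sweep_row(flt, tp, sz, kd,
                                                err = conditionMessage(sel))
          next
        }
        row <- tryCatch({
          take <- sel$selected[seq_len(min(sz, length(sel$selected)))]
          if (selection == "whole") {
            cm <- loocv(X[, take, drop = FALSE], labels, kind = kd,
                        shrinkage = shrinkage, positive = positive)
          } else {
            sel_fn <- function(Xtr, gtr)
              stepwise_select(Xtr, gtr, n_select = min(sz, ncol(Xtr)))$selected
            cm <- loocv(X, labels, kind = kd, shrinkage = shrinkage,
                        positive = positive, select_fn = sel_fn)
          }
          .sweep_row(flt, tp, sz, kd, metrics = classification_metrics(cm),
                     first = cat_t$feature[sel$selected[1]])
        }, error = function(e) .sweep_row(flt, tp, sz, kd,
                                          err = conditionMessage(e)))
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.sweep_row <- function(flt, tp, sz, kd, metrics = NULL, err = NA_character_,
                       first = NA_character_) {
  m <- if (is.null(metrics))
    c(accuracy = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
      precision = NA_real_, f_measure = NA_real_)
  else metrics
  data.frame(filter = flt, type = tp, size = sz, kind = kd,
             as.list(m), first_feature = first, error = err,
             stringsAsFactors = FALSE)
}

#' Channel-importance summary of a feature selection
#'
#' Counts how often each channel appears among the selected features (a
#' correlation feature contributes one slot to each of its two channels,
#' a variance feature one slot to its channel).  With a channel-group map
#' (e.g. motor-cortex vs other electrodes) the selected correlation
#' pairs are additionally tallied by category (within-group A, mixed,
#' within-group B, ...).
#'
#' @param object a fitted \code{"wavediscr"} model, or a data frame of
#'   selected features with columns \code{type}, \code{chan_a},
#'   \code{chan_b}.
#' @param group_map optional named character vector mapping channel names
#'   to group labels; unmapped channels are counted under
#'   \code{"unmapped"} with a warning.
#' @return List of class \code{"electrode_report"}: \code{counts} (named
#'   vector of per-channel occurrence counts, decreasing), \code{slots}
#'   (total channel slots = variances + 2 x correlations),
#'   \code{n_unique} (distinct channels involved), \code{group_counts}
#'   (slots per group, when mapped) and \code{pair_categories}
#'   (correlation pairs per unordered group pair, when mapped).
#' @export
electrode_summary <- function(object, group_map = NULL) {
  sf <- if (inherits(object, "wavediscr")) object$selected_features
        else as.data.frame(object)
  stopifnot(all(c("type", "chan_a") %in% names(sf)))
  if (nrow(sf) == 0) stop("selection is empty", call. = FALSE)
  slots <- c(sf$chan_a, sf$chan_b[sf$type == "cor"])
  slots <- slots[!is.na(slots)]
  counts <- sort(table(slots), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  rep_obj <- list(counts = counts, slots = length(slots),
                  n_unique = length(counts))
  if (!is.null(group_map)) {
    grp <- function(ch) {
      g <- unname(group_map[ch])
      g[is.na(g)] <- "unmapped"
      g
    }
    if (any(!names(counts) %in% names(group_map)))
      warning("channel(s) absent from group map counted as 'unmapped': ",
              paste(setdiff(names(counts), names(group_map)), collapse = ", "),
              call. = FALSE)
    rep_obj$group_counts <- tapply(counts, grp(names(counts)), sum)
    cor_rows <- sf$type == "cor"
    if (any(cor_rows)) {
      pc <- apply(cbind(grp(sf$chan_a[cor_rows]), grp(sf$chan_b[cor_rows])),
                  1, function(p) paste(sort(p), collapse = "-"))
      rep_obj$pair_categories <- table(pc)
    }
  }
  class(rep_obj) <- "electrode_report"
  rep_obj
}

#' @export
print.electrode_report <- function(x, ...) {
  cat("Channel occurrence among selected features (", x$slots,
      " slots, ", x$n_unique, " unique channels)\n", sep = "")
  print(x$counts)
  if (!is.null(x$group_counts)) {
    cat("Slots per channel group:\n")
    print(x$group_counts)
  }
  if (!is.null(x$pair_categories)) {
    cat("Correlation pairs per category:\n")
    print(x$pair_categories)
  }
  invisible(x)
}

#' Two-sample comparison of classification success proportions
#'
#' Treats each classification outcome as a Bernoulli trial and compares
#' the success proportions of two configurations with the standard
#' two-sample z test (normal approximation, variance pooled under the
#' null) and a Wald confidence interval for the difference.
#'
#' @param successes_a,n_a successes and trials in the first sample.
#' @param successes_b,n_b successes and trials in the second sample.
#' @param alpha significance level for the \eqn{1-\alpha} confidence
#'   interval (default 0.05).
#' @return List of class \code{"prop_comparison"}: \code{estimate}
#'   (difference of proportions, a minus b), \code{conf_int},
#'   \code{statistic} (z), \code{p_value} (two-sided), \code{alpha}.
#' @examples
#' prop_compare(90, 100, 50, 100)
#' @export
prop_compare <- function(successes_a, n_a, successes_b, n_b, alpha = 0.05) {
  if (n_a < 1 || n_b < 1) stop("sample sizes must be at least 1", call. = FALSE)
  if (successes_a < 0 || successes_a > n_a || successes_b < 0 ||
      successes_b > n_b)
    stop("successes must lie between 0 and the sample size", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  pa <- successes_a / n_a
  pb <- successes_b / n_b
  pp <- (successes_a + successes_b) / (n_a + n_b)
  se0 <- sqrt(pp * (1 - pp) * (1 / n_a + 1 / n_b))
  z <- if (se0 == 0) 0 else (pa - pb) / se0
  p <- 2 * stats::pnorm(-abs(z))
  se <- sqrt(pa * (1 - pa) / n_a + pb * (1 - pb) / n_b)
  zc <- stats::qnorm(1 - alpha / 2)
  structure(list(estimate = pa - pb,
                 conf_int = c(pa - pb - zc * se, pa - pb + zc * se),
                 statistic = z, p_value = min(p, 1), alpha = alpha),
            class = "prop_comparison")
}

#' @export
print.prop_comparison <- function(x, digits = 4, ...) {
  cat("Two-sample proportion comparison\n")
  cat(sprintf("  difference: %.*f  [%0.*f, %0.*f] (%.0f%% CI)\n", digits,
              x$estimate, digits, x$conf_int[1], digits, x$conf_int[2],
              100 * (1 - x$alpha)))
  cat(sprintf("  z = %.*f, two-sided p = %.4g\n", digits, x$statistic,
              x$p_value))
  invisible(x)
}
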