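#' Z-score normalisation of a series
#'
#' Centres and scales a channel to mean 0 and standard deviation 1,
#' \eqn{(x - \bar x)/\sigma_x}, using the population convention
#' (divide by \eqn{n}).  Every channel is normalised this way before
#' decomposition, which makes all downstream wavelet features invariant
#' to per-channel gain.
#'
#' @param x numeric series with at least 2 samples and nonzero variance.
#' @param context optional string (channel/trial) used in error messages.
#' @return Numeric series with mean 0 and population sd 1.
#' @export
zscore <- function(x, context = NULL) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("series must have at least 2 samples", call. = FALSE)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0)
    stop("zero-variance series",
         if (!is.null(context)) paste0(" (", context, ")") else "",
         ": cannot z-normalise", call. = FALSE)
  (x - m) / s
}

# default level count for feature extraction: the largest j for which the
# non-boundary coefficient count M_j = N - L_j + 1 is at least 2, capped at
# the safe-level bound (at N = 2^k exactly, the safe bound admits a level
# with a single non-boundary coefficient, too short for a variance)
feature_max_level <- function(N, L) {
  J <- max_safe_level(N, L)
  while (J > 1L && N - level_filter_width(J, L) + 1L < 2L) J <- J - 1L
  J
}

# non-boundary index range at level j: t = L_j - 1 .. N - 1 (0-based),
# i.e. M_j = N - L_j + 1 coefficients
nonboundary_idx <- function(d, j) {
  Lj <- d$Lj[j]
  Mj <- d$N - Lj + 1L
  if (Mj < 2)
    stop("series too short at level ", j, ": only ", max(Mj, 0L),
         " non-boundary coefficients (L_j = ", Lj, ", N = ", d$N, ")",
         call. = FALSE)
  seq.int(Lj, d$N)
}

#' Wavelet variance at one level
#'
#' The average squared wavelet coefficient at level \code{j}, restricted
#' to the \eqn{M_j = N - L_j + 1} non-boundary coefficients (those not
#' affected by the circular wrap-around):
#' \eqn{V^2_{X,j} = M_j^{-1} \sum_{t=L_j-1}^{N-1} \widetilde W^2_{X,j,t}}.
#' This estimates the contribution of the level-\eqn{j} octave band to
#' the variance of the series.
#'
#' @param d a \code{"modwt"} decomposition.
#' @param j level, 1..\code{d$J}.
#' @return Non-negative number.
#' @export
wave_variance <- function(d, j) {
  stopifnot(inherits(d, "modwt"))
  j <- check_level(d, j)
  w <- d$W[[j]][nonboundary_idx(d, j)]
  mean(w^2)
}

#' Wavelet correlation between two channels at one level
#'
#' Pearson correlation of the non-boundary wavelet coefficients of two
#' channels at the same level: a measure of band-limited linear coupling
#' between the channels in the level-\eqn{j} octave band.  Always in
#' \eqn{[-1, 1]}.
#'
#' @param dx,dy \code{"modwt"} decompositions of two channels computed
#'   with the same filter, length and number of levels.
#' @param j level, 1..J.
#' @return Number in \eqn{[-1, 1]}.
#' @export
wave_correlation <- function(dx, dy, j) {
  stopifnot(inherits(dx, "modwt"), inherits(dy, "modwt"))
  if (dx$N != dy$N || dx$J != dy$J || dx$filter != dy$filter)
    stop("decompositions are not comparable (different N, J or filter)",
         call. = FALSE)
  j <- check_level(dx, j)
  idx <- nonboundary_idx(dx, j)
  wx <- dx$W[[j]][idx]
  wy <- dy$W[[j]][idx]
  if (stats::sd(wx) == 0 || stats::sd(wy) == 0)
    stop("undefined correlation at level ", j,
         ": constant coefficient segment", call. = FALSE)
  r <- stats::cor(wx, wy)
  max(-1, min(1, r))
}

check_level <- function(d, j) {
  j <- as.integer(j)
  if (length(j) != 1L || is.na(j) || j < 1L || j > d$J)
    stop("level must be in 1..", d$J, call. = FALSE)
  j
}

#' Feature catalog
#'
#' Enumerates the candidate feature set for \code{P} channels and
#' \code{J} levels in a fixed deterministic order: all wavelet variances
#' (channel-major, level-minor), then all same-level pairwise wavelet
#' correlations (level-major, channel pairs in lexicographic order of
#' index).  With both feature types the catalog holds
#' \eqn{J(P + P(P-1)/2)} entries — 22,176 for 63 channels and 11 levels.
#'
#' @param channels channel names (character) or a channel count.
#' @param J number of decomposition levels.
#' @param type feature types to include: \code{"var"}, \code{"cor"} or
#'   \code{"both"}.
#' @return A data frame of class \code{"feature_catalog"} with columns
#'   \code{feature} (name, \code{"type_levelj_chanA[_chanB]"}),
#'   \code{type}, \code{level}, \code{chan_a}, \code{chan_b} (\code{NA}
#'   for variances).
#' @examples
#' nrow(feature_catalog(63, 11, "both"))   # 22176
#' @export
feature_catalog <- function(channels, J, type = c("both", "var", "cor")) {
  type <- match.arg(type)
  if (is.numeric(channels)) {
    if (length(channels) != 1L || channels < 1)
      stop("channel count must be a positive integer", call. = FALSE)
    channels <- sprintf("ch%02d", seq_len(channels))
  }
  P <- length(channels)
  J <- as.integer(J)
  if (J < 1) stop("J must be at least 1", call. = FALSE)
  rows <- list()
  if (type %in% c("both", "var")) {
    rows$var <- data.frame(
      type = "var",
      level = rep(seq_len(J), times = P),
      chan_a = rep(channels, each = J),
      chan_b = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (type %in% c("both", "cor") && P >= 2) {
    pairs <- utils::combn(P, 2)
    npair <- ncol(pairs)
    rows$cor <- data.frame(
      type = "cor",
      level = rep(seq_len(J), each = npair),
      chan_a = rep(channels[pairs[1, ]], times = J),
      chan_b = rep(channels[pairs[2, ]], times = J),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    stop("catalog is empty: correlations require at least 2 channels",
         call. = FALSE)
  cat_df <- do.call(rbind, rows)
  rownames(cat_df) <- NULL
  cat_df <- cbind(feature = ifelse(
    cat_df$type == "var",
    sprintf("var_l%d_%s", cat_df$level, cat_df$chan_a),
    sprintf("cor_l%d_%s_%s", cat_df$level, cat_df$chan_a, cat_df$chan_b)),
    cat_df)
  cat_df$feature <- as.character(cat_df$feature)
  class(cat_df) <- c("feature_catalog", "data.frame")
  cat_df
}

#' Extract wavelet features from one trial
#'
#' Z-normalises each channel, decomposes it with the MODWT, and fills the
#' feature vector in catalog order with per-level wavelet variances and
#' same-level cross-channel wavelet correlations.
#'
#' @param trial numeric matrix, channels in rows (rownames are channel
#'   names) and time samples in columns.
#' @param filter wavelet filter name or object.
#' @param n.levels number of decomposition levels.
#' @param type \code{"both"}, \code{"var"} or \code{"cor"}.
#' @param trial_id optional identifier used in error messages.
#' @return Named numeric vector, one value per catalog entry.
#' @seealso [feature_catalog()], [extract_feature_matrix()].
#' @export
extract_features <- function(trial, filter = "la6", n.levels = NULL,
                             type = c("both", "var", "cor"),
                             trial_id = NULL) {
  type <- match.arg(type)
  trial <- as.matrix(trial)
  P <- nrow(trial)
  N <- ncol(trial)
  chans <- rownames(trial)
  if (is.null(chans)) chans <- sprintf("ch%02d", seq_len(P))
  f <- as_wavelet_filter(filter)
  if (is.null(n.levels)) n.levels <- feature_max_level(N, f$L)
  decs <- vector("list", P)
  for (p in seq_len(P)) {
    ctx <- paste0("channel ", chans[p],
                  if (!is.null(trial_id)) paste0(", trial ", trial_id) else "")
    z <- zscore(trial[p, ], context = ctx)
    decs[[p]] <- modwt(z, f, n.levels = n.levels)
  }
  names(decs) <- chans
  cat_df <- feature_catalog(chans, n.levels, type)
  vals <- numeric(nrow(cat_df))
  ia <- match(cat_df$chan_a, chans)
  ib <- match(cat_df$chan_b, chans)
  for (k in seq_len(nrow(cat_df))) {
    vals[k] <- if (cat_df$type[k] == "var")
      wave_variance(decs[[ia[k]]], cat_df$level[k])
    else
      wave_correlation(decs[[ia[k]]], decs[[ib[k]]], cat_df$level[k])
  }
  names(vals) <- cat_df$feature
  vals
}

#' Extract the feature matrix for a collection of trials
#'
#' Applies [extract_features()] to every trial and stacks the results into
#' an \eqn{n \times p} matrix (one row per trial, catalog order in the
#' columns).
#'
#' @param trials list of channel-by-time matrices with identical channel
#'   sets and lengths.
#' @inheritParams extract_features
#' @return List with \code{X} (feature matrix) and \code{catalog}
#'   (the [feature_catalog()] describing the columns).
#' @export
extract_feature_matrix <- function(trials, filter = "la6", n.levels = NULL,
                                   type = c("both", "var", "cor")) {
  type <- match.arg(type)
  stopifnot(is.list(trials), length(trials) > 0)
  ids <- names(trials)
  if (is.null(ids)) ids <- as.character(seq_along(trials))
  f <- as_wavelet_filter(filter)
  if (is.null(n.levels)) n.levels <- feature_max_level(ncol(trials[[1]]), f$L)
  n.levels <- as.integer(n.levels)
  # warn at most once for the whole collection if levels overrun the bound
  rows <- withCallingHandlers(
    lapply(seq_along(trials), function(i)
      extract_features(trials[[i]], f, n.levels, type, trial_id = ids[i])),
    warning = function(w) {
      if (grepl("maximum safe level", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (length(trials) > 0) {
    Jmax <- max_safe_level(ncol(trials[[1]]), f$L)
    if (n.levels > Jmax)
      warning("n.levels = ", n.levels, " exceeds the maximum safe level ",
              Jmax, " for these trials", call. = FALSE)
  }
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  chans <- rownames(trials[[1]])
  if (is.null(chans)) chans <- sprintf("ch%02d", seq_len(nrow(trials[[1]])))
  list(X = X, catalog = feature_catalog(chans, n.levels, type))
}
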