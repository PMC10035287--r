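#' Maximum safe MODWT decomposition level
#'
#' The largest level \eqn{J} for which the level-\eqn{J} equivalent filter,
#' of width \eqn{L_J = (2^J - 1)(L - 1) + 1}, still fits inside the series,
#' i.e. the largest integer strictly below \eqn{\log_2(N/(L-1) + 1)}.
#' Levels beyond this bound contain no coefficient free of circular
#' boundary wrap-around.
#'
#' @param N series length (samples).
#' @param L filter length, or a \code{"wavelet_filter"} object.
#' @return Integer, the maximum safe decomposition level.
#' @examples
#' max_safe_level(5500, 2)   # 12 for the Haar filter
#' max_safe_level(5500, 6)   # 10 for d6 / la6 / c6
#' @export
max_safe_level <- function(N, L) {
  if (inherits(L, "wavelet_filter")) L <- L$L
  if (!is.numeric(N) || length(N) != 1L || !is.numeric(L) || length(L) != 1L)
    stop("N and L must be single numbers", call. = FALSE)
  if (L < 2) stop("filter length L must be at least 2", call. = FALSE)
  if (N < L) stop("series length N (", N, ") is smaller than the filter length L (",
                  L, ")", call. = FALSE)
  bound <- log2(N / (L - 1) + 1)
  J <- ceiling(bound) - 1L
  as.integer(J)
}

# width of the level-j equivalent filter
level_filter_width <- function(j, L) (2^j - 1L) * (L - 1L) + 1L

# circular filtering step of the pyramid algorithm: y_t = sum_l f_l x_{t - 2^{j-1} l mod N}
.circ_filter <- function(x, f, stride) {
  N <- length(x)
  y <- numeric(N)
  idx <- seq_len(N)
  for (l in seq_along(f)) {
    shift <- ((l - 1L) * stride) %% N
    # x_{t - shift mod N} as a vector over t = 1..N
    y <- y + f[l] * x[((idx - 1L - shift) %% N) + 1L]
  }
  y
}

#' Maximal overlap discrete wavelet transform
#'
#' Decomposes a series of length \eqn{N} into \eqn{J} levels of wavelet
#' (detail) coefficients plus final scaling coefficients, each of length
#' \eqn{N} (the transform is non-decimated), using circular (mod
#' \eqn{N}) boundary treatment.  Level \eqn{j} of the transform captures
#' the octave frequency band roughly \eqn{[f_s/2^{j+1}, f_s/2^j]}.
#' The transform preserves energy
#' (\eqn{\sum_j \|\widetilde W_j\|^2 + \|\widetilde V_J\|^2 = \|x\|^2})
#' and commutes with circular shifts of the input.
#'
#' Computed by the pyramid algorithm: the level-\eqn{j} coefficients are
#' obtained by filtering the level-\eqn{(j-1)} scaling coefficients with
#' the base MODWT filters upsampled by \eqn{2^{j-1}}; this is equivalent
#' to direct circular convolution of the input with the explicit
#' level-\eqn{j} equivalent filters of width \eqn{L_j = (2^j-1)(L-1)+1}.
#'
#' @param x numeric series (all values finite).
#' @param filter filter name or \code{"wavelet_filter"} object; see
#'   [wavelet_filter()].
#' @param n.levels number of detail levels \eqn{J} (default: the maximum
#'   safe level for \code{length(x)} and the filter).  Requesting more
#'   levels than [max_safe_level()] allows emits a warning, not an error:
#'   the extra levels are computed but consist entirely of
#'   boundary-affected coefficients.
#' @return An object of class \code{"modwt"}: a list with \code{W} (list
#'   of \eqn{J} numeric vectors of wavelet coefficients), \code{V} (final
#'   scaling coefficients), \code{N}, \code{J}, \code{filter} (name),
#'   \code{L} and \code{Lj} (per-level equivalent-filter widths).
#' @examples
#' d <- modwt(c(1, 2, 3, 4), "haar", n.levels = 1)
#' d$W[[1]]   # (-1.5, 0.5, 0.5, 0.5)
#' d$V        # ( 2.5, 1.5, 2.5, 3.5)
#' @export
modwt <- function(x, filter = "la6", n.levels = NULL) {
  f <- as_wavelet_filter(filter)
  x <- as.numeric(x)
  N <- length(x)
  if (N < 2) stop("series must have at least 2 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("series contains non-finite values", call. = FALSE)
  if (is.null(n.levels)) n.levels <- max_safe_level(N, f$L)
  J <- as.integer(n.levels)
  if (J < 1) stop("n.levels must be at least 1", call. = FALSE)
  Jmax <- if (N >= f$L) max_safe_level(N, f$L) else 0L
  if (J > Jmax)
    warning("n.levels = ", J, " exceeds the maximum safe level ", Jmax,
            " for N = ", N, " and filter '", f$name,
            "'; levels beyond it hold only boundary-affected coefficients",
            call. = FALSE)
  mf <- modwt_filter(f)
  W <- vector("list", J)
  v <- x
  for (j in seq_len(J)) {
    stride <- 2L^(j - 1L)
    W[[j]] <- .circ_filter(v, mf$h, stride)
    v <- .circ_filter(v, mf$g, stride)
  }
  structure(list(W = W, V = v, N = N, J = J, filter = f$name, L = f$L,
                 Lj = level_filter_width(seq_len(J), f$L)),
            class = "modwt")
}

#' @export
print.modwt <- function(x, ...) {
  cat("MODWT decomposition: N =", x$N, ", J =", x$J,
      "levels, filter '", x$filter, "'\n")
  en <- vapply(x$W, function(w) sum(w^2), numeric(1))
  cat("  detail energy by level:", format(en, digits = 4), "\n")
  cat("  scaling energy:", format(sum(x$V^2), digits = 4), "\n")
  invisible(x)
}

#' @export
plot.modwt <- function(x, ...) {
  J <- x$J
  graphics::par(mfrow = c(J + 1, 1), mar = c(1.5, 4, 0.5, 1))
  for (j in seq_len(J))
    graphics::plot(x$W[[j]], type = "l", ylab = paste0("W", j), xlab = "", ...)
  graphics::plot(x$V, type = "l", ylab = paste0("V", J), xlab = "t", ...)
  invisible(x)
}
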