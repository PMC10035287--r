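# Quadrature filter tables, DWT convention: scaling filter g sums to sqrt(2)
# and has unit energy; wavelet filter h derived by the quadrature-mirror rule
# h_l = (-1)^l g_{L-1-l}.  Scaling coefficients are the standard published
# Daubechies / symlet / coiflet tables (extremal-phase ordering).  The
# order-3 least-asymmetric (symlet) filter coincides with the Daubechies
# filter of the same length, so "la6" shares the d6 table.
.filter_g <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  d4 = c(0.48296291314453416, 0.83651630373780790,
         0.22414386804201339, -0.12940952255126037),
  d6 = c(0.33267055295008263, 0.80689150931109257,
         0.45987750211849157, -0.13501102001025458,
         -0.08544127388202666, 0.03522629188570953),
  d8 = c(0.23037781330889650, 0.71484657055291564,
         0.63088076792985890, -0.02798376941685985,
         -0.18703481171909309, 0.03084138183556076,
         0.03288301166688520, -0.01059740178506903),
  la6 = c(0.33267055295008263, 0.80689150931109257,
          0.45987750211849157, -0.13501102001025458,
          -0.08544127388202666, 0.03522629188570953),
  c6 = c(-0.07273261951252645, 0.33789766245748100,
         0.85257202021160061, 0.38486484686485783,
         -0.07273261951252645, -0.01565572813579199)
)

#' Wavelet filters
#'
#' Returns one of the six supported quadrature filter pairs in the DWT
#' convention: the scaling (low-pass) coefficients \code{g} sum to
#' \eqn{\sqrt 2}, the wavelet (high-pass) coefficients \code{h} sum to zero,
#' both have unit energy, and \eqn{h_l = (-1)^l g_{L-1-l}}.
#'
#' Supported filters: \code{"haar"} (length 2), the Daubechies
#' extremal-phase filters \code{"d4"}, \code{"d6"}, \code{"d8"} (lengths
#' 4, 6, 8), the least-asymmetric (symlet) filter of length 6
#' \code{"la6"}, and the coiflet of length 6 \code{"c6"}.
#'
#' @param name filter identifier, one of \code{"haar"}, \code{"d4"},
#'   \code{"d6"}, \code{"d8"}, \code{"la6"}, \code{"c6"}.
#' @return An object of class \code{"wavelet_filter"}: a list with elements
#'   \code{name}, \code{L} (filter length), \code{g} and \code{h}.
#' @examples
#' f <- wavelet_filter("d4")
#' sum(f$g)    # sqrt(2)
#' sum(f$h)    # 0
#' @seealso [modwt_filter()] for the MODWT-rescaled pair, [modwt()].
#' @export
wavelet_filter <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% names(.filter_g)))
    stop("unsupported filter '", paste(name, collapse = ","),
         "'; supported filters are: ",
         paste(names(.filter_g), collapse = ", "), call. = FALSE)
  g <- .filter_g[[name]]
  L <- length(g)
  l <- seq_len(L) - 1L
  h <- (-1)^l * rev(g)
  structure(list(name = name, L = L, g = g, h = h),
            class = "wavelet_filter")
}

#' @export
print.wavelet_filter <- function(x, ...) {
  cat("Wavelet filter '", x$name, "' (L = ", x$L, ")\n", sep = "")
  cat("  g:", format(x$g, digits = 6), "\n")
  cat("  h:", format(x$h, digits = 6), "\n")
  invisible(x)
}

#' MODWT rescaling of a wavelet filter
#'
#' The MODWT uses the DWT filter pair divided by \eqn{\sqrt 2} at each
#' level, so that the base filters satisfy \eqn{\sum \tilde g_l = 1},
#' \eqn{\sum \tilde h_l = 0} and \eqn{\sum \tilde g_l^2 = \sum \tilde
#' h_l^2 = 1/2}.  This rescaling is what makes the transform
#' energy-preserving without decimation.
#'
#' @param f a \code{"wavelet_filter"} object (see [wavelet_filter()]), or a
#'   filter name.
#' @return A list with elements \code{name}, \code{L}, \code{g} and
#'   \code{h}: the rescaled pair \eqn{(\tilde g, \tilde h) = (g/\sqrt 2,
#'   h/\sqrt 2)}.
#' @examples
#' modwt_filter("haar")$h   # c(1/2, -1/2)
#' @export
modwt_filter <- function(f) {
  f <- as_wavelet_filter(f)
  list(name = f$name, L = f$L, g = f$g / sqrt(2), h = f$h / sqrt(2))
}

as_wavelet_filter <- function(f) {
  if (inherits(f, "wavelet_filter")) return(f)
  wavelet_filter(f)
}

#' Names of the supported wavelet filters
#' @return Character vector of the six supported filter identifiers.
#' @export
wavelet_filter_names <- function() names(.filter_g)
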