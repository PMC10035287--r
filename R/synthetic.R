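#' Configuration for the synthetic two-class trial generator
#'
#' Describes a two-class multichannel dataset with controllable
#' band-limited cross-channel coupling and band-power differences.  The
#' \code{"study"} profile mirrors the motor-imagery recording setup the
#' method targets: 200 trials per class, 63 channels, 5500 samples at
#' 1000 Hz.  The \code{"test"} profile (8 channels, 512 samples) keeps
#' unit tests fast while preserving the same statistical structure.
#'
#' @param profile \code{"study"} or \code{"test"} baseline dimensions.
#' @param n_trials_per_class trials generated for each of the two classes.
#' @param channels number of channels \eqn{P}.
#' @param n_samples samples per trial \eqn{N}.
#' @param fs sampling rate in Hz.
#' @param coupled_pairs data frame with columns \code{chan_a},
#'   \code{chan_b} (channel indices), \code{band_low}, \code{band_high}
#'   (Hz, inside \eqn{(0, f_s/2)}), \code{coupling_class0},
#'   \code{coupling_class1}: each row adds a shared band-limited latent
#'   source to both channels with a class-dependent amplitude (in units
#'   of the noise sd; values in \eqn{[-1, 1]}).
#' @param power_effects data frame with columns \code{chan},
#'   \code{band_low}, \code{band_high}, \code{gain_class0},
#'   \code{gain_class1}: adds an independent band-limited component to
#'   one channel with class-dependent amplitude, creating a band-power
#'   (wavelet-variance) difference.
#' @param noise_sd standard deviation of the white background noise
#'   (must be positive).
#' @param seed integer seed; identical configurations generate
#'   bit-identical datasets.
#' @return A \code{"synth_config"} list.
#' @seealso [synth_dataset()]
#' @export
synth_config <- function(profile = c("study", "test"),
                         n_trials_per_class = NULL, channels = NULL,
                         n_samples = NULL, fs = 1000,
                         coupled_pairs = NULL, power_effects = NULL,
                         noise_sd = 1, seed = 1L) {
  profile <- match.arg(profile)
  base <- switch(profile,
    study = list(n_trials_per_class = 200L, channels = 63L, n_samples = 5500L),
    test  = list(n_trials_per_class = 20L, channels = 8L, n_samples = 512L))
  cfg <- list(
    n_trials_per_class = as.integer(n_trials_per_class %||% base$n_trials_per_class),
    channels = as.integer(channels %||% base$channels),
    n_samples = as.integer(n_samples %||% base$n_samples),
    fs = fs,
    coupled_pairs = coupled_pairs,
    power_effects = power_effects,
    noise_sd = noise_sd,
    seed = as.integer(seed))
  if (cfg$n_trials_per_class < 1 || cfg$channels < 1 || cfg$n_samples < 8)
    stop("invalid dimensions in synthetic configuration", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive", call. = FALSE)
  check_band <- function(lo, hi) {
    if (any(lo <= 0) || any(hi >= cfg$fs / 2) || any(lo >= hi))
      stop("bands must satisfy 0 < low < high < fs/2 = ", cfg$fs / 2,
           call. = FALSE)
  }
  if (!is.null(coupled_pairs)) {
    need <- c("chan_a", "chan_b", "band_low", "band_high",
              "coupling_class0", "coupling_class1")
    stopifnot(all(need %in% names(coupled_pairs)))
    check_band(coupled_pairs$band_low, coupled_pairs$band_high)
    if (any(abs(c(coupled_pairs$coupling_class0,
                  coupled_pairs$coupling_class1)) > 1))
      stop("couplings must lie in [-1, 1]", call. = FALSE)
    if (any(coupled_pairs$chan_a == coupled_pairs$chan_b) ||
        any(c(coupled_pairs$chan_a, coupled_pairs$chan_b) > cfg$channels))
      stop("coupled pairs must name two distinct existing channels",
           call. = FALSE)
  }
  if (!is.null(power_effects)) {
    need <- c("chan", "band_low", "band_high", "gain_class0", "gain_class1")
    stopifnot(all(need %in% names(power_effects)))
    check_band(power_effects$band_low, power_effects$band_high)
    if (any(power_effects$chan > cfg$channels))
      stop("power effects must name existing channels", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# zero-phase band-pass of unit-sd white noise, renormalised to sd 1
.band_source <- function(N, band, fs) {
  bf <- signal::butter(4, c(band[1], band[2]) / (fs / 2), type = "pass")
  s <- signal::filtfilt(bf, stats::rnorm(N))
  s / stats::sd(s)
}

#' Octave band of a MODWT level
#'
#' Level \eqn{j} of the transform captures approximately the frequency
#' band \eqn{[f_s/2^{j+1}, f_s/2^j]} Hz.
#'
#' @param j decomposition level (vectorised).
#' @param fs sampling rate in Hz.
#' @return Two-column matrix of band edges (low, high) in Hz.
#' @export
level_band <- function(j, fs) {
  cbind(low = fs / 2^(j + 1), high = fs / 2^j)
}

#' Levels whose octave band overlaps a frequency band
#'
#' @param band_low,band_high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param J number of levels considered.
#' @return Integer vector of overlapping levels.
#' @export
band_levels <- function(band_low, band_high, fs, J) {
  j <- seq_len(J)
  lb <- level_band(j, fs)
  j[lb[, "low"] < band_high & lb[, "high"] > band_low]
}

#' Generate a synthetic two-class multichannel dataset
#'
#' Each trial is independent Gaussian noise per channel; each configured
#' coupled pair additionally receives a shared band-limited latent source
#' (band-pass-filtered white noise, drawn independently per trial) added
#' to both channels with a class-dependent amplitude, so the pair shows
#' genuine stochastic correlation at the wavelet levels covering the
#' band; configured power effects add an independent band-limited
#' component to a single channel with class-dependent amplitude.
#' Generation is fully determined by \code{cfg$seed}.
#'
#' @param cfg a [synth_config()].
#' @return A \code{"synth_dataset"} list: \code{trials} (named list of
#'   channel-by-time matrices), \code{labels} (factor,
#'   \code{"classA"}/\code{"classB"}, balanced), \code{channel_names},
#'   \code{config}, and \code{ground_truth} — a data frame naming, for
#'   every configured effect, the channels involved and the wavelet
#'   levels (octave bands) where the class difference lives.
#' @export
synth_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  P <- cfg$channels
  N <- cfg$n_samples
  chans <- sprintf("ch%02d", seq_len(P))
  n_per <- cfg$n_trials_per_class
  labels <- factor(rep(c("classA", "classB"), each = n_per))
  n <- length(labels)
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- as.integer(labels[i] == "classB")  # 0 for classA, 1 for classB
    m <- matrix(stats::rnorm(P * N, sd = cfg$noise_sd), nrow = P,
                dimnames = list(chans, NULL))
    cp <- cfg$coupled_pairs
    if (!is.null(cp)) for (k in seq_len(nrow(cp))) {
      amp <- if (cls == 0) cp$coupling_class0[k] else cp$coupling_class1[k]
      s <- .band_source(N, c(cp$band_low[k], cp$band_high[k]), cfg$fs)
      add <- amp * cfg$noise_sd * s
      m[cp$chan_a[k], ] <- m[cp$chan_a[k], ] + add
      m[cp$chan_b[k], ] <- m[cp$chan_b[k], ] + add
    }
    pe <- cfg$power_effects
    if (!is.null(pe)) for (k in seq_len(nrow(pe))) {
      amp <- if (cls == 0) pe$gain_class0[k] else pe$gain_class1[k]
      if (amp != 0) {
        b <- .band_source(N, c(pe$band_low[k], pe$band_high[k]), cfg$fs)
        m[pe$chan[k], ] <- m[pe$chan[k], ] + amp * cfg$noise_sd * b
      }
    }
    trials[[i]] <- m
  }
  names(trials) <- sprintf("trial%03d", seq_len(n))
  gt <- .ground_truth(cfg, chans)
  structure(list(trials = trials, labels = labels, channel_names = chans,
                 config = cfg, ground_truth = gt),
            class = "synth_dataset")
}

.ground_truth <- function(cfg, chans) {
  Jmax <- floor(log2(cfg$n_samples))
  rows <- list()
  cp <- cfg$coupled_pairs
  if (!is.null(cp)) for (k in seq_len(nrow(cp))) {
    lv <- band_levels(cp$band_low[k], cp$band_high[k], cfg$fs, Jmax)
    rows[[length(rows) + 1L]] <- data.frame(
      effect = "coupling",
      chan_a = chans[cp$chan_a[k]], chan_b = chans[cp$chan_b[k]],
      band_low = cp$band_low[k], band_high = cp$band_high[k],
      levels = paste(lv, collapse = ","),
      class0 = cp$coupling_class0[k], class1 = cp$coupling_class1[k],
      stringsAsFactors = FALSE)
  }
  pe <- cfg$power_effects
  if (!is.null(pe)) for (k in seq_len(nrow(pe))) {
    lv <- band_levels(pe$band_low[k], pe$band_high[k], cfg$fs, Jmax)
    rows[[length(rows) + 1L]] <- data.frame(
      effect = "power",
      chan_a = chans[pe$chan[k]], chan_b = NA_character_,
      band_low = pe$band_low[k], band_high = pe$band_high[k],
      levels = paste(lv, collapse = ","),
      class0 = pe$gain_class0[k], class1 = pe$gain_class1[k],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(effect = character(), chan_a = character(),
                      chan_b = character(), band_low = numeric(),
                      band_high = numeric(), levels = character(),
                      class0 = numeric(), class1 = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("Synthetic dataset:", length(x$trials), "trials,",
      length(x$channel_names), "channels,",
      ncol(x$trials[[1]]), "samples at", x$config$fs, "Hz\n")
  print(table(x$labels))
  if (nrow(x$ground_truth)) {
    cat("Ground-truth effects:\n")
    print(x$ground_truth, row.names = FALSE)
  } else cat("No class effects (null dataset)\n")
  invisible(x)
}
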