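#' Write a trial collection to disk
#'
#' Writes one comma-delimited matrix per trial (header row of channel
#' names, one row per time sample) plus a manifest table with columns
#' \code{trial_id}, \code{path} (relative to the manifest's directory)
#' and \code{label}.  For synthetic datasets the ground-truth table is
#' written alongside as \code{ground_truth.csv}.
#'
#' @param dataset a \code{"synth_dataset"}, or a list with elements
#'   \code{trials} (named list of channel-by-time matrices) and
#'   \code{labels}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @seealso [read_trials()]
#' @export
write_trials <- function(dataset, dir) {
  stopifnot(is.list(dataset$trials), length(dataset$trials) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- names(dataset$trials)
  if (is.null(ids)) ids <- sprintf("trial%03d", seq_along(dataset$trials))
  paths <- paste0(ids, ".csv")
  for (i in seq_along(ids)) {
    m <- t(dataset$trials[[i]])  # samples in rows, channels in columns
    utils::write.csv(m, file.path(dir, paths[i]), row.names = FALSE)
  }
  manifest <- data.frame(trial_id = ids, path = paths,
                         label = as.character(dataset$labels),
                         stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  if (!is.null(dataset$ground_truth) && nrow(dataset$ground_truth))
    utils::write.csv(dataset$ground_truth,
                     file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(mpath)
}

#' Read a trial collection from a manifest
#'
#' Reads the manifest (columns \code{trial_id}, \code{path},
#' \code{label}; paths resolved relative to the manifest's directory) and
#' every per-trial delimited matrix.  All trials must share the same
#' channel set and length; channels are re-aligned by name to the order
#' of the first trial, so a permuted header is tolerated.
#'
#' @param manifest path to the manifest file.
#' @return List with \code{trials} (named list of channel-by-time
#'   matrices), \code{labels} (factor) and \code{channel_names}.
#' @export
read_trials <- function(manifest) {
  if (!file.exists(manifest))
    stop("manifest not found: ", manifest, call. = FALSE)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("trial_id", "path", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  base <- dirname(manifest)
  trials <- vector("list", nrow(man))
  chans <- NULL
  N <- NULL
  for (i in seq_len(nrow(man))) {
    fp <- file.path(base, man$path[i])
    if (!file.exists(fp))
      stop("trial file missing: ", fp, " (trial ", man$trial_id[i], ")",
           call. = FALSE)
    m <- as.matrix(utils::read.csv(fp, check.names = FALSE))
    if (is.null(chans)) {
      chans <- colnames(m)
      N <- nrow(m)
    } else {
      if (nrow(m) != N)
        stop("trial ", man$trial_id[i], " has ", nrow(m),
             " samples; expected ", N, " (", fp, ")", call. = FALSE)
      if (!setequal(colnames(m), chans))
        stop("trial ", man$trial_id[i], " has a different channel set (",
             fp, ")", call. = FALSE)
      m <- m[, chans, drop = FALSE]
    }
    trials[[i]] <- t(m)
  }
  names(trials) <- man$trial_id
  list(trials = trials, labels = factor(man$label), channel_names = chans)
}
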