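#' Sleep-stage label set
#'
#' Canonical stage labels used throughout the package: AASM stages plus an
#' anesthesia state and an explicit unknown.
#' @export
STAGES <- c("W", "N1", "N2", "N3", "REM", "ANESTHESIA", "UNKNOWN")

#' Construct a multichannel recording
#'
#' A recording holds a channels-by-samples numeric matrix in microvolts, the
#' sampling rate, and per-channel labels and roles. All downstream analyses
#' (spectra, slope tracks, slow-wave detection, connectivity) consume this
#' container.
#'
#' @param data numeric matrix, channels x samples (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param channel_roles character vector over \{"EEG","iEEG","EMG","EOG","ECG"\}.
#' @return an object of class \code{"recording"}.
#' @export
recording <- function(data, fs, channel_labels = NULL, channel_roles = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric channels x samples matrix")
  stopifnot_scalar(fs, "fs")
  if (fs <= 0) stop("'fs' must be positive")
  nch <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- paste0("EEG", seq_len(nch))
  if (is.null(channel_roles)) channel_roles <- rep("EEG", nch)
  if (length(channel_labels) != nch || length(channel_roles) != nch)
    stop("channel labels/roles must match the number of channels")
  bad <- setdiff(channel_roles, c("EEG", "iEEG", "EMG", "EOG", "ECG"))
  if (length(bad)) stop("unknown channel roles: ", paste(bad, collapse = ", "))
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 channel_roles = channel_roles),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(sprintf("%s[%s]", x$channel_labels, x$channel_roles),
                           collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param x a \code{recording}.
#' @export
duration <- function(x) ncol(x$data) / x$fs

#' Construct a hypnogram
#'
#' One stage label per fixed-length scoring epoch (30 s by convention).
#'
#' @param labels character vector of stage labels (see \code{\link{STAGES}}).
#' @param epoch_sec epoch length in seconds.
#' @return an object of class \code{"hypnogram"}.
#' @export
hypnogram <- function(labels, epoch_sec = 30) {
  labels <- as.character(labels)
  if (!length(labels)) stop("hypnogram must be non-empty")
  bad <- setdiff(unique(labels), STAGES)
  if (length(bad)) stop("unknown stage labels: ", paste(bad, collapse = ", "))
  stopifnot_scalar(epoch_sec, "epoch_sec")
  structure(list(labels = labels, epoch_sec = epoch_sec), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = intersect(STAGES, unique(x$labels))))
  cat(sprintf("<hypnogram> %d epochs x %g s\n", length(x$labels), x$epoch_sec))
  print(tab)
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' Map stages to an ordinal depth-of-synchronization scale
#'
#' Rank correlations between slope and hypnogram need an ordinal coding of
#' stage. The default follows increasing cortical synchronization:
#' W=0, REM=1, N1=2, N2=3, N3=4. The mapping is configurable because scoring
#' conventions differ.
#'
#' @param hyp a \code{hypnogram}.
#' @param depth_map named numeric vector giving the ordinal code per stage.
#' @return numeric vector, one depth per epoch (NA for unmapped stages).
#' @export
stage_depth <- function(hyp, depth_map = c(W = 0, REM = 1, N1 = 2, N2 = 3, N3 = 4)) {
  unname(depth_map[hyp$labels])
}
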