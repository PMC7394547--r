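# File input/output: array-container and EDF recordings, plain-text
# hypnograms, CSV exports, and montage/re-referencing utilities.

#' Write a recording to the array container
#'
#' Two files: \code{<path>.csv} with one column per channel (samples in rows)
#' and \code{<path>.json} with the sampling rate, channel labels and roles,
#' and optional metadata such as the generator seed.
#'
#' @param rec a \code{\link{recording}}.
#' @param path file path prefix (no extension).
#' @param meta optional named list merged into the sidecar.
#' @return invisibly, the two file paths.
#' @export
write_recording <- function(rec, path, meta = NULL) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  m <- t(rec$data)
  colnames(m) <- rec$channel_labels
  utils::write.csv(m, csv, row.names = FALSE)
  side <- c(list(fs = rec$fs, channel_labels = rec$channel_labels,
                 channel_roles = rec$channel_roles), meta)
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Read a recording
#'
#' \code{array_container}: \code{<path>.csv} + \code{<path>.json} as written
#' by \code{\link{write_recording}}. \code{edf}: a 16-bit European Data
#' Format file; signals stored at different rates are resampled (linear
#' interpolation) to the highest rate present, with a warning.
#'
#' @param path path (prefix for the container, file path for EDF).
#' @param format \code{"auto"} (by extension), \code{"array_container"} or
#'   \code{"edf"}.
#' @return a \code{\link{recording}}.
#' @export
read_recording <- function(path, format = c("auto", "array_container", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "array_container"
  if (format == "edf") return(read_edf(path))
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  for (f in c(csv, js))
    if (!file.exists(f)) stop("missing file: ", f)
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  m <- t(as.matrix(utils::read.csv(csv, check.names = FALSE)))
  dimnames(m) <- NULL
  recording(m, as.numeric(side$fs), side$channel_labels, side$channel_roles)
}

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' Minimal European Data Format writer (16-bit samples, 1 s data records);
#' complements \code{\link{read_edf}} and quantizes each channel over its own
#' physical range. Samples beyond the last whole second are dropped.
#'
#' @param rec a \code{\link{recording}} with integer sampling rate.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF record")
  pmin_ <- apply(rec$data, 1, min); pmax_ <- apply(rec$data, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(pad_field("0", 8), pad_field("synthetic", 80),
                pad_field("slopetrack", 80), pad_field("01.01.00", 8),
                pad_field("00.00.00", 8), pad_field(256 * (1 + ns), 8),
                pad_field("", 44), pad_field(n_rec, 8), pad_field(1, 8),
                pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(c(rec$channel_labels, 16), c(rep("", ns), 80),
                 c(rep("uV", ns), 8),
                 c(formatC(pmin_, digits = 5, format = "g"), 8),
                 c(formatC(pmax_, digits = 5, format = "g"), 8),
                 c(rep("-32768", ns), 8), c(rep("32767", ns), 8),
                 c(rep("", ns), 80), c(rep(fs, ns), 8), c(rep("", ns), 32))
  for (f in fields) {
    w <- as.integer(f[length(f)])
    vals <- f[-length(f)]
    writeChar(paste(vapply(vals, pad_field, "", width = w), collapse = ""),
              con, eos = NULL)
  }
  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * fs + seq_len(fs)
    for (ch in seq_len(ns)) {
      dig <- round((rec$data[ch, idx] - pmin_[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Minimal reader for 16-bit EDF/EDF+ continuous recordings. Signals with
#' differing sampling rates are linearly resampled to the highest rate, with
#' a warning. Annotation channels are ignored.
#'
#' @param path EDF file path.
#' @return a \code{\link{recording}}.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header length (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                       # transducer
  for (i in seq_len(ns)) rd(8)                        # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)                       # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  sig <- lapply(seq_len(ns), function(i) numeric(0))
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little",
                     signed = TRUE)
      if (keep[ch]) sig[[ch]] <- c(sig[[ch]], raw)
    }
  }
  sig <- sig[keep]; labels <- labels[keep]
  pmin_ <- pmin_[keep]; pmax_ <- pmax_[keep]
  dmin_ <- dmin_[keep]; dmax_ <- dmax_[keep]; spr <- spr[keep]
  phys <- lapply(seq_along(sig), function(i)
    pmin_[i] + (sig[[i]] - dmin_[i]) * (pmax_[i] - pmin_[i]) /
      (dmax_[i] - dmin_[i]))
  rates <- spr / rec_dur
  fs <- max(rates)
  if (length(unique(rates)) > 1) {
    warning("signals sampled at different rates; resampling all to ",
            fs, " Hz")
    n_target <- as.integer(round(n_rec * rec_dur * fs))
    phys <- lapply(seq_along(phys), function(i) {
      if (rates[i] == fs) return(phys[[i]])
      stats::approx(seq_along(phys[[i]]) / rates[i], phys[[i]],
                    xout = seq_len(n_target) / fs, rule = 2)$y
    })
  }
  roles <- ifelse(grepl("emg", labels, ignore.case = TRUE), "EMG",
           ifelse(grepl("eog", labels, ignore.case = TRUE), "EOG",
           ifelse(grepl("ecg|ekg", labels, ignore.case = TRUE), "ECG", "EEG")))
  recording(do.call(rbind, phys), fs, labels, roles)
}

# Stage alias table for hypnogram parsing.
stage_alias <- c(
  W = "W", WAKE = "W", WACH = "W", "0" = "W",
  N1 = "N1", NREM1 = "N1", S1 = "N1", "1" = "N1",
  N2 = "N2", NREM2 = "N2", S2 = "N2", "2" = "N2",
  N3 = "N3", NREM3 = "N3", S3 = "N3", S4 = "N3", SWS = "N3", "3" = "N3",
  "4" = "N3",
  REM = "REM", R = "REM", "5" = "REM",
  ANESTHESIA = "ANESTHESIA", A = "ANESTHESIA",
  UNKNOWN = "UNKNOWN", "?" = "UNKNOWN"
)

#' Read a plain-text hypnogram
#'
#' Accepts one stage token per line, or (onset_s, duration_s, stage) triplets
#' (whitespace/comma separated) that are expanded onto the 30 s epoch grid.
#' Tokens are matched case-insensitively against a documented alias table
#' (e.g. NREM3 and SWS map to N3); unknown tokens abort with the offending
#' tokens listed verbatim.
#'
#' @param path text file path.
#' @param epoch_sec epoch length, s.
#' @return a \code{\link{hypnogram}}.
#' @export
read_hypnogram <- function(path, epoch_sec = 30) {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty hypnogram file: ", path)
  parts <- strsplit(lines, "[,[:space:]]+")
  map_token <- function(tok) {
    m <- stage_alias[toupper(tok)]
    if (any(is.na(m)))
      stop("unknown stage tokens: ",
           paste(unique(tok[is.na(m)]), collapse = ", "))
    unname(m)
  }
  if (all(lengths(parts) == 1L)) {
    labs <- map_token(vapply(parts, `[`, "", 1))
  } else if (all(lengths(parts) == 3L)) {
    onset <- as.numeric(vapply(parts, `[`, "", 1))
    dur <- as.numeric(vapply(parts, `[`, "", 2))
    st <- map_token(vapply(parts, `[`, "", 3))
    n_ep <- as.integer(ceiling(max(onset + dur) / epoch_sec))
    labs <- rep("UNKNOWN", n_ep)
    for (i in seq_along(onset)) {
      e0 <- floor(onset[i] / epoch_sec) + 1L
      e1 <- ceiling((onset[i] + dur[i]) / epoch_sec)
      labs[e0:e1] <- st[i]
    }
  } else stop("hypnogram must be one token per line or (onset,duration,stage) triplets")
  hypnogram(labs, epoch_sec = epoch_sec)
}

#' Write a hypnogram as plain text, one label per line
#' @param hyp a \code{\link{hypnogram}}.
#' @param path output path.
#' @export
write_hypnogram <- function(hyp, path) {
  writeLines(hyp$labels, path)
  invisible(path)
}

#' Export a slope track as CSV
#'
#' Long format: segment_start_s, channel, slope, r_squared, band_lo, band_hi,
#' method.
#'
#' @param track a \code{slope_track}.
#' @param path output CSV path.
#' @export
export_track_csv <- function(track, path) {
  nch <- ncol(track$slopes)
  labs <- track$channel_labels %||% paste0("ch", seq_len(nch))
  df <- do.call(rbind, lapply(seq_len(nch), function(ch)
    data.frame(segment_start_s = track$times, channel = labs[ch],
               slope = track$slopes[, ch], r_squared = track$r_squared[, ch],
               band_lo = track$band[1], band_hi = track$band[2],
               method = track$method, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a power spectrum as CSV
#'
#' Long format: channel, freq_hz, power, method, segment_sec.
#'
#' @param psd a \code{power_spectrum}.
#' @param path output CSV path.
#' @export
export_psd_csv <- function(psd, path) {
  df <- do.call(rbind, lapply(seq_len(nrow(psd$power)), function(ch)
    data.frame(channel = psd$channel_labels[ch], freq_hz = psd$freqs,
               power = psd$power[ch, ], method = psd$method,
               segment_sec = psd$segment_sec, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Synthetic 25-channel scalp montage
#'
#' A synthetic 5 x 5 grid layout standing in for a scalp montage template:
#' channel name plus 2-D coordinates, shipped as
#' \code{extdata/montage25_synthetic.csv}. Used for cluster-permutation
#' adjacency and Laplacian referencing.
#'
#' @return data.frame (channel, x, y).
#' @export
montage25 <- function() {
  utils::read.csv(system.file("extdata", "montage25_synthetic.csv",
                              package = "slopetrack"),
                  stringsAsFactors = FALSE)
}

#' Neighbourhood adjacency from a 2-D layout
#'
#' Channels closer than \code{max_dist} are neighbours.
#'
#' @param layout data.frame with columns x, y (one row per channel).
#' @param max_dist neighbour distance threshold, layout units.
#' @return symmetric logical adjacency matrix (diagonal FALSE).
#' @export
adjacency_from_layout <- function(layout, max_dist = 1.1) {
  d <- as.matrix(stats::dist(layout[, c("x", "y")]))
  adj <- d > 0 & d <= max_dist
  dimnames(adj) <- NULL
  adj
}

#' Re-reference a recording
#'
#' Montage robustness tool: common average (mean of EEG-role channels
#' subtracted from each EEG channel), linked mastoids (mean of two named
#' channels), Laplacian (each EEG channel minus the mean of its neighbours)
#' and sequential bipolar derivations. Non-EEG channels pass through
#' unchanged (bipolar keeps them appended).
#'
#' @param rec a \code{\link{recording}}.
#' @param scheme referencing scheme.
#' @param adjacency logical adjacency matrix over channels (Laplacian).
#' @param mastoids length-2 character, channel labels (linked mastoids).
#' @return a re-referenced \code{\link{recording}}.
#' @export
reref <- function(rec, scheme = c("car", "linked_mastoids", "laplacian",
                                  "bipolar"),
                  adjacency = NULL, mastoids = NULL) {
  scheme <- match.arg(scheme)
  eeg <- which(rec$channel_roles %in% c("EEG", "iEEG"))
  dat <- rec$data
  if (scheme == "car") {
    ref <- colMeans(dat[eeg, , drop = FALSE])
    dat[eeg, ] <- sweep(dat[eeg, , drop = FALSE], 2, ref)
  } else if (scheme == "linked_mastoids") {
    if (is.null(mastoids) || length(mastoids) != 2)
      stop("provide two mastoid channel labels")
    mi <- match(mastoids, rec$channel_labels)
    if (anyNA(mi)) stop("mastoid channels not found")
    ref <- colMeans(dat[mi, , drop = FALSE])
    dat[eeg, ] <- sweep(dat[eeg, , drop = FALSE], 2, ref)
  } else if (scheme == "laplacian") {
    if (is.null(adjacency)) stop("Laplacian referencing needs an adjacency matrix")
    orig <- dat
    for (ch in eeg) {
      nb <- intersect(which(adjacency[ch, ]), eeg)
      if (length(nb)) dat[ch, ] <- orig[ch, ] - colMeans(orig[nb, , drop = FALSE])
    }
  } else {                      # bipolar: successive EEG differences
    if (length(eeg) < 2) stop("bipolar referencing needs at least 2 EEG channels")
    pairs <- cbind(eeg[-length(eeg)], eeg[-1])
    bip <- dat[pairs[, 1], , drop = FALSE] - dat[pairs[, 2], , drop = FALSE]
    labs <- paste0(rec$channel_labels[pairs[, 1]], "-",
                   rec$channel_labels[pairs[, 2]])
    other <- setdiff(seq_len(nrow(dat)), eeg)
    return(recording(rbind(bip, dat[other, , drop = FALSE]), rec$fs,
                     c(labs, rec$channel_labels[other]),
                     c(rep("EEG", nrow(bip)), rec$channel_roles[other])))
  }
  recording(dat, rec$fs, rec$channel_labels, rec$channel_roles)
}
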