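# Relating the time-resolved slope to the hypnogram.
#
# The slope track is epoched onto the 30 s scoring grid, discretized, and
# scored against the stage sequence with mutual information. Significance is
# calibrated with block-swap surrogates that preserve the stage composition
# and local autocorrelation of the hypnogram while destroying its alignment
# with the slope.

#' Align a slope track to a hypnogram
#'
#' Produces one slope value per scoring epoch: identical segments when the
#' track spacing equals the epoch length, the mean of the sub-segments when
#' the spacing is an integer divisor. Epochs with any missing slope value are
#' excluded from both series.
#'
#' @param track a \code{slope_track}.
#' @param hyp a \code{\link{hypnogram}}.
#' @param channel channel column of the track to align.
#' @return data.frame with columns \code{epoch}, \code{slope}, \code{stage}
#'   (missing-slope epochs dropped).
#' @export
align_to_hypnogram <- function(track, hyp, channel = 1) {
  ratio <- hyp$epoch_sec / track$segment_sec
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop("track spacing must equal the epoch length or an integer divisor")
  ratio <- as.integer(round(ratio))
  v <- track$slopes[, channel]
  n_full <- length(v) %/% ratio
  n_ep <- min(n_full, length(hyp$labels))
  if (n_ep == 0) stop("no overlapping epochs between track and hypnogram")
  per_epoch <- vapply(seq_len(n_ep), function(e) {
    sub <- v[(e - 1L) * ratio + seq_len(ratio)]
    if (anyNA(sub)) NA_real_ else mean(sub)
  }, 0)
  keep <- !is.na(per_epoch)
  data.frame(epoch = which(keep), slope = per_epoch[keep],
             stage = hyp$labels[which(keep)], stringsAsFactors = FALSE)
}

#' Discretize a continuous series into equal-width bins
#'
#' Bins span [min, max] with equal widths; the maximum is assigned to the top
#' bin. Equal-width binning is invariant to affine transforms of the input.
#'
#' @param values numeric vector with at least \code{n_bins} distinct values.
#' @param n_bins number of bins.
#' @return integer vector of bin labels 1..n_bins.
#' @export
discretize_values <- function(values, n_bins = 5) {
  if (length(unique(values[is.finite(values)])) < n_bins)
    stop("need at least 'n_bins' distinct values to discretize")
  lo <- min(values); hi <- max(values)
  width <- (hi - lo) / n_bins
  pmin(as.integer(floor((values - lo) / width)) + 1L, as.integer(n_bins))
}

#' Mutual information between two discrete series in bits
#'
#' Plug-in estimate from the joint contingency table,
#' MI(X;Y) = sum p(x,y) log2( p(x,y) / (p(x) p(y)) ), with probabilities
#' normalized by their sum and zero-count cells contributing zero.
#' Symmetric, non-negative, bounded by min(H(X), H(Y)).
#'
#' @param x_labels,y_labels equal-length discrete sequences (NA pairs dropped).
#' @return MI in bits.
#' @export
mutual_information <- function(x_labels, y_labels) {
  if (length(x_labels) != length(y_labels))
    stop("'x_labels' and 'y_labels' must have equal length")
  ok <- !is.na(x_labels) & !is.na(y_labels)
  x <- x_labels[ok]; y <- y_labels[ok]
  if (length(x) < 2) stop("need at least 2 complete pairs")
  j <- table(x, y)
  p <- j / sum(j)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Block-swap surrogate hypnograms
#'
#' Builds null stage sequences by randomly rearranging contiguous blocks of
#' the hypnogram, preserving the stage composition exactly and the local
#' autocorrelation structure while destroying the alignment with any
#' co-recorded series. The number of randomization steps S equals the number
#' of distinct stages present (overridable via \code{n_blocks}). Two
#' constructions are provided:
#' \describe{
#'   \item{\code{"swap_ops"} (default)}{S successive swap operations, each
#'     cutting the sequence at a uniformly random interior point and swapping
#'     the two blocks. Under the null this yields a surrogate z that is
#'     closest to nominally calibrated (|z| > 1.96 in about 5 percent of
#'     independent pairings), including for autocorrelated series.}
#'   \item{\code{"block_permute"}}{cuts the sequence into S contiguous blocks
#'     at random interior points and permutes the block order uniformly;
#'     slightly conservative at small S.}
#' }
#'
#' @param hyp a \code{\link{hypnogram}}.
#' @param n_surrogates number of surrogate sequences.
#' @param seed integer seed.
#' @param n_blocks randomization steps S (default: distinct stages present).
#' @param mode surrogate construction, see Details.
#' @return character matrix, n_surrogates x epochs; with S < 2 the original
#'   sequence is returned with a warning.
#' @export
block_swap_surrogates <- function(hyp, n_surrogates = 200, seed = NULL,
                                  n_blocks = NULL,
                                  mode = c("swap_ops", "block_permute")) {
  mode <- match.arg(mode)
  labs <- hyp$labels
  n <- length(labs)
  B <- if (is.null(n_blocks)) length(unique(labs)) else as.integer(n_blocks)
  if (B < 2) {
    warning("fewer than 2 blocks; surrogates identical to the original")
    return(matrix(rep(labs, n_surrogates), nrow = n_surrogates, byrow = TRUE))
  }
  if (n < 2 * B) stop("hypnogram too short for the requested block count")
  with_seed(seed, {
    out <- matrix(NA_character_, n_surrogates, n)
    for (s in seq_len(n_surrogates)) {
      if (mode == "swap_ops") {
        x <- labs
        for (i in seq_len(B)) {
          cut <- sample.int(n - 1L, 1L)
          x <- c(x[(cut + 1L):n], x[1:cut])
        }
        out[s, ] <- x
      } else {
        cuts <- sort(sample(seq_len(n - 1L), B - 1L))
        starts <- c(1L, cuts + 1L)
        ends <- c(cuts, n)
        ord <- sample(B)
        out[s, ] <- unlist(lapply(ord, function(b) labs[starts[b]:ends[b]]),
                           use.names = FALSE)
      }
    }
    out
  })
}

#' Z-score an observed statistic against its surrogate distribution
#'
#' z = (observed - surrogate mean) / surrogate SD, with the two-tailed p-value
#' from the normal CDF. z = 1.96 corresponds to uncorrected two-tailed
#' p = 0.05; z > 2.8 survives Bonferroni correction over 19 channels
#' (0.05/19 = 0.0026).
#'
#' @param observed observed statistic.
#' @param surrogates numeric vector of surrogate statistics (>= 20).
#' @return object of class \code{"surrogate_result"}: observed,
#'   surrogate_mean, surrogate_sd, z, p_two_tailed, n_surrogates, and the two
#'   conventional significance flags.
#' @export
surrogate_zscore <- function(observed, surrogates) {
  if (length(surrogates) < 20) stop("need at least 20 surrogates")
  m <- mean(surrogates); s <- stats::sd(surrogates)
  if (s == 0) stop("zero surrogate standard deviation")
  z <- (observed - m) / s
  structure(list(observed = observed, surrogate_mean = m, surrogate_sd = s,
                 z = z, p_two_tailed = z_to_p_two_tailed(z),
                 n_surrogates = length(surrogates),
                 sig_uncorrected = z >= 1.96, sig_bonferroni19 = z >= 2.8),
            class = "surrogate_result")
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf("<surrogate_result> obs %.4f vs %.4f +/- %.4f (n=%d): z = %.2f, p = %.4g\n",
              x$observed, x$surrogate_mean, x$surrogate_sd, x$n_surrogates,
              x$z, x$p_two_tailed))
  invisible(x)
}

#' Surrogate-calibrated mutual information between slope and hypnogram
#'
#' Convenience composite: discretizes the epoch-aligned slope series into
#' \code{n_bins} equal-width bins, computes its MI with the stage labels, and
#' calibrates against block-swap surrogate hypnograms.
#'
#' @param slope_series numeric vector, one slope per epoch.
#' @param hyp a \code{\link{hypnogram}} of matching length.
#' @param n_surrogates surrogate count.
#' @param n_bins slope discretization bins.
#' @param seed integer seed.
#' @param n_blocks block count forwarded to \code{\link{block_swap_surrogates}}.
#' @return a \code{surrogate_result} with the observed MI.
#' @export
mi_surrogate_test <- function(slope_series, hyp, n_surrogates = 200,
                              n_bins = 5, seed = NULL, n_blocks = NULL) {
  if (length(slope_series) != length(hyp$labels))
    stop("slope series and hypnogram length differ")
  ok <- !is.na(slope_series)
  sl <- discretize_values(slope_series[ok], n_bins)
  labs <- hyp$labels[ok]
  obs <- mutual_information(sl, labs)
  sur <- block_swap_surrogates(hypnogram(labs, hyp$epoch_sec), n_surrogates,
                               seed = seed, n_blocks = n_blocks)
  mis <- apply(sur, 1, function(s) mutual_information(sl, s))
  surrogate_zscore(obs, mis)
}

#' Spearman (partial) correlation between slope and hypnogram depth
#'
#' Ranks the slope series against the ordinal depth-of-synchronization coding
#' of the hypnogram. With a covariate (typically the EMG-channel slope), all
#' three series are ranked and the covariate partialled out of both before
#' correlating; p-values use the r-to-t transform.
#'
#' @param slope_series numeric vector, one value per epoch.
#' @param hyp a \code{\link{hypnogram}}.
#' @param covariate optional numeric covariate series of the same length.
#' @param depth_map stage-to-ordinal mapping (see \code{\link{stage_depth}}).
#' @return list with \code{rho}, \code{p}, and when a covariate is given
#'   \code{partial_rho}, \code{partial_p}; plus \code{n}.
#' @export
correlate_with_hypnogram <- function(slope_series, hyp, covariate = NULL,
                                     depth_map = c(W = 0, REM = 1, N1 = 2,
                                                   N2 = 3, N3 = 4)) {
  depth <- stage_depth(hyp, depth_map)
  ok <- !is.na(slope_series) & !is.na(depth)
  if (!is.null(covariate)) ok <- ok & !is.na(covariate)
  x <- slope_series[ok]; y <- depth[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant series")
  n <- length(x)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  out <- list(rho = unname(ct$estimate), p = ct$p.value, n = n)
  if (!is.null(covariate)) {
    rx <- rank(x); ry <- rank(y); rc <- rank(covariate[ok])
    ex <- stats::lm.fit(cbind(1, rc), rx)$residuals
    ey <- stats::lm.fit(cbind(1, rc), ry)$residuals
    # a covariate collinear with a series leaves nothing to correlate
    pr <- if (stats::sd(ex) < 1e-12 || stats::sd(ey) < 1e-12) 0
          else stats::cor(ex, ey)
    t <- r_to_t(pr, n - 1)   # one df spent on the covariate
    out$partial_rho <- pr
    out$partial_p <- 2 * stats::pt(-abs(t), df = n - 3)
  }
  out
}

#' Per-state slope summaries
#'
#' Mean and SEM of the epoch-aligned slope for each requested state, per
#' channel. States absent from the data are reported as missing, never zero.
#'
#' @param track a \code{slope_track}.
#' @param hyp a \code{\link{hypnogram}}.
#' @param states states to summarize.
#' @param channels channel columns (default all).
#' @return data.frame (state, channel, mean, sem, n_epochs).
#' @export
state_summary <- function(track, hyp, states = c("W", "N3", "REM"),
                          channels = NULL) {
  if (is.null(channels)) channels <- seq_len(ncol(track$slopes))
  out <- do.call(rbind, lapply(channels, function(ch) {
    al <- align_to_hypnogram(track, hyp, channel = ch)
    do.call(rbind, lapply(states, function(st) {
      v <- al$slope[al$stage == st]
      data.frame(state = st,
                 channel = track$channel_labels[ch],
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
                 n_epochs = length(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
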