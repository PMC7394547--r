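# Permutation statistics, cluster correction, effect sizes and threshold
# arithmetic.
#
# Observed test statistics are always the classical ones (paired t,
# Greenhouse-Geisser-corrected repeated-measures F); their null distributions
# come from exchangeability-respecting randomizations: sign flips of paired
# differences, within-subject condition permutations, and subject-level sign
# flips for channel clusters. Monte-Carlo p-values use the add-one convention
# (#exceedances + 1)/(n_perm + 1); exhaustive enumerations use the exact
# count.

perm_result <- function(observed_stat, p_value, n_permutations, effect_size_d,
                        null_summary, exhaustive = FALSE, extra = NULL) {
  structure(c(list(observed_stat = observed_stat, p_value = p_value,
                   n_permutations = n_permutations,
                   effect_size_d = effect_size_d,
                   null_summary = null_summary, exhaustive = exhaustive),
              extra),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> stat = %.4f, p = %.4g (%s, n = %d)",
              x$observed_stat, x$p_value,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations))
  if (!is.na(x$effect_size_d)) cat(sprintf(", d = %.3f", x$effect_size_d))
  cat("\n")
  invisible(x)
}

#' Paired permutation t-test
#'
#' Observed statistic: the paired t on the differences. Null distribution:
#' independent random sign flips of the differences (the exchangeable null for
#' paired data), enumerated exhaustively when 2^n <= n_perm, otherwise
#' Monte-Carlo. Two-tailed.
#'
#' @param x,y paired samples; alternatively pass the differences as \code{x}
#'   and leave \code{y} NULL.
#' @param n_perm permutation count.
#' @param seed integer seed (Monte-Carlo only).
#' @return a \code{permutation_test} with Cohen's d of the differences.
#' @export
permutation_t_paired <- function(x, y = NULL, n_perm = 10000, seed = NULL) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    x - y
  }
  n <- length(d)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(d) == 0) stop("zero-variance differences")
  ss <- sum(d^2)
  t_of_means <- function(m) {
    s2 <- (ss - n * m^2) / (n - 1)
    m / sqrt(s2 / n)
  }
  t_obs <- t_of_means(mean(d))
  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_null <- t_of_means(as.numeric(signs %*% d) / n)
    p <- mean(abs(t_null) >= abs(t_obs) - 1e-12)
    n_used <- 2^n
  } else {
    t_null <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      t_of_means(as.numeric(signs %*% d) / n)
    })
    p <- (sum(abs(t_null) >= abs(t_obs) - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  perm_result(t_obs, p, n_used, mean(d) / stats::sd(d),
              c(mean = mean(t_null), sd = stats::sd(t_null)), exhaustive)
}

# Greenhouse-Geisser epsilon from the conditions' covariance matrix.
gg_epsilon <- function(data) {
  k <- ncol(data)
  S <- stats::cov(data)
  C <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  lam <- Re(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (sum(lam^2) < 1e-24) return(1)   # no within-subject variance: trivially spherical
  sum(lam)^2 / ((k - 1) * sum(lam^2))
}

rm_anova_F <- function(data) {
  n <- nrow(data); k <- ncol(data)
  grand <- mean(data)
  ss_subj <- k * sum((rowMeans(data) - grand)^2)
  ss_cond <- n * sum((colMeans(data) - grand)^2)
  ss_tot <- sum((data - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  scale_ <- max(ss_tot, .Machine$double.eps)
  if (ss_err / scale_ < 1e-12)        # degenerate: no residual variance
    return(if (ss_cond / scale_ < 1e-12) 0 else Inf)
  (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

#' Permutation repeated-measures ANOVA (Greenhouse-Geisser corrected)
#'
#' Observed statistic: the one-way repeated-measures F across conditions, with
#' Greenhouse-Geisser epsilon-adjusted degrees of freedom reported (epsilon is
#' 1 under exact sphericity). Null distribution: condition labels permuted
#' independently within each subject.
#'
#' @param data subjects x conditions numeric matrix, no missing cells,
#'   >= 3 conditions and >= 4 subjects.
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @return a \code{permutation_test}; extra fields \code{gg_epsilon},
#'   \code{df_corrected} (epsilon-scaled numerator/denominator df) and
#'   \code{p_parametric_gg}.
#' @export
permutation_rm_anova <- function(data, n_perm = 10000, seed = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("missing cells are not supported")
  n <- nrow(data); k <- ncol(data)
  if (k < 3) stop("need at least 3 conditions")
  if (n < 4) stop("need at least 4 subjects")
  F_obs <- rm_anova_F(data)
  eps <- gg_epsilon(data)
  df1 <- eps * (k - 1); df2 <- eps * (k - 1) * (n - 1)
  F_null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- t(apply(data, 1, sample))
    rm_anova_F(perm)
  }, 0))
  p <- (sum(F_null >= F_obs - 1e-12) + 1) / (n_perm + 1)
  perm_result(F_obs, p, n_perm, NA_real_,
              c(mean = mean(F_null), sd = stats::sd(F_null)),
              extra = list(gg_epsilon = eps, df_corrected = c(df1, df2),
                           p_parametric_gg = stats::pf(F_obs, df1, df2,
                                                       lower.tail = FALSE)))
}

# Connected components among a set of channels under an adjacency matrix.
components_in <- function(members, adjacency) {
  comp <- integer(0); labs <- integer(length(members)); cur <- 0L
  names(labs) <- members
  visited <- rep(FALSE, length(members))
  for (i in seq_along(members)) {
    if (visited[i]) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (visited[j]) next
      visited[j] <- TRUE; labs[j] <- cur
      nbrs <- which(adjacency[members[j], members] & !visited)
      queue <- c(queue, nbrs)
    }
  }
  labs
}

#' Cluster-based permutation test across channels
#'
#' Paired comparison of two conditions at every channel: channels whose paired
#' t-test passes \code{thresh_p} (two-tailed) are joined into spatial clusters
#' of common effect sign via the adjacency graph; the cluster statistic is the
#' cluster size (maxsize criterion). The null distribution of the maximum
#' cluster size is built by flipping each subject's condition assignment
#' (Monte-Carlo), and each observed cluster receives a corrected p-value
#' against it.
#'
#' @param cond_a,cond_b subjects x channels matrices.
#' @param adjacency square logical/0-1 channel adjacency matrix.
#' @param thresh_p cluster-forming threshold (two-tailed p).
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @return list with \code{clusters} (data.frame: cluster, size, sign,
#'   p_corrected, channels), \code{channel_t}, \code{channel_p},
#'   \code{null_max_size}.
#' @export
cluster_permutation_channels <- function(cond_a, cond_b, adjacency,
                                         thresh_p = 0.05, n_perm = 1000,
                                         seed = NULL) {
  cond_a <- as.matrix(cond_a); cond_b <- as.matrix(cond_b)
  if (!all(dim(cond_a) == dim(cond_b))) stop("condition matrices must match")
  n_ch <- ncol(cond_a)
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != n_ch || ncol(adjacency) != n_ch)
    stop("adjacency must be channels x channels")
  if (!any(adjacency != 0)) stop("empty adjacency")
  n <- nrow(cond_a)
  tcrit <- stats::qt(1 - thresh_p / 2, df = n - 1)
  chan_t <- function(d) {
    m <- colMeans(d)
    s <- apply(d, 2, stats::sd)
    m / (s / sqrt(n))
  }
  clusters_of <- function(tv) {
    out <- list()
    for (sgn in c(1, -1)) {
      members <- which(sgn * tv > tcrit)
      if (!length(members)) next
      labs <- components_in(members, adjacency > 0)
      for (cl in unique(labs))
        out[[length(out) + 1L]] <- list(channels = members[labs == cl],
                                        sign = sgn)
    }
    out
  }
  d_obs <- cond_a - cond_b
  t_obs <- chan_t(d_obs)
  obs_clusters <- clusters_of(t_obs)
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    flip <- sample(c(-1, 1), n, replace = TRUE)
    cls <- clusters_of(chan_t(d_obs * flip))
    if (!length(cls)) 0L else max(vapply(cls, function(c) length(c$channels), 0L))
  }, 0L))
  cl_df <- if (length(obs_clusters)) {
    do.call(rbind, lapply(seq_along(obs_clusters), function(i) {
      sz <- length(obs_clusters[[i]]$channels)
      data.frame(cluster = i, size = sz, sign = obs_clusters[[i]]$sign,
                 p_corrected = (sum(null_max >= sz) + 1) / (n_perm + 1),
                 channels = paste(obs_clusters[[i]]$channels, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(cluster = integer(0), size = integer(0), sign = numeric(0),
                    p_corrected = numeric(0), channels = character(0))
  list(clusters = cl_df, channel_t = t_obs,
       channel_p = 2 * stats::pt(-abs(t_obs), df = n - 1),
       null_max_size = null_max)
}

#' Cohen's d
#'
#' \code{"pooled"}: difference of group means over the pooled SD.
#' \code{"paired_diff"}: mean of the paired differences over their SD. The
#' mode is recorded in the result because the two can differ substantially.
#'
#' @param x,y samples (for \code{paired_diff} they must be paired).
#' @param mode effect-size convention.
#' @return numeric with attribute \code{mode}.
#' @export
cohens_d <- function(x, y, mode = c("pooled", "paired_diff")) {
  mode <- match.arg(mode)
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  d <- if (mode == "pooled") {
    sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    if (sp == 0) stop("zero pooled variance")
    (mean(x) - mean(y)) / sp
  } else {
    if (length(x) != length(y)) stop("paired mode needs equal lengths")
    dd <- x - y
    if (stats::sd(dd) == 0) {
      if (mean(dd) == 0) 0 else stop("zero variance of differences")
    } else mean(dd) / stats::sd(dd)
  }
  structure(d, mode = mode)
}

#' 2x2 chi-squared test with continuity correction
#'
#' Yates-corrected chi-squared (the default reported value) together with the
#' uncorrected statistic; correction ON reproduces printed contingency results
#' for electrode-count tables.
#'
#' @param table 2x2 count matrix.
#' @return list with \code{statistic} (corrected), \code{p_value},
#'   \code{statistic_uncorrected}, \code{p_uncorrected}, \code{expected}.
#' @export
chi2_2x2_yates <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate margins")
  cc <- stats::chisq.test(table, correct = TRUE)
  if (any(cc$expected <= 0)) stop("expected counts must be positive")
  uc <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(cc$statistic), p_value = cc$p.value,
       statistic_uncorrected = unname(uc$statistic),
       p_uncorrected = uc$p.value, expected = cc$expected)
}

#' Correlation-to-t transform
#'
#' t = r sqrt(N - 2) / sqrt(1 - r^2).
#'
#' @param r correlation coefficient, |r| < 1.
#' @param N sample size, >= 3.
#' @return t statistic on N - 2 degrees of freedom.
#' @export
r_to_t <- function(r, N) {
  if (abs(r) >= 1) stop("|r| must be below 1")
  if (N < 3) stop("need N >= 3")
  r * sqrt(N - 2) / sqrt(1 - r^2)
}

#' Bonferroni-corrected alpha threshold
#'
#' @param alpha family-wise alpha.
#' @param m number of comparisons.
#' @return alpha / m.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) stop("'m' must be at least 1")
  alpha / m
}

#' Two-tailed normal p-value for a z-score
#'
#' p = 2 (1 - Phi(|z|)).
#'
#' @param z z-score.
#' @return two-tailed p-value.
#' @export
z_to_p_two_tailed <- function(z) {
  if (!is.finite(z)) stop("'z' must be finite")
  2 * stats::pnorm(-abs(z))
}
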