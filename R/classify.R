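# State discrimination: balanced leave-one-out LDA, logit transforms, and
# the general-linear-model variance decomposition.

# Pooled-covariance linear discriminant with ridge fallback; used when the
# standard fit fails on a singular within-class covariance.
ridge_lda_predict <- function(train_x, train_y, test_x, eps_scale = 1e-6) {
  classes <- levels(train_y)
  p <- ncol(train_x)
  means <- lapply(classes, function(cl) colMeans(train_x[train_y == cl, , drop = FALSE]))
  sw <- matrix(0, p, p)
  for (cl in classes) {
    xc <- scale(train_x[train_y == cl, , drop = FALSE], scale = FALSE)
    sw <- sw + crossprod(xc)
  }
  sw <- sw / (nrow(train_x) - length(classes))
  sw <- sw + diag(eps_scale * max(sum(diag(sw)) / p, 1), p)
  swi <- solve(sw)
  scores <- vapply(seq_along(classes), function(i) {
    m <- means[[i]]
    as.numeric(test_x %*% swi %*% m - 0.5 * t(m) %*% swi %*% m)
  }, numeric(nrow(test_x)))
  classes[max.col(matrix(scores, nrow = nrow(test_x)))]
}

#' Balanced leave-one-out LDA classification
#'
#' Repeated balanced cross-validation: in each repeat every class is randomly
#' subsampled to the minority-class count, then each trial of the balanced set
#' is held out once while a pooled-covariance linear discriminant is trained
#' on the rest and predicts it. Accuracy is the percent correct, averaged over
#' repeats. Works with 1-D features (e.g., the spectral slope, or slow-wave
#' power) and with 2 or 3 classes (chance 50 or 33.3 percent).
#'
#' @param features trials x predictors matrix (or a vector for one predictor).
#' @param labels class labels, 2 or 3 classes, >= 2 trials each.
#' @param n_repeats number of balanced subsampling repeats.
#' @param seed integer seed.
#' @return object of class \code{"classifier_result"}: \code{accuracy}
#'   (percent), \code{logit_accuracy}, \code{per_repeat} accuracies,
#'   \code{n_repeats}, \code{chance_level}, \code{n_per_class}.
#' @export
lda_balanced_cv <- function(features, labels, n_repeats = 50, seed = NULL) {
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  labels <- factor(labels)
  k <- nlevels(labels)
  if (k < 2 || k > 3) stop("need 2 or 3 classes")
  counts <- table(labels)
  if (any(counts < 2)) stop("need at least 2 trials per class")
  m <- min(counts)
  per_repeat <- with_seed(seed, vapply(seq_len(n_repeats), function(r) {
    idx <- unlist(lapply(levels(labels), function(cl)
      sample(which(labels == cl), m)), use.names = FALSE)
    x <- features[idx, , drop = FALSE]
    y <- droplevels(labels[idx])
    stopifnot(all(table(y) == m))    # balanced by construction
    correct <- vapply(seq_along(idx), function(i) {
      pred <- tryCatch({
        fit <- MASS::lda(x[-i, , drop = FALSE], grouping = y[-i])
        as.character(stats::predict(fit, x[i, , drop = FALSE])$class)
      }, error = function(e)
        ridge_lda_predict(x[-i, , drop = FALSE], y[-i], x[i, , drop = FALSE]))
      pred == as.character(y[i])
    }, NA)
    100 * mean(correct)
  }, 0))
  acc <- mean(per_repeat)
  structure(list(accuracy = acc,
                 logit_accuracy = logit_transform(acc / 100),
                 per_repeat = per_repeat, n_repeats = n_repeats,
                 chance_level = 100 / k, n_per_class = m),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("<classifier_result> %.2f%% correct (chance %.1f%%, %d repeats, %d/class)\n",
              x$accuracy, x$chance_level, x$n_repeats, x$n_per_class))
  invisible(x)
}

#' Logit transform of a proportion
#'
#' ln(p / (1 - p)), with p clipped to [eps, 1 - eps] so that perfect
#' proportions stay finite. Used to make accuracies approximately unbounded
#' before averaging across channels.
#'
#' @param p proportion in [0, 1].
#' @param eps clipping bound.
#' @return logit value.
#' @export
logit_transform <- function(p, eps = 1e-4) {
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Inverse logit
#' @param x logit value.
#' @return proportion in (0, 1).
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' GLM decomposition of state by slope and slow-wave power
#'
#' Z-scores both predictors, fits the linear model
#' state ~ slope + so_power (+ slope:so_power), and reports the unique
#' explained variance of every term as eta squared = SS_term / SS_total.
#' Sums of squares use a Type II decomposition by default (each main effect
#' adjusted for the other, the interaction adjusted for both); Type I and
#' Type III are available and the type used is always recorded. For
#' orthogonal predictors all types coincide.
#'
#' @param state binary outcome per trial (0/1 or two-level factor).
#' @param slope,so_power numeric predictors per trial, non-constant.
#' @param include_interaction model the slope x power interaction.
#' @param ss_type 1, 2 or 3.
#' @return object of class \code{"glm_result"}: \code{eta_squared} (named:
#'   slope, so_power, interaction), \code{coefficients},
#'   \code{residual_variance}, \code{ss_type}, \code{n}.
#' @export
glm_state_model <- function(state, slope, so_power, include_interaction = TRUE,
                            ss_type = 2) {
  if (is.factor(state)) state <- as.numeric(state) - 1
  n <- length(state)
  if (n < 10) stop("need at least 10 trials")
  if (stats::sd(slope) == 0 || stats::sd(so_power) == 0)
    stop("predictors must be non-constant")
  df <- data.frame(state = state,
                   slope = as.numeric(scale(slope)),
                   so_power = as.numeric(scale(so_power)))
  fml <- if (include_interaction) state ~ slope * so_power
         else state ~ slope + so_power
  fit <- stats::lm(fml, data = df)
  if (fit$rank < length(stats::coef(fit))) stop("rank-deficient design")
  ss_total <- sum((state - mean(state))^2)
  terms_wanted <- c("slope", "so_power",
                    if (include_interaction) "slope:so_power")
  ss <- if (ss_type == 1) {
    a <- stats::anova(fit)
    stats::setNames(a[terms_wanted, "Sum Sq"], terms_wanted)
  } else {
    a <- car::Anova(fit, type = ss_type)
    stats::setNames(a[terms_wanted, "Sum Sq"], terms_wanted)
  }
  eta <- ss / ss_total
  names(eta) <- c("slope", "so_power",
                  if (include_interaction) "interaction")
  structure(list(eta_squared = eta, coefficients = stats::coef(fit),
                 residual_variance = stats::sigma(fit)^2,
                 ss_type = ss_type, n = n),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> eta2: %s (Type %s SS, n = %d)\n",
              paste(sprintf("%s %.3f", names(x$eta_squared), x$eta_squared),
                    collapse = ", "),
              x$ss_type, x$n))
  invisible(x)
}
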