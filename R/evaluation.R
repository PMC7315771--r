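#' Marginal reliability of trait estimates
#'
#' On a latent scale with unit variance, the sample-level reliability of a
#' set of trait estimates is \eqn{1 - \mathrm{mean}(SE^2)}, the aggregate
#' counterpart of the per-person identity \eqn{r(\theta) = 1 - SE(\theta)^2}.
#'
#' @param se_values per-person standard errors (all positive).
#' @return a scalar \eqn{\le 1}; a warning is emitted if it is negative
#'   (mean squared SE above 1).
#' @examples
#' marginalReliability(rep(0.31, 100))   # 1 - 0.31^2
#' @export
marginalReliability <- function(se_values) {
  if (any(!is.finite(se_values)) || any(se_values <= 0))
    stop("all SE values must be positive and finite")
  r <- 1 - mean(se_values^2)
  if (r < 0) warning("marginal reliability is negative")
  r
}

#' Dichotomize criterion scores at a cutoff
#'
#' @param criterion_scores numeric vector (criterion-questionnaire total
#'   scores).
#' @param cutoff inclusive threshold: scores at or above it are labelled 1.
#' @return integer vector of 0/1 labels.
#' @export
classifyByCriterion <- function(criterion_scores, cutoff = 75) {
  stopifnot(is.numeric(criterion_scores))
  as.integer(criterion_scores >= cutoff)
}

#' Screening metrics at a cutpoint
#'
#' Sensitivity \eqn{TP/(TP+FN)}, specificity \eqn{TN/(TN+FP)} and Youden
#' index (sensitivity + specificity - 1) for classifying \code{scores >=
#' cutpoint} as positive, plus the AUC computed by the rank
#' (Mann-Whitney) formulation with ties counted one half.  The AUC does
#' not depend on the cutpoint and is invariant under strictly monotone
#' transformations of the scores.
#'
#' @param scores numeric test scores (higher = more severe).
#' @param labels binary reference labels (0/1 or logical).
#' @param cutpoint classification threshold, inclusive for positives.
#' @return object of class \code{"screeningMetrics"}: list with
#'   \code{cutpoint}, \code{sensitivity}, \code{specificity},
#'   \code{youden}, \code{auc}.
#' @examples
#' screeningMetrics(c(0, 1, 2, 3), c(0, 0, 1, 1), cutpoint = 1.5)
#' @export
screeningMetrics <- function(scores, labels, cutpoint) {
  labels <- normalizeLabels(labels)
  if (length(unique(labels)) != 2L)
    stop("both classes must be present")
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1L
  sens <- mean(scores[pos] >= cutpoint)
  spec <- mean(scores[!pos] < cutpoint)
  structure(list(cutpoint = cutpoint, sensitivity = sens,
                 specificity = spec, youden = sens + spec - 1,
                 auc = rankAUC(scores, pos)),
            class = "screeningMetrics")
}

#' @export
print.screeningMetrics <- function(x, ...) {
  cat(sprintf(paste0("<screening at cutpoint %.3g: sensitivity %.3f, ",
                     "specificity %.3f, Youden %.3f, AUC %.3f>\n"),
              x$cutpoint, x$sensitivity, x$specificity, x$youden, x$auc))
  invisible(x)
}

normalizeLabels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  l <- as.integer(labels)
  if (anyNA(l) || !all(l %in% c(0L, 1L)))
    stop("labels must be binary (0/1 or logical)")
  l
}

# Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(tie)
rankAUC <- function(scores, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal cutpoint
#'
#' Exhaustive search over the observed scores (each observed value tried
#' as an inclusive threshold): returns the cutpoint maximizing the Youden
#' index, with ties broken toward the lowest cutpoint.
#'
#' @inheritParams screeningMetrics
#' @return list with \code{cutpoint} and \code{metrics} (a
#'   \code{screeningMetrics} at that cutpoint).
#' @export
optimalCutpoint <- function(scores, labels) {
  cand <- sort(unique(scores))
  youd <- vapply(cand, function(ct) {
    m <- screeningMetrics(scores, labels, ct)
    m$youden
  }, numeric(1))
  best <- cand[which.max(youd)]     # first max = lowest cutpoint
  list(cutpoint = best, metrics = screeningMetrics(scores, labels, best))
}

#' Diagnosis-probability and percentile curve
#'
#' Fits a logistic regression of the diagnostic label on the test score
#' and tabulates the empirical percentile rank of each score, the two
#' ingredients of a score-interpretation chart: for any score one can
#' read off the fitted probability of meeting the diagnostic criterion
#' and where that score sits in the sample distribution.
#'
#' @param scores numeric test scores.
#' @param labels binary diagnostic labels.
#' @return object of class \code{"diagnosisCurve"}: list with
#'   \code{intercept}, \code{slope}, \code{p50} (score at fitted
#'   probability one half, \eqn{-intercept/slope}), \code{probability}
#'   (function score -> fitted probability) and \code{percentile}
#'   (function score -> empirical percentile, 0..100).
#' @export
diagnosisCurve <- function(scores, labels) {
  labels <- normalizeLabels(labels)
  if (length(unique(labels)) != 2L)
    stop("both classes must be present")
  if (length(scores) < 50L)
    warning("fewer than 50 observations; the fitted curve will be unstable")
  fit <- stats::glm(labels ~ scores, family = stats::binomial())
  beta <- unname(stats::coef(fit))
  cdf <- stats::ecdf(scores)
  structure(list(
    intercept = beta[1L], slope = beta[2L],
    p50 = -beta[1L] / beta[2L],
    probability = function(s) stats::plogis(beta[1L] + beta[2L] * s),
    percentile = function(s) 100 * cdf(s)),
    class = "diagnosisCurve")
}

#' @export
print.diagnosisCurve <- function(x, ...) {
  cat(sprintf(paste0("<diagnosisCurve: logit(p) = %.3f + %.3f * score; ",
                     "p = 0.5 at score %.3f>\n"),
              x$intercept, x$slope, x$p50))
  invisible(x)
}

#' Per-item response descriptives
#'
#' Sample mean, SD (n-1 denominator), skewness and excess kurtosis
#' (Normal = 0) of the raw category codes, the usual summary table
#' accompanying a calibrated bank.  Constant items get \code{NaN} skewness
#' and kurtosis with a warning.
#'
#' @param responses a \code{\link{responseMatrix}} or matrix of codes.
#' @return data.frame with columns \code{item_id}, \code{mean}, \code{sd},
#'   \code{skewness}, \code{kurtosis}.
#' @export
responseDescriptives <- function(responses) {
  codes <- responseCodes(responses)
  out <- lapply(seq_len(ncol(codes)), function(j) {
    x <- codes[!is.na(codes[, j]), j]
    if (length(x) < 2L)
      stop("item '", colnames(codes)[j], "' has fewer than 2 responses")
    s <- stats::sd(x)
    if (s == 0) {
      warning("item '", colnames(codes)[j],
              "' is constant; skewness/kurtosis undefined")
      sk <- ku <- NaN
    } else {
      z <- (x - mean(x)) / s
      sk <- mean(z^3)
      ku <- mean(z^4) - 3
    }
    data.frame(item_id = colnames(codes)[j], mean = mean(x), sd = s,
               skewness = sk, kurtosis = ku)
  })
  do.call(rbind, out)
}
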