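#' Response-category probabilities
#'
#' Probability of each response category of one item at one or more latent
#' trait values.  Under the GRM, with cumulative curves
#' \eqn{P^*_k(\theta) = \mathrm{logistic}(a(\theta - b_k))},
#' \eqn{P(X = k) = P^*_k - P^*_{k+1}} with \eqn{P^*_0 = 1} and
#' \eqn{P^*_m = 0}.  The GPCM and NRM use divide-by-total (adjacent-category
#' and nominal) logits respectively.
#'
#' @param item an \code{\link{grmItem}} / \code{gpcmItem} / \code{nrmItem}.
#' @param theta numeric vector of latent trait values.
#' @return numeric matrix, \code{length(theta)} rows by \code{m} columns;
#'   each row is nonnegative and sums to 1.
#' @examples
#' categoryProbs(grmItem("i", a = 2, b = c(-0.5, 1)), theta = 0)
#' @export
categoryProbs <- function(item, theta) {
  stopifnot(inherits(item, "itemParameters"), is.numeric(theta))
  if (anyNA(theta) || any(!is.finite(theta)))
    stop("theta must be finite")
  m <- item$n_categories
  nt <- length(theta)
  P <- switch(item$model,
    GRM = {
      # cumulative logistic curves, differenced
      pstar <- stats::plogis(item$a * outer(theta, item$b, `-`))
      cbind(1, pstar) - cbind(pstar, 0)
    },
    GPCM = {
      # z_k = sum_{v<=k} a (theta - d_v), z_0 = 0
      steps <- item$a * outer(theta, item$b, `-`)        # nt x (m-1)
      z <- cbind(0, steps)
      for (k in seq_len(m - 1L) + 1L) z[, k] <- z[, k - 1L] + steps[, k - 1L]
      softmaxRows(z, nt, m)
    },
    NRM = {
      z <- outer(theta, item$a) +
        matrix(item$b, nt, m, byrow = TRUE)
      softmaxRows(z, nt, m)
    },
    stop("unknown model tag: ", item$model))
  # numerical guard: differencing can give tiny negatives at extreme theta
  P[P < 0] <- 0
  P / rowSums(P)
}

softmaxRows <- function(z, nt, m) {
  if (is.null(dim(z))) z <- matrix(z, nt, m)
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# d P_k / d theta, same shape as categoryProbs(); analytic per model
categoryProbDeriv <- function(item, theta) {
  m <- item$n_categories
  nt <- length(theta)
  switch(item$model,
    GRM = {
      pstar <- stats::plogis(item$a * outer(theta, item$b, `-`))
      dstar <- item$a * pstar * (1 - pstar)
      cbind(0, dstar) - cbind(dstar, 0)  # dP_k = dP*_k - dP*_{k+1}
    },
    GPCM = {
      P <- categoryProbs(item, theta)
      zdot <- matrix(item$a * (0:(m - 1L)), nt, m, byrow = TRUE)
      P * (zdot - rowSums(P * zdot))
    },
    NRM = {
      P <- categoryProbs(item, theta)
      zdot <- matrix(item$a, nt, m, byrow = TRUE)
      P * (zdot - rowSums(P * zdot))
    },
    stop("unknown model tag: ", item$model))
}

#' Log-likelihood of a response pattern
#'
#' Sum of log category probabilities over the observed (non-missing)
#' responses; missing entries contribute zero, so an all-missing pattern
#' has log-likelihood 0.
#'
#' @param responses integer vector of 0-based category codes, \code{NA}
#'   for missing, aligned with \code{bank}.
#' @param bank an \code{\link{itemBank}} (or subset) of the same length.
#' @param theta a single finite latent trait value.
#' @return a scalar \eqn{\le 0}.
#' @export
responseLogLik <- function(responses, bank, theta) {
  stopifnot(inherits(bank, "itemBank"), length(theta) == 1L,
            is.finite(theta))
  if (length(responses) != nItems(bank))
    stop("responses and bank lengths differ")
  ll <- 0
  for (j in seq_along(bank)) {
    x <- responses[[j]]
    if (is.na(x)) next
    item <- bank[[j]]
    if (x < 0 || x >= item$n_categories || x != round(x))
      stop("response code ", x, " out of range for item '",
           item$item_id, "' (", item$n_categories, " categories)")
    ll <- ll + log(categoryProbs(item, theta)[1L, x + 1L])
  }
  ll
}
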