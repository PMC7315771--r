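#' Unidimensionality screen via exploratory factor analysis
#'
#' Checks that a set of ordinal items measures a single dominant factor.
#' The inter-item correlation matrix is decomposed, first-factor loadings
#' are taken as the leading eigenvector scaled by the square root of the
#' leading eigenvalue, and items loading below \code{loading_min} in
#' absolute value are dropped; the analysis is then repeated on the
#' survivors (two passes: screen, then confirm).  The screen passes when
#' the ratio of the first to the second eigenvalue reaches
#' \code{ratio_min} and the first factor explains at least
#' \code{variance_min_pct} percent of total variance.
#'
#' @param responses a \code{\link{responseMatrix}} or matrix of codes;
#'   persons with missing values are dropped listwise here.
#' @param loading_min minimum absolute first-factor loading (default 0.30).
#' @param ratio_min minimum first/second eigenvalue ratio (default 3).
#' @param variance_min_pct minimum percent variance of the first factor
#'   (default 20).
#' @param cor_method \code{"pearson"} (raw ordinal codes) or
#'   \code{"polychoric"} (latent-correlation estimate for ordinal data).
#' @param max_rounds maximum removal rounds before the confirmatory pass.
#' @return object of class \code{"unidimReport"}: list with
#'   \code{eigenvalues} (descending, final pass), \code{ratio_1_2},
#'   \code{variance_pct_first}, \code{loadings_first},
#'   \code{removed_items}, \code{passed}.
#' @examples
#' resp <- generateRespondents(300, exampleBank()[1:10], seed = 7)
#' unidimensionalityCheck(resp$responses)$passed
#' @export
unidimensionalityCheck <- function(responses, loading_min = 0.30,
                                   ratio_min = 3, variance_min_pct = 20,
                                   cor_method = c("pearson", "polychoric"),
                                   max_rounds = 2L) {
  cor_method <- match.arg(cor_method)
  codes <- responseCodes(responses)
  codes <- codes[stats::complete.cases(codes), , drop = FALSE]
  if (ncol(codes) < 3L) stop("need at least 3 items")
  if (nrow(codes) < 50L) stop("need at least 50 complete persons")
  constant <- colnames(codes)[apply(codes, 2L, stats::sd) == 0]
  if (length(constant) > 0L)
    stop("correlation matrix is singular; constant items: ",
         paste(constant, collapse = ", "))

  removed <- character(0)
  keep <- colnames(codes)
  for (round in seq_len(max_rounds)) {
    R <- itemCorrelation(codes[, keep, drop = FALSE], cor_method)
    e <- eigen(R, symmetric = TRUE)
    lam <- e$values
    v1 <- e$vectors[, 1L]
    if (sum(v1) < 0) v1 <- -v1          # orient the factor positively
    loadings <- v1 * sqrt(lam[1L])
    names(loadings) <- keep
    low <- keep[abs(loadings) < loading_min]
    if (length(low) == 0L || round == max_rounds) break
    removed <- c(removed, low)
    keep <- setdiff(keep, low)
    if (length(keep) < 3L) stop("fewer than 3 items survive the screen")
  }
  ratio <- lam[1L] / lam[2L]
  var_pct <- 100 * lam[1L] / length(keep)
  structure(list(eigenvalues = lam, ratio_1_2 = ratio,
                 variance_pct_first = var_pct, loadings_first = loadings,
                 removed_items = removed,
                 passed = ratio >= ratio_min &&
                          var_pct >= variance_min_pct),
            class = "unidimReport")
}

#' @export
print.unidimReport <- function(x, ...) {
  cat(sprintf(paste0("<unidimensionality: lambda1/lambda2 = %.2f, ",
                     "first factor %.1f%% variance, %d item(s) removed; %s>\n"),
              x$ratio_1_2, x$variance_pct_first, length(x$removed_items),
              if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' First-to-second eigenvalue ratio
#'
#' @param eigenvalues numeric vector in descending order.
#' @return \code{eigenvalues[1] / eigenvalues[2]}.
#' @export
eigenvalueRatio <- function(eigenvalues) {
  stopifnot(length(eigenvalues) >= 2L)
  eigenvalues[1L] / eigenvalues[2L]
}

itemCorrelation <- function(codes, method) {
  if (method == "pearson") return(stats::cor(codes))
  p <- ncol(codes)
  R <- diag(p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      R[i, j] <- R[j, i] <- polychoricRho(codes[, i], codes[, j])
    }
  }
  dimnames(R) <- list(colnames(codes), colnames(codes))
  R
}

# two-step polychoric correlation: thresholds from the margins, rho by
# maximizing the bivariate-normal cell likelihood
polychoricRho <- function(x, y) {
  tx <- marginThresholds(x)
  ty <- marginThresholds(y)
  tab <- table(factor(x, levels = sort(unique(x))),
               factor(y, levels = sort(unique(y))))
  nll <- function(rho) {
    P <- cellProbs(tx, ty, rho)
    -sum(tab * log(pmax(P, 1e-12)))
  }
  stats::optimize(nll, interval = c(-0.999, 0.999))$minimum
}

marginThresholds <- function(x) {
  cum <- cumsum(table(factor(x, levels = sort(unique(x))))) / length(x)
  stats::qnorm(pmin(pmax(cum[-length(cum)], 1e-6), 1 - 1e-6))
}

cellProbs <- function(tx, ty, rho) {
  ax <- c(-Inf, tx, Inf)
  ay <- c(-Inf, ty, Inf)
  F2 <- outer(ax, ay, Vectorize(function(a, b) pbvn(a, b, rho)))
  nx <- length(ax) - 1L
  ny <- length(ay) - 1L
  F2[2:(nx + 1L), 2:(ny + 1L), drop = FALSE] -
    F2[1:nx, 2:(ny + 1L), drop = FALSE] -
    F2[2:(nx + 1L), 1:ny, drop = FALSE] +
    F2[1:nx, 1:ny, drop = FALSE]
}

# bivariate standard normal CDF by one-dimensional quadrature
pbvn <- function(a, b, rho) {
  if (is.infinite(a) && a < 0 || is.infinite(b) && b < 0) return(0)
  if (is.infinite(a)) return(stats::pnorm(b))
  if (is.infinite(b)) return(stats::pnorm(a))
  f <- function(x) stats::dnorm(x) *
    stats::pnorm((b - rho * x) / sqrt(1 - rho^2))
  stats::integrate(f, -8, a, rel.tol = 1e-8)$value
}

#' S-X2 item-fit statistics
#'
#' Orlando-Thissen summed-score item fit for polytomous items: for every
#' total score \eqn{s}, the model-implied conditional category
#' distribution of item \eqn{j} is obtained from the recursive
#' summed-score (Lord-Wingersky) algorithm applied to the remaining items,
#' and compared with the observed category frequencies among persons with
#' that total score by a Pearson chi-square.  Adjacent total-score groups
#' are merged, from the extremes inward, until every expected cell count
#' reaches \code{collapse_min}; degrees of freedom are the summed
#' (collapsed cells - 1) minus the item's parameter count.
#'
#' Complete response vectors are required (persons with missing values are
#' dropped).
#'
#' @param responses a \code{\link{responseMatrix}} or matrix of codes.
#' @param bank the calibrated \code{\link{itemBank}} for these items.
#' @param grid a \code{\link{thetaGrid}}.
#' @param alpha flagging level: items with \eqn{p < \alpha} are marked as
#'   misfitting (default 0.05).
#' @param collapse_min minimum expected cell count (default 1).
#' @return data.frame with one row per item: \code{item_id}, \code{sx2},
#'   \code{df}, \code{p_value}, \code{flagged}.
#' @export
itemFitSX2 <- function(responses, bank, grid = thetaGrid(), alpha = 0.05,
                       collapse_min = 1) {
  assertThetaGrid(grid)
  codes <- responseCodes(responses)
  codes <- codes[, itemIds(bank), drop = FALSE]
  codes <- codes[stats::complete.cases(codes), , drop = FALSE]
  n <- nrow(codes)
  p <- ncol(codes)
  Q <- length(grid$points)
  probs <- lapply(bank, categoryProbs, grid$points)  # Q x m each
  total <- rowSums(codes)
  smax <- sum(nCategories(bank) - 1L)

  # score distribution over all items, per node: (smax+1) x Q
  S_all <- lwRecursion(probs, smax, Q)
  out <- vector("list", p)
  for (j in seq_len(p)) {
    m <- bank[[j]]$n_categories
    S_minus <- lwRecursion(probs[-j], smax - (m - 1L), Q)
    # E[k | s]: numerator integrates P_jk * S^(-j)_{s-k} over the prior
    scores <- 0:smax
    denom <- as.numeric(S_all %*% grid$weights)          # P(S = s)
    pred <- matrix(0, smax + 1L, m)
    for (k in seq_len(m) - 1L) {
      srows <- scores - k
      valid <- srows >= 0L & srows <= smax - (m - 1L)
      pred[valid, k + 1L] <-
        (S_minus[srows[valid] + 1L, , drop = FALSE] *
           matrix(probs[[j]][, k + 1L], sum(valid), Q, byrow = TRUE)) %*%
        grid$weights
    }
    obs_counts <- matrix(0, smax + 1L, m)
    for (k in seq_len(m) - 1L) {
      tabk <- table(factor(total[codes[, j] == k], levels = scores))
      obs_counts[, k + 1L] <- as.integer(tabk)
    }
    ns <- rowSums(obs_counts)
    cond <- pred / pmax(denom, 1e-300)
    # renormalize guard (recursion is exact up to rounding)
    cond <- cond / pmax(rowSums(cond), 1e-300)
    expected <- cond * ns
    res <- collapseAndChisq(obs_counts, expected, collapse_min,
                            nItemParams(bank[[j]]))
    if (is.na(res$p) && res$df == 0L)
      warning("item '", bank[[j]]$item_id,
              "': too few persons for an S-X2 test")
    out[[j]] <- data.frame(item_id = bank[[j]]$item_id, sx2 = res$stat,
                           df = res$df, p_value = res$p,
                           flagged = isTRUE(res$p < alpha))
  }
  do.call(rbind, out)
}

# Lord-Wingersky recursion: P(summed score = s | theta) for every node.
# probs: list of Q x m matrices. Returns (smax+1) x Q.
lwRecursion <- function(probs, smax, Q) {
  S <- matrix(0, smax + 1L, Q)
  S[1L, ] <- 1
  top <- 0L
  for (pj in probs) {
    m <- ncol(pj)
    Snew <- matrix(0, smax + 1L, Q)
    for (k in seq_len(m) - 1L) {
      rows <- seq_len(top + 1L)
      Snew[rows + k, ] <- Snew[rows + k, ] +
        S[rows, , drop = FALSE] * matrix(pj[, k + 1L], length(rows), Q,
                                         byrow = TRUE)
    }
    S <- Snew
    top <- top + m - 1L
  }
  S
}

collapseAndChisq <- function(obs, expected, collapse_min, n_item_params) {
  ns <- rowSums(obs)
  keep <- ns > 0
  obs <- obs[keep, , drop = FALSE]
  expected <- expected[keep, , drop = FALSE]
  # merge adjacent score groups, working from the extremes inward, until
  # every expected cell reaches the minimum
  repeat {
    if (nrow(obs) <= 1L) break
    mins <- apply(expected, 1L, min)
    if (min(mins) >= collapse_min) break
    i <- which(mins < collapse_min)[1L]
    tgt <- if (i < nrow(obs)) i + 1L else i - 1L
    obs[tgt, ] <- obs[tgt, ] + obs[i, ]
    expected[tgt, ] <- expected[tgt, ] + expected[i, ]
    obs <- obs[-i, , drop = FALSE]
    expected <- expected[-i, , drop = FALSE]
  }
  usable <- expected > 0
  df <- sum(rowSums(usable) - 1L) - n_item_params
  if (df <= 0L || nrow(obs) == 0L)
    return(list(stat = NA_real_, df = 0L, p = NA_real_))
  stat <- sum((obs[usable] - expected[usable])^2 / expected[usable])
  list(stat = stat, df = as.integer(df),
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Differential item functioning by ordinal logistic regression
#'
#' Per item, nested proportional-odds models conditioned on the trait
#' estimate are compared: \code{response ~ theta} against
#' \code{response ~ theta + group + theta:group}.  Effect size is the
#' change in McFadden's pseudo-\eqn{R^2}
#' (\eqn{R^2 = 1 - \ell_{model}/\ell_{intercept}}); an item is flagged
#' when the change reaches \code{threshold}.  Results are invariant to
#' which group is coded as reference.
#'
#' @param responses a \code{\link{responseMatrix}} or matrix of codes.
#' @param theta_hat per-person trait estimates (the conditioning
#'   variable), typically EAP scores from the calibrated bank.
#' @param group binary group labels (factor, character, or 0/1).
#' @param threshold pseudo-\eqn{R^2} change needed to flag (default 0.02,
#'   the conventional negligible/slight boundary).
#' @param grouping optional label recorded in the output (e.g.
#'   \code{"gender"}).
#' @return data.frame with one row per item: \code{item_id},
#'   \code{grouping}, \code{delta_pseudo_r2}, \code{flagged}.
#' @export
difAnalysis <- function(responses, theta_hat, group, threshold = 0.02,
                        grouping = NA_character_) {
  codes <- responseCodes(responses)
  stopifnot(length(theta_hat) == nrow(codes),
            length(group) == nrow(codes))
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("group must have exactly two levels")
  if (min(table(group)) < 25L)
    warning("a group has fewer than 25 persons; DIF tests will be weak")
  out <- vector("list", ncol(codes))
  for (j in seq_len(ncol(codes))) {
    ok <- !is.na(codes[, j]) & !is.na(theta_hat) & !is.na(group)
    d <- data.frame(y = codes[ok, j], th = theta_hat[ok], g = group[ok])
    d$y <- factor(d$y, ordered = TRUE)
    d$y <- droplevels(d$y)
    dr2 <- tryCatch({
      ll0 <- polrLogLik(y ~ 1, d)
      ll1 <- polrLogLik(y ~ th, d)
      ll2 <- polrLogLik(y ~ th * g, d)
      r1 <- 1 - ll1 / ll0
      r2 <- 1 - ll2 / ll0
      max(r2 - r1, 0)
    }, error = function(e) NA_real_)
    out[[j]] <- data.frame(item_id = colnames(codes)[j],
                           grouping = grouping,
                           delta_pseudo_r2 = dr2,
                           flagged = isTRUE(dr2 >= threshold))
  }
  do.call(rbind, out)
}

polrLogLik <- function(formula, data) {
  if (nlevels(data$y) == 2L) {
    # proportional-odds model with two categories is plain logistic
    f <- stats::update(formula, I(as.integer(y) - 1L) ~ .)
    as.numeric(stats::logLik(stats::glm(f, data = data,
                                        family = stats::binomial())))
  } else {
    fit <- MASS::polr(formula, data = data, method = "logistic",
                      Hess = FALSE)
    as.numeric(stats::logLik(fit))
  }
}

#' Discrimination filter
#'
#' Drops items whose slope falls below \code{min_a}; the conventional
#' floor of 0.8 keeps only items informative enough to be worth selecting
#' adaptively.
#'
#' @param bank a GRM/GPCM \code{\link{itemBank}}.
#' @param min_a minimum discrimination (inclusive).
#' @return list with \code{retained} (an \code{itemBank}, original order
#'   preserved) and \code{removed} (character ids).
#' @examples
#' discriminationFilter(exampleBank())$removed   # character(0)
#' @export
discriminationFilter <- function(bank, min_a = 0.8) {
  a <- discriminations(bank)
  keep <- a >= min_a
  if (!any(keep)) stop("no items survive the discrimination filter")
  list(retained = bank[which(keep)], removed = itemIds(bank)[!keep])
}
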