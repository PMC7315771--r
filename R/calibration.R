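#' Marginal-maximum-likelihood EM item calibration
#'
#' Estimates item parameters for one polytomous model from an ordinal
#' response matrix by the standard MML-EM scheme: the latent trait is
#' integrated over a fixed quadrature grid with Normal prior weights
#' (E-step: posterior mass of every person at every node, accumulated into
#' expected category counts per item and node), and each item's parameters
#' are then updated by maximizing its expected complete-data log-likelihood
#' (M-step, quasi-Newton on an unconstrained reparameterization: log slope
#' for GRM/GPCM, log threshold gaps for the GRM so threshold order is
#' preserved by construction).  Missing responses contribute nothing to the
#' likelihood (missing-at-random).
#'
#' Convergence is declared when the relative change in marginal
#' log-likelihood falls below \code{tol_loglik} or the largest absolute
#' parameter change falls below \code{tol_par}; the marginal log-likelihood
#' is non-decreasing across iterations up to M-step numerical slack.
#'
#' @param responses a \code{\link{responseMatrix}} or integer matrix of
#'   0-based codes, persons x items.
#' @param model one of \code{"GRM"}, \code{"GPCM"}, \code{"NRM"}.
#' @param grid a \code{\link{thetaGrid}}; default 81 points on [-4, 4]
#'   with standard Normal weights.
#' @param tol_loglik,tol_par convergence tolerances.
#' @param max_iter maximum EM cycles.
#' @param verbose print the log-likelihood each cycle.
#' @return object of class \code{"calibrationResult"}: list with
#'   \code{bank} (estimated \code{\link{itemBank}}), \code{loglik}
#'   (marginal), \code{loglik_trace}, \code{n_params}, \code{n_iter},
#'   \code{converged}.
#' @examples
#' bank <- exampleBank()[1:5]
#' resp <- generateRespondents(300, bank, seed = 1)
#' fit <- fitMmlEm(resp$responses, "GRM", max_iter = 50)
#' fit$converged
#' @export
fitMmlEm <- function(responses, model = c("GRM", "GPCM", "NRM"),
                     grid = thetaGrid(), tol_loglik = 1e-7,
                     tol_par = 1e-4, max_iter = 500L, verbose = FALSE) {
  model <- match.arg(model)
  assertThetaGrid(grid)
  codes <- responseCodes(responses)
  n <- nrow(codes)
  p <- ncol(codes)
  if (n < 50L)
    warning("fewer than 50 persons; item parameter estimates will be noisy")
  mcat <- apply(codes, 2L, function(x) max(x, na.rm = TRUE) + 1L)
  for (j in seq_len(p)) {
    obs <- unique(codes[!is.na(codes[, j]), j])
    if (length(obs) < 2L)
      stop("item '", colnames(codes)[j],
           "' has a single observed category; cannot be calibrated")
  }
  pars <- lapply(seq_len(p), function(j)
    initItemPars(codes[, j], mcat[j], model, colnames(codes)[j]))

  Q <- length(grid$points)
  logw <- log(grid$weights)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: log-likelihood of each person at each node
    logL <- matrix(0, n, Q)
    logP <- vector("list", p)
    for (j in seq_len(p)) {
      item <- parsToItem(pars[[j]], model, mcat[j], colnames(codes)[j])
      lp <- log(pmax(categoryProbs(item, grid$points), 1e-300))  # Q x m
      logP[[j]] <- lp
      obs <- which(!is.na(codes[, j]))
      logL[obs, ] <- logL[obs, ] + t(lp[, codes[obs, j] + 1L, drop = FALSE])
    }
    lw <- sweep(logL, 2L, logw, `+`)
    mx <- apply(lw, 1L, max)
    post <- exp(lw - mx)
    rs <- rowSums(post)
    ll <- sum(mx + log(rs))
    post <- post / rs
    ll_trace <- c(ll_trace, ll)
    if (verbose) message(sprintf("EM cycle %d: loglik %.4f", iter, ll))

    # M-step: per-item expected-count weighted multinomial fit
    max_change <- 0
    for (j in seq_len(p)) {
      obs <- which(!is.na(codes[, j]))
      r <- rowsumByCategory(post[obs, , drop = FALSE], codes[obs, j],
                            mcat[j])              # Q x m expected counts
      old <- pars[[j]]
      pars[[j]] <- mstepItem(old, r, grid$points, model, mcat[j])
      max_change <- max(max_change, max(abs(pars[[j]] - old)))
    }
    rel <- abs(ll - ll_old) / (abs(ll_old) + 1e-10)
    if (iter > 1L && (rel < tol_loglik || max_change < tol_par)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }

  items <- lapply(seq_len(p), function(j)
    parsToItem(pars[[j]], model, mcat[j], colnames(codes)[j]))
  bank <- itemBank(items)
  structure(list(bank = bank, loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace,
                 n_params = sum(vapply(bank, nItemParams, integer(1))),
                 n_iter = iter, converged = converged, model = model,
                 n_persons = n, grid = grid),
            class = "calibrationResult")
}

#' @export
print.calibrationResult <- function(x, ...) {
  cat(sprintf(
    "<%s calibration: %d items, %d persons, loglik %.2f, %d EM cycles%s>\n",
    x$model, nItems(x$bank), x$n_persons, x$loglik, x$n_iter,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# Q x m matrix of expected counts: sum of posterior masses per node and
# observed category
rowsumByCategory <- function(post, codes, m) {
  r <- matrix(0, ncol(post), m)
  for (k in seq_len(m) - 1L) {
    idx <- which(codes == k)
    if (length(idx) > 0L)
      r[, k + 1L] <- colSums(post[idx, , drop = FALSE])
  }
  r
}

# --- parameter transforms -------------------------------------------------
# Unconstrained working vectors per model:
#   GRM:  (log a, b1, log(b2-b1), ..., log(b_{m-1}-b_{m-2}))
#   GPCM: (log a, d1..d_{m-1})
#   NRM:  (a2..a_m, c2..c_m)

initItemPars <- function(x, m, model, id) {
  x <- x[!is.na(x)]
  cum <- vapply(seq_len(m - 1L), function(k) mean(x >= k), numeric(1))
  cum <- pmin(pmax(cum, 0.02), 0.98)
  b <- -stats::qlogis(cum)                 # rough thresholds under a = 1
  b <- sort(b)
  b <- b + seq(0, 0.01, length.out = m - 1L)  # break exact ties
  switch(model,
         GRM = c(0, b[1L], log(pmax(diff(b), 1e-3))),
         GPCM = c(0, b),
         NRM = c(seq(0.25, 1, length.out = m - 1L), -b))
}

parsToItem <- function(par, model, m, id) {
  switch(model,
    GRM = {
      # clamp the working scale so optim exploration cannot underflow a
      # threshold gap to zero or blow up the slope
      gaps <- exp(pmin(pmax(par[seq_len(m - 2L) + 2L], -12), 12))
      b <- cumsum(c(par[2L], gaps))
      grmItem(id, exp(pmin(pmax(par[1L], -9), 5)), b)
    },
    GPCM = gpcmItem(id, exp(pmin(pmax(par[1L], -9), 5)), par[-1L]),
    NRM = nrmItem(id, c(0, par[seq_len(m - 1L)]),
                  c(0, par[seq_len(m - 1L) + (m - 1L)])))
}

mstepItem <- function(par, r, points, model, m) {
  negQ <- function(p) {
    item <- parsToItem(p, model, m, "tmp")
    lp <- log(pmax(categoryProbs(item, points), 1e-300))
    -sum(r * lp)
  }
  fit <- stats::optim(par, negQ, method = "BFGS",
                      control = list(maxit = 50L, reltol = 1e-10))
  # optim can only improve on the start value; keep old params otherwise
  if (fit$value <= negQ(par)) fit$par else par
}

#' Information criteria of a calibrated model
#'
#' \eqn{AIC = -2\ell + 2p} and \eqn{BIC = -2\ell + p\,\ln N} from the
#' marginal log-likelihood \eqn{\ell}, parameter count \eqn{p} and number
#' of persons \eqn{N}.
#'
#' @param result a \code{calibrationResult}, or a bare log-likelihood.
#' @param n_persons number of persons (taken from \code{result} when
#'   omitted).
#' @param n_params parameter count when \code{result} is a bare number.
#' @return named vector \code{c(AIC, BIC)}.
#' @export
informationCriteria <- function(result, n_persons = NULL, n_params = NULL) {
  if (inherits(result, "calibrationResult")) {
    ll <- result$loglik
    if (is.null(n_params)) n_params <- result$n_params
    if (is.null(n_persons)) n_persons <- result$n_persons
  } else {
    ll <- result
    if (is.null(n_params) || is.null(n_persons))
      stop("n_params and n_persons are required with a bare log-likelihood")
  }
  c(AIC = -2 * ll + 2 * n_params,
    BIC = -2 * ll + n_params * log(n_persons))
}

#' Choose among candidate models by information criteria
#'
#' Picks the model minimizing both criteria when they agree; when AIC and
#' BIC disagree, BIC (the more parsimonious criterion) decides and a
#' warning is emitted.
#'
#' @param aic,bic named numeric vectors over the same models.
#' @return list with \code{selected} (model name) and \code{agreement}
#'   (logical).
#' @export
modelSelection <- function(aic, bic) {
  stopifnot(identical(names(aic), names(bic)), !is.null(names(aic)))
  by_aic <- names(aic)[which.min(aic)]
  by_bic <- names(bic)[which.min(bic)]
  if (by_aic != by_bic)
    warning("AIC prefers ", by_aic, " but BIC prefers ", by_bic,
            "; selecting by BIC")
  list(selected = by_bic, agreement = by_aic == by_bic)
}

#' Fit and compare the three polytomous models
#'
#' Calibrates GRM, GPCM and NRM on identical data and quadrature and
#' compares them by AIC/BIC.
#'
#' @inheritParams fitMmlEm
#' @param models model tags to include.
#' @return object of class \code{"modelComparison"}: list with
#'   \code{table} (data.frame of loglik, n_params, AIC, BIC per model),
#'   \code{selected}, and the fitted \code{calibrationResult}s in
#'   \code{fits}.
#' @export
compareModels <- function(responses, grid = thetaGrid(),
                          models = c("GRM", "GPCM", "NRM"), ...) {
  fits <- lapply(models, function(m) fitMmlEm(responses, m, grid, ...))
  names(fits) <- models
  ic <- t(vapply(fits, informationCriteria, numeric(2)))
  tab <- data.frame(model = models,
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
                    AIC = ic[, "AIC"], BIC = ic[, "BIC"],
                    row.names = NULL)
  sel <- modelSelection(stats::setNames(tab$AIC, models),
                        stats::setNames(tab$BIC, models))
  structure(list(table = tab, selected = sel$selected,
                 agreement = sel$agreement, fits = fits),
            class = "modelComparison")
}

#' @export
print.modelComparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("selected:", x$selected,
      if (!x$agreement) "(AIC/BIC disagreed; BIC decided)" else "", "\n")
  invisible(x)
}
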