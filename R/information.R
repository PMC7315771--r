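#' Fisher information and derived precision measures
#'
#' \code{itemInfo} computes the Fisher information of one polytomous item,
#' \deqn{I_j(\theta) = \sum_k \frac{(\partial P_{jk}/\partial\theta)^2}{P_{jk}(\theta)},}
#' \code{testInfo} the test information \eqn{I(\theta) = \sum_j I_j(\theta)}
#' of a bank, and \code{bankItemInfo} the per-item information vector used
#' for adaptive item selection.
#'
#' @param item an \code{itemParameters} object.
#' @param bank an \code{\link{itemBank}}.
#' @param theta numeric vector of latent trait values.
#' @return \code{itemInfo}/\code{testInfo}: numeric vector along
#'   \code{theta}; \code{bankItemInfo}: named numeric vector, one entry per
#'   item at a single \code{theta}.
#' @examples
#' bank <- exampleBank()
#' seFromInfo(testInfo(bank, 0))   # full-bank SE at the prior mean
#' @export
itemInfo <- function(item, theta) {
  P <- categoryProbs(item, theta)
  dP <- categoryProbDeriv(item, theta)
  ratio <- dP * dP / P
  ratio[P < 1e-300] <- 0   # vanishing categories contribute nothing
  rowSums(ratio)
}

#' @rdname itemInfo
#' @export
testInfo <- function(bank, theta) {
  stopifnot(inherits(bank, "itemBank"))
  info <- numeric(length(theta))
  for (item in bank) info <- info + itemInfo(item, theta)
  info
}

#' @rdname itemInfo
#' @export
bankItemInfo <- function(bank, theta) {
  stopifnot(length(theta) == 1L)
  vapply(bank, itemInfo, numeric(1), theta)
}

#' Standard error and reliability from test information
#'
#' The conditional standard error of measurement is the reciprocal square
#' root of the test information, \eqn{SE(\theta) = 1/\sqrt{I(\theta)}}, and
#' on a latent scale with mean 0 and SD 1 the corresponding reliability is
#' \eqn{r_{xx}(\theta) = 1 - 1/I(\theta)}.  The two satisfy
#' \eqn{r = 1 - SE^2} exactly.
#'
#' @param info positive test information value(s).
#' @return \code{seFromInfo}: \eqn{1/\sqrt{info}}.
#'   \code{reliabilityFromInfo}: \eqn{1 - 1/info}, which is negative when
#'   information is below 1; such values are returned as-is with a warning.
#' @export
seFromInfo <- function(info) {
  if (any(!is.finite(info)) || any(info <= 0))
    stop("non-positive information")
  1 / sqrt(info)
}

#' @rdname seFromInfo
#' @export
reliabilityFromInfo <- function(info) {
  if (any(!is.finite(info)) || any(info <= 0))
    stop("non-positive information")
  r <- 1 - 1 / info
  if (any(r < 0))
    warning("reliability is negative where information < 1")
  r
}

#' Quadrature grid over the latent trait
#'
#' Equally spaced points with Normal prior masses renormalized to sum to 1.
#' The default (81 points on [-4, 4], standard Normal) is used for both
#' calibration and EAP scoring.
#'
#' @param n number of points.
#' @param lower,upper grid range, latent-trait units.
#' @param mean,sd prior Normal moments.
#' @return object of class \code{"thetaGrid"}: list with \code{points}
#'   (strictly increasing) and \code{weights} (sum to 1).
#' @export
thetaGrid <- function(n = 81L, lower = -4, upper = 4, mean = 0, sd = 1) {
  stopifnot(n >= 2L, lower < upper, sd > 0)
  points <- seq(lower, upper, length.out = n)
  w <- stats::dnorm(points, mean, sd)
  structure(list(points = points, weights = w / sum(w)),
            class = "thetaGrid")
}

# --- fast all-GRM information path ---------------------------------------
# Pads each item's thresholds with +Inf so a whole GRM bank becomes two
# rectangular arrays; absent categories then get probability 0 and
# contribute nothing to the information sum.
grmInfoTable <- function(bank) {
  models <- vapply(bank, `[[`, character(1), "model")
  if (!all(models == "GRM")) return(NULL)
  kmax <- max(nCategories(bank)) - 1L
  b <- t(vapply(bank, function(it) {
    out <- rep(Inf, kmax)
    out[seq_along(it$b)] <- it$b
    out
  }, numeric(kmax)))
  list(a = vapply(bank, `[[`, numeric(1), "a"),
       b = matrix(b, nrow = nItems(bank)))
}

# per-item information at a single theta for all (or idx) items at once
grmInfoAt <- function(tab, theta, idx = NULL) {
  a <- tab$a
  b <- tab$b
  if (!is.null(idx)) {
    a <- a[idx]
    b <- b[idx, , drop = FALSE]
  }
  pstar <- stats::plogis(a * (theta - b))         # p x kmax, 0 where padded
  dstar <- a * pstar * (1 - pstar)
  P <- cbind(1, pstar) - cbind(pstar, 0)
  dP <- cbind(0, dstar) - cbind(dstar, 0)
  ratio <- dP * dP / P
  ratio[P < 1e-300] <- 0
  rowSums(ratio)
}

assertThetaGrid <- function(grid) {
  if (!inherits(grid, "thetaGrid"))
    stop("expected a thetaGrid object")
  if (is.unsorted(grid$points, strictly = TRUE))
    stop("grid points must be strictly increasing")
  if (any(grid$weights < 0) || abs(sum(grid$weights) - 1) > 1e-10)
    stop("grid weights must be nonnegative and sum to 1")
  invisible(grid)
}
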