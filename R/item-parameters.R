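#' Item parameter objects for polytomous IRT models
#'
#' Constructors for single-item parameter sets under the three polytomous
#' models supported by the package: the graded response model (GRM), the
#' generalized partial credit model (GPCM) and the nominal response model
#' (NRM).  An item with \eqn{m} response categories is scored
#' \eqn{0, \dots, m-1}.
#'
#' For the GRM the item is described by a discrimination \eqn{a > 0} and
#' \eqn{m - 1} strictly increasing thresholds \eqn{b_1 < \dots < b_{m-1}};
#' the cumulative probability of responding in category \eqn{k} or above is
#' \eqn{P^*_k(\theta) = \mathrm{logistic}(a(\theta - b_k))} (no 1.7 scaling
#' constant).  For the GPCM the item carries a slope \eqn{a > 0} and
#' \eqn{m - 1} step difficulties.  For the NRM each category has its own
#' slope and intercept, with the first category's pair anchored at zero for
#' identifiability.
#'
#' @param item_id single character or numeric identifier.
#' @param a discrimination.  Scalar for GRM/GPCM; for the NRM a vector of
#'   \eqn{m} category slopes whose first element must be 0.
#' @param b numeric vector of \eqn{m - 1} GRM thresholds, strictly
#'   increasing.
#' @param d numeric vector of \eqn{m - 1} GPCM step difficulties.
#' @param c numeric vector of \eqn{m} NRM category intercepts, first
#'   element 0.
#' @return An object of class \code{"itemParameters"}: a list with fields
#'   \code{item_id}, \code{model}, \code{n_categories}, \code{a} and the
#'   model's location parameters.
#' @examples
#' it <- grmItem("x1", a = 1.2, b = c(-0.5, 0.4, 1.3))
#' categoryProbs(it, theta = 0)
#' @export
grmItem <- function(item_id, a, b) {
  stopifnot(length(a) == 1L, is.numeric(a), is.numeric(b), length(b) >= 1L)
  if (!is.finite(a) || a <= 0)
    stop("GRM discrimination 'a' must be a positive finite number")
  if (anyNA(b) || any(!is.finite(b)))
    stop("GRM thresholds must be finite")
  if (is.unsorted(b, strictly = TRUE))
    stop("GRM thresholds must be strictly increasing for item '",
         item_id, "'")
  newItemParameters(item_id, "GRM", n_categories = length(b) + 1L,
                    a = as.numeric(a), b = as.numeric(b))
}

#' @rdname grmItem
#' @export
gpcmItem <- function(item_id, a, d) {
  stopifnot(length(a) == 1L, is.numeric(a), is.numeric(d), length(d) >= 1L)
  if (!is.finite(a) || a <= 0)
    stop("GPCM discrimination 'a' must be a positive finite number")
  newItemParameters(item_id, "GPCM", n_categories = length(d) + 1L,
                    a = as.numeric(a), b = as.numeric(d))
}

#' @rdname grmItem
#' @export
nrmItem <- function(item_id, a, c) {
  stopifnot(is.numeric(a), is.numeric(c), length(a) == length(c),
            length(a) >= 2L)
  if (a[1L] != 0 || c[1L] != 0)
    stop("NRM first-category slope and intercept must be fixed to 0")
  newItemParameters(item_id, "NRM", n_categories = length(a),
                    a = as.numeric(a), b = as.numeric(c))
}

# shared backbone; `b` holds thresholds (GRM), steps (GPCM) or
# intercepts (NRM)
newItemParameters <- function(item_id, model, n_categories, a, b) {
  structure(
    list(item_id = as.character(item_id), model = model,
         n_categories = as.integer(n_categories), a = a, b = b),
    class = "itemParameters")
}

#' @export
print.itemParameters <- function(x, ...) {
  loc <- paste(format(x$b, digits = 3), collapse = ", ")
  cat(sprintf("<%s item '%s': %d categories, a = %s, loc = [%s]>\n",
              x$model, x$item_id, x$n_categories,
              paste(format(x$a, digits = 3), collapse = ","), loc))
  invisible(x)
}

#' Number of free parameters of one calibrated item
#'
#' GRM and GPCM items carry one slope plus \eqn{m-1} location parameters;
#' NRM items carry \eqn{m-1} free slopes and \eqn{m-1} free intercepts.
#'
#' @param item an \code{itemParameters} object.
#' @return integer count.
#' @export
nItemParams <- function(item) {
  m <- item$n_categories
  switch(item$model,
         GRM = m, GPCM = m, NRM = 2L * (m - 1L),
         stop("unknown model tag: ", item$model))
}
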