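#' Item banks
#'
#' An item bank is an ordered collection of \code{\link{grmItem}} /
#' \code{gpcmItem} / \code{nrmItem} parameter objects with unique
#' identifiers.  Items keep their own category counts; banks may mix
#' 3-, 4- and 5-category items (or any other counts).
#'
#' @param items list of \code{itemParameters} objects.
#' @return object of class \code{"itemBank"} (a named list of items).
#' @seealso \code{\link{readItemBank}} for the CSV/JSON interchange format,
#'   \code{\link{exampleBank}} for the packaged 68-item bank.
#' @export
itemBank <- function(items) {
  if (length(items) == 0L) stop("an item bank must contain at least one item")
  ok <- vapply(items, inherits, logical(1), "itemParameters")
  if (!all(ok)) stop("all elements must be itemParameters objects")
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids))
    stop("duplicate item ids: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))
  structure(stats::setNames(items, ids), class = "itemBank")
}

#' @export
`[.itemBank` <- function(x, i) {
  itemBank(unclass(x)[i])
}

#' @rdname itemBank
#' @param bank an \code{itemBank}.
#' @export
nItems <- function(bank) length(bank)

#' @rdname itemBank
#' @export
itemIds <- function(bank) {
  unname(vapply(bank, `[[`, character(1), "item_id"))
}

#' @rdname itemBank
#' @export
nCategories <- function(bank) {
  vapply(bank, `[[`, integer(1), "n_categories")
}

#' Item discriminations of a GRM/GPCM bank
#'
#' @param bank an \code{itemBank} of GRM or GPCM items.
#' @return named numeric vector of slopes.
#' @export
discriminations <- function(bank) {
  models <- vapply(bank, `[[`, character(1), "model")
  if (any(models == "NRM"))
    stop("discriminations() is defined for GRM/GPCM banks only")
  vapply(bank, `[[`, numeric(1), "a")
}

#' @export
print.itemBank <- function(x, ...) {
  m <- table(nCategories(x))
  cat(sprintf("<itemBank: %d items (%s); categories: %s>\n", nItems(x),
              paste(unique(vapply(x, `[[`, character(1), "model")),
                    collapse = "/"),
              paste(sprintf("%sx%s", m, names(m)), collapse = ", ")))
  invisible(x)
}

#' The packaged 68-item separation-anxiety GRM bank
#'
#' Loads the calibrated graded-response-model item bank shipped with the
#' package: 68 separation-anxiety items drawn from six published child and
#' adolescent anxiety questionnaires, with mixed 3/4/5-point response
#' scales, slopes between 0.83 and 1.95 and thresholds spanning roughly
#' \eqn{-1.1} to \eqn{4.4} on the latent scale.  Used throughout the
#' package's examples and simulation studies.
#'
#' @return an \code{itemBank} of 68 GRM items.
#' @examples
#' bank <- exampleBank()
#' testInfo(bank, theta = 0)
#' @export
exampleBank <- function() {
  path <- system.file("extdata", "item_bank_68.csv", package = "gradedCAT",
                      mustWork = TRUE)
  readItemBank(path)
}
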