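#' Response matrices
#'
#' A persons-by-items matrix of ordinal category codes (0-based integers,
#' \code{NA} for missing), with optional person-level grouping columns
#' (e.g. region, gender, age band, health status) carried alongside.
#'
#' @param codes integer matrix, persons in rows, items in columns; column
#'   names are item ids (defaulting to \code{V1..Vp}).
#' @param person_ids optional row identifiers.
#' @param meta optional data.frame of person-level covariates, one row per
#'   person.
#' @param bank optional \code{\link{itemBank}}; when supplied, codes are
#'   validated against each item's category count.
#' @return object of class \code{"responseMatrix"}.
#' @export
responseMatrix <- function(codes, person_ids = NULL, meta = NULL,
                           bank = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("V", seq_len(ncol(codes)))
  if (is.null(person_ids)) {
    person_ids <- if (!is.null(rownames(codes))) rownames(codes)
                  else as.character(seq_len(nrow(codes)))
  }
  rownames(codes) <- person_ids
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != nrow(codes))
      stop("meta must have one row per person")
  }
  neg <- which(!is.na(codes) & codes < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative response code at person '%s', item '%s'",
                 person_ids[neg[1L, 1L]], colnames(codes)[neg[1L, 2L]]))
  x <- structure(list(codes = codes, meta = meta), class = "responseMatrix")
  if (!is.null(bank)) validateCodes(x, bank)
  x
}

validateCodes <- function(responses, bank) {
  codes <- responseCodes(responses)
  ids <- intersect(colnames(codes), itemIds(bank))
  for (id in ids) {
    m <- bank[[id]]$n_categories
    bad <- which(!is.na(codes[, id]) & codes[, id] >= m)
    if (length(bad) > 0L)
      stop(sprintf(
        "response code %d at person '%s', item '%s' exceeds %d categories",
        codes[bad[1L], id], rownames(codes)[bad[1L]], id, m))
  }
  invisible(responses)
}

# accept either a responseMatrix or a bare matrix everywhere
responseCodes <- function(x) {
  if (inherits(x, "responseMatrix")) x$codes
  else if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
    x
  } else stop("expected a responseMatrix or a matrix of codes")
}

responseMeta <- function(x) {
  if (inherits(x, "responseMatrix")) x$meta else NULL
}

#' @export
print.responseMatrix <- function(x, ...) {
  cat(sprintf("<responseMatrix: %d persons x %d items, %d missing%s>\n",
              nrow(x$codes), ncol(x$codes), sum(is.na(x$codes)),
              if (is.null(x$meta)) ""
              else paste0("; meta: ", paste(names(x$meta), collapse = ", "))))
  invisible(x)
}

#' @export
dim.responseMatrix <- function(x) dim(x$codes)

#' @export
`[.responseMatrix` <- function(x, i, j, ..., drop = TRUE) {
  codes <- if (missing(i) && missing(j)) x$codes
           else if (missing(j)) x$codes[i, , drop = drop]
           else if (missing(i)) x$codes[, j, drop = drop]
           else x$codes[i, j, drop = drop]
  if (!is.matrix(codes)) return(codes)   # dropped to a plain code vector
  meta <- x$meta
  if (!is.null(meta) && !missing(i)) meta <- meta[i, , drop = FALSE]
  responseMatrix(codes, meta = meta)
}
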