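#' Read and write item banks
#'
#' The CSV dialect has columns \code{item_id, model, n_categories, a,
#' b1..bK}, one row per item, with trailing threshold cells left blank for
#' items with fewer categories (so a mixed-format bank stays rectangular).
#' NRM items need per-category slope vectors and therefore round-trip
#' through the JSON mirror, which stores each item's full parameter
#' vectors; files ending in \code{.json} are read/written as JSON.
#'
#' @param path file path (\code{.csv} or \code{.json}).
#' @param bank an \code{\link{itemBank}} to write.
#' @return \code{readItemBank}: an \code{itemBank};
#'   \code{writeItemBank}: \code{path}, invisibly.
#' @examples
#' bank <- exampleBank()
#' f <- tempfile(fileext = ".csv")
#' writeItemBank(bank, f)
#' identical(itemIds(readItemBank(f)), itemIds(bank))
#' @export
readItemBank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    return(bankFromList(jsonlite::read_json(path, simplifyVector = TRUE,
                                            simplifyDataFrame = FALSE)))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(item_id = "character"))
  need <- c("item_id", "model", "n_categories", "a", "b1")
  if (!all(need %in% names(df)))
    stop("bank CSV must have columns: ", paste(need, collapse = ", "))
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("b", "", bcols)))]
  items <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    m <- df$n_categories[i]
    b <- as.numeric(df[i, bcols[seq_len(m - 1L)]])
    if (anyNA(b))
      stop(sprintf("row %d (item '%s'): expected %d location parameters",
                   i, df$item_id[i], m - 1L))
    items[[i]] <- switch(df$model[i],
      GRM = tryCatch(grmItem(df$item_id[i], df$a[i], b),
                     error = function(e)
                       stop(sprintf("row %d (item '%s'): %s", i,
                                    df$item_id[i], conditionMessage(e)),
                            call. = FALSE)),
      GPCM = gpcmItem(df$item_id[i], df$a[i], b),
      stop(sprintf("row %d: model '%s' not supported in CSV banks",
                   i, df$model[i])))
  }
  itemBank(items)
}

#' @rdname readItemBank
#' @export
writeItemBank <- function(bank, path) {
  stopifnot(inherits(bank, "itemBank"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lapply(unclass(bank), unclass), path,
                         auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  models <- vapply(bank, `[[`, character(1), "model")
  if (any(models == "NRM"))
    stop("NRM banks must be written as JSON")
  kmax <- max(nCategories(bank)) - 1L
  rows <- lapply(bank, function(item) {
    b <- rep(NA_real_, kmax)
    b[seq_along(item$b)] <- item$b
    data.frame(item_id = item$item_id, model = item$model,
               n_categories = item$n_categories, a = item$a,
               t(b), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df)[-(1:4)] <- paste0("b", seq_len(kmax))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

bankFromList <- function(lst) {
  items <- lapply(lst, function(it) {
    switch(it$model,
           GRM = grmItem(it$item_id, as.numeric(it$a), as.numeric(it$b)),
           GPCM = gpcmItem(it$item_id, as.numeric(it$a), as.numeric(it$b)),
           NRM = nrmItem(it$item_id, as.numeric(it$a), as.numeric(it$b)),
           stop("unknown model tag: ", it$model))
  })
  itemBank(items)
}

#' Read a response matrix from CSV
#'
#' Wide format: one row per person, one column per item, \code{NA} (empty
#' cell) for missing.  An optional \code{person_id} column and any columns
#' named in \code{meta_cols} are carried as metadata rather than responses.
#'
#' @param path CSV file.
#' @param bank optional \code{\link{itemBank}} used to pick the item
#'   columns and validate code ranges.
#' @param one_based set \code{TRUE} for Likert data coded \code{1..m};
#'   codes are shifted down to the package's 0-based convention.
#' @param meta_cols names of person-level covariate columns.
#' @return a \code{\link{responseMatrix}}.
#' @export
readResponses <- function(path, bank = NULL, one_based = FALSE,
                          meta_cols = c("region", "gender", "age",
                                        "health")) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  person_ids <- if ("person_id" %in% names(df)) {
    ids <- as.character(df$person_id); df$person_id <- NULL; ids
  } else as.character(seq_len(nrow(df)))
  meta <- df[intersect(meta_cols, names(df))]
  item_cols <- if (!is.null(bank)) {
    missing_items <- setdiff(itemIds(bank), names(df))
    if (length(missing_items) > 0L)
      stop("response file lacks bank items: ",
           paste(missing_items, collapse = ", "))
    itemIds(bank)
  } else setdiff(names(df), names(meta))
  codes <- as.matrix(df[item_cols])
  if (!is.numeric(codes)) stop("non-numeric response codes in ", path)
  if (one_based) codes <- codes - 1L
  responseMatrix(codes, person_ids = person_ids,
                 meta = if (ncol(meta) > 0L) meta else NULL, bank = bank)
}

#' @rdname readResponses
#' @param responses a \code{responseMatrix} to write.
#' @export
writeResponses <- function(responses, path) {
  codes <- responseCodes(responses)
  meta <- responseMeta(responses)
  df <- data.frame(person_id = rownames(codes), check.names = FALSE)
  if (!is.null(meta)) df <- cbind(df, meta)
  df <- cbind(df, codes)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Lie-detection pair screen
#'
#' Questionnaires sometimes embed reversed twins of existing items as a
#' carelessness check: a respondent answering a statement and its negation
#' with the same raw category is treated as random responding.  A person is
#' removed when, for at least one pair, the raw code on the item equals the
#' raw code on its reversed twin.
#'
#' @param responses a \code{\link{responseMatrix}} (or matrix).
#' @param pairs list of length-2 character vectors
#'   \code{c(item_id, reversed_item_id)}.
#' @return list with \code{kept} (filtered \code{responseMatrix}) and
#'   \code{removed_ids}.
#' @export
liePairFilter <- function(responses, pairs) {
  codes <- responseCodes(responses)
  bad <- rep(FALSE, nrow(codes))
  for (p in pairs) {
    if (length(p) != 2L || !all(p %in% colnames(codes)))
      stop("each pair must name two items present in the responses")
    same <- !is.na(codes[, p[1L]]) & !is.na(codes[, p[2L]]) &
      codes[, p[1L]] == codes[, p[2L]]
    bad <- bad | same
  }
  meta <- responseMeta(responses)
  list(kept = responseMatrix(codes[!bad, , drop = FALSE],
                             meta = if (is.null(meta)) NULL
                                    else meta[!bad, , drop = FALSE]),
       removed_ids = rownames(codes)[bad])
}

#' Listwise deletion
#'
#' Removes every person with a missing value in the named columns (all
#' item and metadata columns by default).
#'
#' @param responses a \code{\link{responseMatrix}}.
#' @param on column names to screen; default all items plus metadata.
#' @return the filtered \code{responseMatrix}.
#' @export
listwiseDelete <- function(responses, on = NULL) {
  codes <- responseCodes(responses)
  meta <- responseMeta(responses)
  all_cols <- if (is.null(meta)) as.data.frame(codes)
              else cbind(as.data.frame(codes), meta)
  if (is.null(on)) on <- names(all_cols)
  unknown <- setdiff(on, names(all_cols))
  if (length(unknown) > 0L)
    stop("unknown columns: ", paste(unknown, collapse = ", "))
  keep <- stats::complete.cases(all_cols[on])
  if (!any(keep)) warning("listwise deletion removed every person")
  responseMatrix(codes[keep, , drop = FALSE],
                 meta = if (is.null(meta)) NULL
                        else meta[keep, , drop = FALSE])
}
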