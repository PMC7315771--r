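#' Four-stage item-screening pipeline
#'
#' Runs the bank-construction screen in the conventional order —
#' unidimensionality, calibration, S-X2 item fit, DIF, discrimination —
#' with each stage consuming the previous stage's surviving items, and
#' returns the final calibrated bank together with a stage-by-stage
#' report of what was removed and why.
#'
#' DIF is checked against every grouping column supplied in
#' \code{groups}; the conditioning trait estimates are EAP scores from
#' the bank as calibrated on the surviving items, recomputed after any
#' removal.
#'
#' @param responses a \code{\link{responseMatrix}} (complete cases are
#'   used for calibration-dependent stages).
#' @param groups optional data.frame of binary grouping columns for DIF
#'   (defaults to the response matrix's metadata).
#' @param model IRT model for calibration (default GRM).
#' @param grid a \code{\link{thetaGrid}}.
#' @param loading_min,ratio_min,variance_min_pct unidimensionality screen
#'   settings.
#' @param sx2_alpha item-fit flagging level.
#' @param dif_threshold pseudo-R2 change needed to flag DIF.
#' @param min_a discrimination floor.
#' @param ... passed to \code{\link{fitMmlEm}}.
#' @return object of class \code{"qcReport"}: list with \code{bank}
#'   (final \code{itemBank}), \code{stages} (data.frame of stage name,
#'   items in, items out), \code{removed} (data.frame of item_id, stage,
#'   rule), \code{unidim}, \code{item_fit}, \code{dif}, \code{calibration}.
#' @export
runQcPipeline <- function(responses, groups = NULL, model = "GRM",
                          grid = thetaGrid(), loading_min = 0.30,
                          ratio_min = 3, variance_min_pct = 20,
                          sx2_alpha = 0.05, dif_threshold = 0.02,
                          min_a = 0.8, ...) {
  codes <- responseCodes(responses)
  if (is.null(groups)) groups <- responseMeta(responses)
  removed <- data.frame(item_id = character(0), stage = character(0),
                        rule = character(0))
  note <- function(ids, stage, rule) {
    if (length(ids) > 0L)
      rbind(removed, data.frame(item_id = ids, stage = stage, rule = rule))
    else removed
  }
  stages <- list()
  mark <- function(stage, n_in, n_out)
    data.frame(stage = stage, items_in = n_in, items_out = n_out)

  # 1. unidimensionality
  n_in <- ncol(codes)
  unidim <- unidimensionalityCheck(codes, loading_min, ratio_min,
                                   variance_min_pct)
  removed <- note(unidim$removed_items, "unidimensionality",
                  sprintf("|loading| < %.2f", loading_min))
  keep <- setdiff(colnames(codes), unidim$removed_items)
  stages[[1L]] <- mark("unidimensionality", n_in, length(keep))

  # 2. calibrate survivors
  fit <- fitMmlEm(codes[, keep, drop = FALSE], model, grid, ...)

  # 3. S-X2 item fit
  fitres <- itemFitSX2(codes[, keep, drop = FALSE], fit$bank, grid,
                       alpha = sx2_alpha)
  bad <- fitres$item_id[fitres$flagged]
  removed <- note(bad, "item_fit", sprintf("S-X2 p < %.2f", sx2_alpha))
  keep <- setdiff(keep, bad)
  stages[[2L]] <- mark("item_fit", nrow(fitres), length(keep))
  if (length(bad) > 0L)
    fit <- fitMmlEm(codes[, keep, drop = FALSE], model, grid, ...)

  # 4. DIF against each grouping
  difres <- NULL
  if (!is.null(groups) && ncol(as.data.frame(groups)) > 0L) {
    groups <- as.data.frame(groups)
    complete <- stats::complete.cases(codes[, keep, drop = FALSE])
    theta_hat <- fullBankScores(codes[complete, keep, drop = FALSE],
                                fit$bank, grid)$theta
    difres <- do.call(rbind, lapply(names(groups), function(g)
      difAnalysis(codes[complete, keep, drop = FALSE], theta_hat,
                  groups[complete, g], dif_threshold, grouping = g)))
    bad <- unique(difres$item_id[difres$flagged])
    removed <- note(bad, "dif",
                    sprintf("delta pseudo-R2 >= %.3g", dif_threshold))
    if (length(bad) > 0L) {
      keep <- setdiff(keep, bad)
      fit <- fitMmlEm(codes[, keep, drop = FALSE], model, grid, ...)
    }
  }
  stages[[3L]] <- mark("dif", stages[[2L]]$items_out, length(keep))

  # 5. discrimination floor
  disc <- discriminationFilter(fit$bank, min_a)
  removed <- note(disc$removed, "discrimination",
                  sprintf("a < %.2f", min_a))
  stages[[4L]] <- mark("discrimination", length(keep),
                       nItems(disc$retained))

  structure(list(bank = disc$retained, stages = do.call(rbind, stages),
                 removed = removed, unidim = unidim, item_fit = fitres,
                 dif = difres, calibration = fit),
            class = "qcReport")
}

#' @export
print.qcReport <- function(x, ...) {
  cat("Item-screening pipeline\n")
  print(x$stages, row.names = FALSE)
  if (nrow(x$removed) > 0L) {
    cat("removed items:\n")
    print(x$removed, row.names = FALSE)
  } else cat("no items removed\n")
  invisible(x)
}

#' Write a QC report to JSON
#'
#' Serializes the stage table, removal list and headline statistics
#' (eigenvalue ratio, variance share, item-fit and DIF tables) for
#' archiving; the final bank itself is written with
#' \code{\link{writeItemBank}}.
#'
#' @param report a \code{qcReport}.
#' @param path output JSON file.
#' @export
writeQcReport <- function(report, path) {
  stopifnot(inherits(report, "qcReport"))
  jsonlite::write_json(list(
    stages = report$stages,
    removed = report$removed,
    unidimensionality = list(
      ratio_1_2 = report$unidim$ratio_1_2,
      variance_pct_first = report$unidim$variance_pct_first,
      passed = report$unidim$passed),
    item_fit = report$item_fit,
    dif = report$dif,
    final_items = itemIds(report$bank)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
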