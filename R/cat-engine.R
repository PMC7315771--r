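#' Expected a posteriori trait estimate
#'
#' Posterior mean and SD of the latent trait over a quadrature grid,
#' \deqn{\hat\theta = \frac{\sum_q \theta_q w_q L(\theta_q)}{\sum_q w_q L(\theta_q)},}
#' with likelihoods accumulated in log space to avoid underflow.  With no
#' observed responses the estimate is the prior mean.
#'
#' @param responses integer vector of 0-based codes (\code{NA} = missing)
#'   aligned with \code{bank}.
#' @param bank an \code{\link{itemBank}} (or subset).
#' @param grid a \code{\link{thetaGrid}}.
#' @return list with \code{theta} (posterior mean) and \code{sd}
#'   (posterior SD).
#' @examples
#' bank <- exampleBank()
#' eapEstimate(rep(0L, 68), bank)$theta   # floor responses, low trait
#' @export
eapEstimate <- function(responses, bank, grid = thetaGrid()) {
  assertThetaGrid(grid)
  stopifnot(length(responses) == nItems(bank))
  logpost <- log(grid$weights)
  for (j in seq_along(bank)) {
    x <- responses[[j]]
    if (is.na(x)) next
    item <- bank[[j]]
    if (x < 0 || x >= item$n_categories)
      stop("response code ", x, " out of range for item '",
           item$item_id, "'")
    logpost <- logpost +
      log(pmax(categoryProbs(item, grid$points)[, x + 1L], 1e-300))
  }
  eapFromLogPost(logpost, grid$points)
}

eapFromLogPost <- function(logpost, points) {
  mx <- max(logpost)
  if (!is.finite(mx))
    stop("posterior mass underflowed to zero; use log-space likelihoods")
  w <- exp(logpost - mx)
  w <- w / sum(w)
  th <- sum(points * w)
  list(theta = th, sd = sqrt(max(sum((points - th)^2 * w), 0)))
}

#' CAT configuration
#'
#' @param se_threshold stop once the information-based SE of the trait
#'   estimate drops below this value; \code{NULL} for no precision rule
#'   (the whole bank is administered).
#' @param max_items test-length cap; defaults to 20 when a precision
#'   threshold is set, otherwise to the bank size at run time.
#' @param grid \code{\link{thetaGrid}} for EAP scoring.
#' @param seed seed for the random first item (its own RNG stream, so it
#'   does not disturb or depend on the caller's RNG state).
#' @param first_item \code{"random"} or the id of a fixed starting item.
#' @return object of class \code{"catConfig"}.
#' @export
catConfig <- function(se_threshold = NULL, max_items = NULL,
                      grid = thetaGrid(), seed = NULL,
                      first_item = "random") {
  if (!is.null(se_threshold) && se_threshold <= 0)
    stop("se_threshold must be positive")
  if (is.null(max_items) && !is.null(se_threshold)) max_items <- 20L
  if (!is.null(max_items) && max_items < 1L)
    stop("max_items must be at least 1")
  assertThetaGrid(grid)
  structure(list(se_threshold = se_threshold, max_items = max_items,
                 grid = grid, seed = seed, first_item = first_item),
            class = "catConfig")
}

#' Maximum-Fisher-information item selection
#'
#' Among unadministered items, returns the one with greatest Fisher
#' information at the current trait estimate; ties break to the lowest
#' bank index.
#'
#' @param theta current trait estimate.
#' @param bank an \code{\link{itemBank}}.
#' @param administered character vector of already-used item ids.
#' @param exclude additional ids to skip (e.g. items without an available
#'   response in post-hoc mode).
#' @return the selected item id.
#' @export
selectNextItem <- function(theta, bank, administered = character(0),
                           exclude = character(0)) {
  ids <- itemIds(bank)
  candidates <- setdiff(ids, c(administered, exclude))
  if (length(candidates) == 0L)
    stop("item bank exhausted; no candidates remain")
  info <- bankItemInfo(bank[candidates], theta)
  candidates[which.max(info)]   # which.max takes the first (lowest index)
}

#' Information-based standard error of a CAT state
#'
#' \eqn{SE = 1/\sqrt{\sum_{j \in administered} I_j(\hat\theta)}}, the
#' precision measure the stopping rule monitors.
#'
#' @param state a \code{catResult} (or any list with \code{administered}
#'   ids and \code{theta} estimate).
#' @param bank the \code{\link{itemBank}} the test was run from.
#' @return the standard error.
#' @export
currentSE <- function(state, bank) {
  if (length(state$administered) == 0L)
    stop("no items administered yet")
  seFromInfo(testInfo(bank[state$administered], state$theta))
}

#' Run one adaptive test
#'
#' Administers items adaptively: a random (seeded) first item, then
#' repeatedly record the response, update the EAP trait estimate, update
#' the information-based SE, check the stopping conditions (SE below
#' threshold, test-length cap, or bank exhausted) and otherwise give the
#' unadministered item with maximum Fisher information at the current
#' estimate.  The stop check runs only after each response, so the minimum
#' test length is 1.
#'
#' @param answers either a named vector of 0-based codes covering the bank
#'   (post-hoc mode, e.g. one row of a \code{\link{responseMatrix}}), or a
#'   function \code{f(item_id)} returning a code (interactive/simulated
#'   mode).  \code{NA} answers cause the item to be skipped in selection,
#'   with a warning.
#' @param bank an \code{\link{itemBank}}.
#' @param config a \code{\link{catConfig}}.
#' @return object of class \code{"catResult"}: list with
#'   \code{administered}, \code{responses}, \code{theta}, \code{se},
#'   \code{posterior_sd}, \code{stop_reason} (\code{"se_met"},
#'   \code{"max_items"} or \code{"bank_exhausted"}) and
#'   \code{trajectory}, a data.frame of (step, item_id, response, theta,
#'   se, posterior_sd).
#' @examples
#' bank <- exampleBank()
#' resp <- generateRespondents(1, bank, seed = 3)
#' run <- runCAT(resp$responses[1, ], bank,
#'               catConfig(se_threshold = 0.4, seed = 11))
#' run$stop_reason
#' @param precomp optional precomputed tables from
#'   \code{catPrecompute(bank, config$grid)}; lets batch callers share
#'   the per-item grid probabilities across many runs.
#' @export
runCAT <- function(answers, bank, config = catConfig(), precomp = NULL) {
  stopifnot(inherits(bank, "itemBank"), inherits(config, "catConfig"))
  ids <- itemIds(bank)
  lookup <- makeAnswerSource(answers, ids)
  max_items <- if (is.null(config$max_items)) nItems(bank)
               else min(config$max_items, nItems(bank))
  grid <- config$grid
  points <- grid$points
  if (is.null(precomp)) precomp <- catPrecompute(bank, grid)
  logprobs <- precomp$logprobs
  info_tab <- precomp$info_tab

  administered <- character(0)
  admin_idx <- integer(0)
  responses <- integer(0)
  excluded <- character(0)
  logpost <- log(grid$weights)
  est <- eapFromLogPost(logpost, points)
  traj <- vector("list", max_items)
  stop_reason <- NA_character_
  warned_na <- FALSE

  next_id <- firstItem(bank, config)
  repeat {
    x <- lookup(next_id)
    if (is.na(x)) {
      if (!warned_na) {
        warning("no response available for item '", next_id,
                "'; skipping it in selection")
        warned_na <- TRUE
      }
      excluded <- c(excluded, next_id)
    } else {
      item <- bank[[next_id]]
      if (x < 0 || x >= item$n_categories)
        stop("response code ", x, " out of range for item '", next_id, "'")
      administered <- c(administered, next_id)
      admin_idx <- c(admin_idx, match(next_id, ids))
      responses <- c(responses, as.integer(x))
      logpost <- logpost + logprobs[[next_id]][, x + 1L]
      est <- eapFromLogPost(logpost, points)
      se <- if (is.null(info_tab))
              seFromInfo(testInfo(bank[administered], est$theta))
            else seFromInfo(sum(grmInfoAt(info_tab, est$theta, admin_idx)))
      traj[[length(administered)]] <-
        data.frame(step = length(administered), item_id = next_id,
                   response = as.integer(x), theta = est$theta, se = se,
                   posterior_sd = est$sd)
      if (!is.null(config$se_threshold) && se < config$se_threshold) {
        stop_reason <- "se_met"
        break
      }
      if (length(administered) + length(excluded) >= nItems(bank)) {
        stop_reason <- "bank_exhausted"
        break
      }
      if (length(administered) >= max_items) {
        stop_reason <- "max_items"
        break
      }
    }
    if (length(administered) + length(excluded) >= nItems(bank)) {
      stop_reason <- "bank_exhausted"
      break
    }
    next_id <- if (is.null(info_tab))
      selectNextItem(est$theta, bank, administered, excluded)
    else {
      cand <- which(!(ids %in% c(administered, excluded)))
      ids[cand[which.max(grmInfoAt(info_tab, est$theta, cand))]]
    }
  }
  trajectory <- do.call(rbind, traj[seq_len(length(administered))])
  structure(list(administered = administered, responses = responses,
                 theta = est$theta,
                 se = if (length(administered) > 0L)
                        trajectory$se[nrow(trajectory)] else NA_real_,
                 posterior_sd = est$sd, stop_reason = stop_reason,
                 trajectory = trajectory),
            class = "catResult")
}

#' Precompute per-item grid tables for repeated CAT runs
#'
#' Returns the per-item log category probabilities over the quadrature
#' grid (and, for all-GRM banks, the padded parameter arrays behind the
#' vectorized information evaluator) so batch drivers such as
#' \code{\link{runStudy}} compute them once instead of once per person.
#'
#' @param bank an \code{\link{itemBank}}.
#' @param grid a \code{\link{thetaGrid}}.
#' @return list with \code{logprobs} and \code{info_tab} (NULL for
#'   mixed-model banks, which fall back to the generic path).
#' @export
catPrecompute <- function(bank, grid = thetaGrid()) {
  assertThetaGrid(grid)
  list(logprobs = lapply(bank, function(item)
         log(pmax(categoryProbs(item, grid$points), 1e-300))),
       info_tab = grmInfoTable(bank))
}

#' @export
print.catResult <- function(x, ...) {
  cat(sprintf(
    "<catResult: %d items, theta = %.3f, SE = %.3f, stopped: %s>\n",
    length(x$administered), x$theta, x$se, x$stop_reason))
  invisible(x)
}

makeAnswerSource <- function(answers, ids) {
  if (is.function(answers)) return(answers)
  if (is.null(names(answers))) {
    if (length(answers) != length(ids))
      stop("unnamed answer vector must cover the whole bank")
    names(answers) <- ids
  }
  function(id) {
    if (!id %in% names(answers)) return(NA_integer_)
    answers[[id]]
  }
}

# draw the first item with a private RNG stream so administration
# randomness neither disturbs nor depends on the caller's RNG state
firstItem <- function(bank, config) {
  ids <- itemIds(bank)
  if (!identical(config$first_item, "random")) {
    if (!config$first_item %in% ids)
      stop("fixed first item '", config$first_item, "' not in bank")
    return(config$first_item)
  }
  if (is.null(config$seed)) return(ids[sample.int(length(ids), 1L)])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)
  ids[sample.int(length(ids), 1L)]
}
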