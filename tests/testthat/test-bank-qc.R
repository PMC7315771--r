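test_that("eigenvalue ratio reproduces hand-computed screening values", {
  expect_equal(round(eigenvalueRatio(c(25.08, 5.59, 2.1)), 2), 4.49)
})

test_that("independent items fail the unidimensionality screen", {
  set.seed(8)
  # independent uniform categories: population correlation identity
  codes <- matrix(sample(0:3, 300 * 6, TRUE), 300, 6,
                  dimnames = list(NULL, paste0("i", 1:6)))
  u <- suppressWarnings(unidimensionalityCheck(codes))
  expect_false(u$passed)
  expect_lt(u$ratio_1_2, 3)
})

test_that("one-factor data pass the screen and weak items are removed", {
  set.seed(9)
  bank <- fixtureBank()[1:10]
  r <- generateRespondents(1000, bank, seed = 31)
  u <- unidimensionalityCheck(r$responses)
  expect_true(u$passed)
  expect_gte(u$ratio_1_2, 3)
  expect_gte(u$variance_pct_first, 20)
  expect_length(u$removed_items, 0)
  # append an unrelated noise item: loading near 0, must be removed
  codes <- cbind(r$responses$codes,
                 noise = sample(0:3, 1000, TRUE))
  u2 <- unidimensionalityCheck(codes)
  expect_true("noise" %in% u2$removed_items)
  expect_true(u2$passed)
})

test_that("constant items make the correlation matrix singular", {
  codes <- cbind(fixtureResponses100(), flat = 1L)
  expect_error(unidimensionalityCheck(codes), "flat")
})

test_that("polychoric correlation tracks the latent correlation", {
  set.seed(10)
  n <- 800
  z1 <- rnorm(n); z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
  x <- cut(z1, c(-Inf, -0.5, 0.5, Inf), labels = FALSE) - 1L
  y <- cut(z2, c(-Inf, 0, 1, Inf), labels = FALSE) - 1L
  rho <- gradedCAT:::polychoricRho(x, y)
  expect_lt(abs(rho - 0.6), 0.1)
  # pearson on coarse codes attenuates; polychoric should not
  expect_gt(rho, cor(x, y))
})

test_that("S-X2 keeps its size under the null and flags injected misfit", {
  # null case: fit the model to its own simulated data, then test fit
  bank <- fixtureBank()[1:10]
  flags <- 0L
  for (s in 1:3) {
    r <- generateRespondents(1000, bank, seed = 200 + s)
    fit <- fitMmlEm(r$responses, "GRM", max_iter = 200)
    sx <- itemFitSX2(r$responses, fit$bank)
    expect_true(all(sx$p_value >= 0 & sx$p_value <= 1, na.rm = TRUE))
    flags <- flags + sum(sx$flagged)
  }
  expect_lte(flags / (3 * nItems(bank)), 2 * 0.05)

  # generate with slope 3, evaluate against a bank claiming slope 0.5
  b1 <- bank[[1]]
  gen <- itemBank(c(list(grmItem(b1$item_id, 3, b1$b)), unclass(bank)[-1]))
  wrong <- itemBank(c(list(grmItem(b1$item_id, 0.5, b1$b)),
                      unclass(bank)[-1]))
  r <- generateRespondents(1000, gen, seed = 41)
  sx <- itemFitSX2(r$responses, wrong)
  expect_true(sx$flagged[1])
})

test_that("DIF is silent under the null and catches an injected shift", {
  bank <- fixtureBank()[1:8]
  r <- generateRespondents(2000, bank, seed = 42)
  th <- fullBankScores(r$responses, bank)$theta
  grp <- rep(c(0, 1), each = 1000)
  d0 <- difAnalysis(r$responses, th, grp)
  expect_true(all(d0$delta_pseudo_r2 < 0.02))
  expect_false(any(d0$flagged))

  # shift one item's thresholds by 1.0 for group 1 only
  codes <- r$responses$codes
  b3 <- bank[[3]]
  shifted <- grmItem(b3$item_id, b3$a, b3$b + 1.0)
  set.seed(7)
  th1 <- r$theta[grp == 1]
  P <- categoryProbs(shifted, th1)
  cum <- t(apply(P, 1, cumsum))
  codes[grp == 1, 3] <- rowSums(runif(length(th1)) >
                                  cum[, -ncol(cum), drop = FALSE])
  d1 <- difAnalysis(codes, th, grp)
  expect_identical(which.max(d1$delta_pseudo_r2), 3L)
  expect_true(d1$flagged[3])

  # relabeling symmetry
  d1b <- difAnalysis(codes, th, 1 - grp)
  expect_equal(d1$delta_pseudo_r2, d1b$delta_pseudo_r2, tolerance = 1e-8)

  expect_error(difAnalysis(codes, th, rep(1, nrow(codes))), "two levels")
})

test_that("discrimination filter applies an inclusive floor in bank order", {
  bank <- itemBank(list(grmItem("lo", 0.79, 0), grmItem("at", 0.8, 0),
                        grmItem("hi", 1.4, 0)))
  f <- discriminationFilter(bank)
  expect_identical(f$removed, "lo")
  expect_identical(itemIds(f$retained), c("at", "hi"))
  # the packaged bank (slopes from 0.83 up) loses nothing
  expect_length(discriminationFilter(fixtureBank())$removed, 0)
  # monotone in the floor
  n_kept <- vapply(c(0.5, 0.8, 1.0, 1.5),
                   function(m) nItems(discriminationFilter(fixtureBank(),
                                                           m)$retained),
                   numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("the pipeline stages consume each other's survivors", {
  bank <- fixtureBank()[1:10]
  r <- generateRespondents(600, bank, seed = 61)
  set.seed(61)
  meta <- data.frame(gender = sample(c("m", "f"), 600, TRUE))
  resp <- responseMatrix(r$responses$codes, meta = meta)
  qc <- runQcPipeline(resp, max_iter = 60)
  expect_s3_class(qc, "qcReport")
  expect_identical(qc$stages$stage,
                   c("unidimensionality", "item_fit", "dif",
                     "discrimination"))
  expect_true(all(diff(c(qc$stages$items_in[1], qc$stages$items_out)) <= 0))
  expect_identical(nItems(qc$bank), qc$stages$items_out[4])
  # every removed item names the rule that removed it
  if (nrow(qc$removed) > 0)
    expect_true(all(nzchar(qc$removed$rule)))
  f <- tempfile(fileext = ".json")
  writeQcReport(qc, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
})
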