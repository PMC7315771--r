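test_that("GRM category probabilities match direct logistic evaluation", {
  # symmetric one-threshold item splits 50/50 at its threshold
  expect_equal(as.numeric(categoryProbs(grmItem("i", 1, 0), 0)),
               c(0.5, 0.5), tolerance = 1e-12)
  # two cumulative curves evaluated and differenced by hand:
  # P*1 = plogis(2*(0+0.5)), P*2 = plogis(2*(0-1))
  p <- as.numeric(categoryProbs(grmItem("i", 2, c(-0.5, 1)), 0))
  p1 <- plogis(1); p2 <- plogis(-2)
  expect_equal(p, c(1 - p1, p1 - p2, p2), tolerance = 1e-12)
  expect_equal(round(p, 4), c(0.2689, 0.6119, 0.1192))
})

test_that("probabilities normalize and stay in [0,1] for random items/theta", {
  set.seed(1)
  for (rep in 1:200) {
    m <- sample(2:5, 1)
    item <- switch(sample(3, 1),
      grmItem("r", runif(1, 0.3, 2.5), sort(rnorm(m - 1, 0, 1.5)) +
                seq(0, 0.1, length.out = m - 1)),
      gpcmItem("r", runif(1, 0.3, 2.5), rnorm(m - 1, 0, 1.5)),
      nrmItem("r", c(0, runif(m - 1, 0.2, 2)), c(0, rnorm(m - 1))))
    th <- runif(50, -6, 6)
    P <- categoryProbs(item, th)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(rowSums(P), rep(1, 50), tolerance = 1e-12)
  }
})

test_that("GRM cumulative curves increase in theta and decrease in k", {
  item <- grmItem("i", 1.4, c(-1, 0.2, 1.3))
  th <- seq(-4, 4, 0.25)
  P <- categoryProbs(item, th)
  cum <- t(apply(P[, ncol(P):1], 1L, cumsum))[, ncol(P):1]  # P(X >= k)
  for (k in 2:ncol(cum))
    expect_true(all(diff(cum[, k]) > 0))        # increasing in theta
  for (i in seq_along(th))
    expect_true(all(diff(cum[i, ]) < 0))        # decreasing in k
})

test_that("response log-likelihood is additive and handles missing codes", {
  bank <- tinyBank()
  expect_equal(responseLogLik(c(0L, rep(NA, 4)), bank, 0),
               log(categoryProbs(bank[[1]], 0)[1, 1]))
  expect_identical(responseLogLik(rep(NA_integer_, 5), bank, 0.7), 0)
  r <- c(1L, 0L, NA, 1L, NA)
  per_item <- sum(vapply(c(1, 2, 4), function(j)
    log(categoryProbs(bank[[j]], 0.3)[1, r[j] + 1]), numeric(1)))
  expect_equal(responseLogLik(r, bank, 0.3), per_item, tolerance = 1e-12)
  expect_lte(responseLogLik(r, bank, 0.3), 0)
  expect_error(responseLogLik(c(9L, rep(NA, 4)), bank, 0), "g1")
})

test_that("item information matches a numerical-derivative oracle", {
  # on every fixture item across a theta grid, and on GPCM/NRM items
  th <- seq(-3.5, 3.5, 0.5)
  for (item in fixtureBank())
    expect_equal(itemInfo(item, th), numericalItemInfo(item, th),
                 tolerance = 1e-6)
  for (item in mixedModelBank())
    expect_equal(itemInfo(item, th), numericalItemInfo(item, th),
                 tolerance = 1e-6)
})

test_that("information is nonnegative, vanishes in the tails, grows with a", {
  item <- grmItem("i", 1, 0)
  expect_lt(itemInfo(item, 8), 1e-3)
  expect_true(all(itemInfo(grmItem("i", 2, c(-0.5, 1)), seq(-5, 5, 0.5)) >= 0))
  # doubling the slope raises peak information (grid-scan oracle)
  th <- seq(-4, 4, 0.01)
  expect_gte(max(itemInfo(grmItem("i", 2, 0.4), th)),
             max(itemInfo(grmItem("i", 1, 0.4), th)))
})

test_that("test information is the item sum, permutation-invariant", {
  bank <- fixtureBank()
  expect_equal(testInfo(bank, 0.3),
               sum(vapply(bank, itemInfo, numeric(1), 0.3)),
               tolerance = 1e-10)
  one <- bank[1]
  expect_equal(testInfo(one, 1.1), itemInfo(bank[[1]], 1.1))
  set.seed(2)
  perm <- sample(nItems(bank))
  expect_equal(testInfo(bank[perm], -0.8), testInfo(bank, -0.8),
               tolerance = 1e-12)
})

test_that("vectorized GRM information path agrees with the generic one", {
  bank <- fixtureBank()
  tab <- gradedCAT:::grmInfoTable(bank)
  for (th in c(-2, 0, 1.5))
    expect_equal(unname(gradedCAT:::grmInfoAt(tab, th)),
                 unname(vapply(bank, itemInfo, numeric(1), th)),
                 tolerance = 1e-12)
})

test_that("SE and reliability transforms obey their closed forms", {
  expect_identical(seFromInfo(4), 0.5)
  expect_equal(seFromInfo(11.1111), 0.3, tolerance = 1e-4)
  expect_error(seFromInfo(0), "non-positive")
  expect_equal(reliabilityFromInfo(10), 0.9)
  expect_equal(reliabilityFromInfo(1), 0)
  expect_warning(r <- reliabilityFromInfo(0.5), "negative")
  expect_equal(r, -1)
  # r = 1 - SE^2 exactly
  info <- c(0.7, 1, 2.5, 40)
  expect_warning(r <- reliabilityFromInfo(info))
  expect_equal(r, 1 - seFromInfo(info)^2, tolerance = 1e-15)
})

test_that("invalid item parameters are rejected at construction", {
  expect_error(grmItem("x", 1, c(0.5, 0.5)), "strictly increasing")
  expect_error(grmItem("x", -1, 0), "positive")
  expect_error(nrmItem("x", c(0.5, 1), c(0, 0)), "fixed to 0")
  expect_error(itemBank(list(grmItem("a", 1, 0), grmItem("a", 1, 1))),
               "duplicate")
})
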