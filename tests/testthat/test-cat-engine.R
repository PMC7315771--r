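test_that("EAP reduces to the prior with no data and tilts with responses", {
  bank <- tinyBank()
  e <- eapEstimate(rep(NA_integer_, 5), bank)
  expect_lt(abs(e$theta), 1e-9)          # symmetric grid, Normal(0,1) prior
  one <- itemBank(list(grmItem("i", 1, 0)))
  expect_gt(eapEstimate(1L, one)$theta, 0)
  expect_lt(eapEstimate(0L, one)$theta, 0)
})

test_that("default-grid EAP matches a 2001-point brute-force posterior mean", {
  bank <- fixtureBank()
  r <- generateRespondents(5, bank, seed = 51)
  for (i in 1:5) {
    coarse <- eapEstimate(r$responses[i, ], bank)$theta
    fine <- eapEstimate(r$responses[i, ], bank, thetaGrid(2001))$theta
    expect_lt(abs(coarse - fine), 0.01)
  }
})

test_that("current SE matches the cross-module information formula", {
  bank <- tinyBank()
  r <- generateRespondents(1, bank, seed = 6)
  res <- runCAT(r$responses[1, ], bank,
                catConfig(se_threshold = 0.9, max_items = 3, seed = 2))
  expect_equal(currentSE(res, bank),
               seFromInfo(testInfo(bank[res$administered], res$theta)),
               tolerance = 1e-12)
  expect_equal(res$se, currentSE(res, bank), tolerance = 1e-12)
  # SE shrinks along the trajectory when theta is held fixed
  th <- res$theta
  info_cum <- cumsum(vapply(res$administered,
                            function(id) itemInfo(bank[[id]], th),
                            numeric(1)))
  expect_true(all(diff(seFromInfo(info_cum)) < 0))
})

test_that("item selection maximizes information, excludes used items", {
  two <- itemBank(list(grmItem("near", 1.5, 0), grmItem("far", 1.5, 3)))
  expect_identical(selectNextItem(0, two), "near")
  expect_identical(selectNextItem(0, two, administered = "near"), "far")
  # identical items tie to the lowest bank index
  twins <- itemBank(list(grmItem("a", 1, 0), grmItem("b", 1, 0)))
  expect_identical(selectNextItem(0.4, twins), "a")
  expect_error(selectNextItem(0, two, administered = c("near", "far")),
               "exhausted")
})

test_that("adaptive runs respect stopping rules, caps and determinism", {
  bank <- fixtureBank()
  r <- generateRespondents(3, bank, seed = 71)
  # unreachable precision: always stops at the cap
  res <- runCAT(r$responses[1, ], bank,
                catConfig(se_threshold = 1e-9, max_items = 20, seed = 3))
  expect_identical(res$stop_reason, "max_items")
  expect_length(res$administered, 20L)
  # no repeats, trajectory bookkeeping
  expect_false(anyDuplicated(res$administered) > 0)
  expect_identical(nrow(res$trajectory), 20L)
  # determinism under the same seed; different first item otherwise
  res2 <- runCAT(r$responses[1, ], bank,
                 catConfig(se_threshold = 1e-9, max_items = 20, seed = 3))
  expect_identical(res$administered, res2$administered)
  expect_identical(res$trajectory, res2$trajectory)
  # stopping is immediate: no SE before the last is below the threshold
  res3 <- runCAT(r$responses[2, ], bank,
                 catConfig(se_threshold = 0.4, seed = 5))
  if (res3$stop_reason == "se_met") {
    pre <- head(res3$trajectory$se, -1)
    expect_true(all(pre >= 0.4))
    expect_lt(res3$trajectory$se[nrow(res3$trajectory)], 0.4)
  }
})

test_that("a mid-trait simulee reaches SE < 0.3 before the 20-item cap", {
  bank <- fixtureBank()
  r <- generateRespondents(1, bank, theta = 0, seed = 72)
  res <- runCAT(r$responses[1, ], bank,
                catConfig(se_threshold = 0.3, seed = 8))
  expect_identical(res$stop_reason, "se_met")
  expect_lt(length(res$administered), 20L)
  expect_lt(res$se, 0.3)
})

test_that("with no precision rule the CAT reproduces the full-bank EAP", {
  bank <- tinyBank()
  r <- generateRespondents(4, bank, seed = 73)
  full <- fullBankScores(r$responses, bank)
  for (i in 1:4) {
    res <- runCAT(r$responses[i, ], bank, catConfig(seed = i))
    expect_identical(res$stop_reason, "bank_exhausted")
    expect_length(res$administered, 5L)
    expect_equal(res$theta, full$theta[i], tolerance = 1e-12)
  }
})

test_that("missing answers are skipped with a warning, not administered", {
  bank <- tinyBank()
  answers <- c(g1 = 1L, g2 = NA, g3 = 2L, g4 = 0L, g5 = 1L)
  expect_warning(
    res <- runCAT(answers, bank, catConfig(first_item = "g2")),
    "skipping")
  expect_false("g2" %in% res$administered)
  expect_length(res$administered, 4L)
})

test_that("relaxed thresholds administer a prefix of the stricter run", {
  bank <- fixtureBank()
  r <- generateRespondents(20, bank, seed = 74)
  for (i in c(1, 7, 13)) {
    seqs <- lapply(c(0.3, 0.4, 0.5), function(rule)
      runCAT(r$responses[i, ], bank,
             catConfig(se_threshold = rule, seed = 1000 + i))$administered)
    expect_true(length(seqs[[1]]) >= length(seqs[[2]]))
    expect_true(length(seqs[[2]]) >= length(seqs[[3]]))
    expect_identical(seqs[[2]], seqs[[1]][seq_along(seqs[[2]])])
    expect_identical(seqs[[3]], seqs[[2]][seq_along(seqs[[3]])])
  }
})
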