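test_that("marginal reliability follows 1 - mean(SE^2) exactly", {
  expect_equal(marginalReliability(rep(0.31, 40)), 1 - 0.31^2,
               tolerance = 1e-15)
  expect_equal(round(marginalReliability(rep(0.31, 40)), 4), 0.9039)
  expect_equal(round(marginalReliability(rep(0.19, 40)), 4), 0.9639)
  set.seed(26)
  s <- runif(100, 0.1, 0.6)
  expect_equal(marginalReliability(s), 1 - mean(s^2), tolerance = 1e-15)
  expect_warning(marginalReliability(c(1.5, 1.4)), "negative")
  expect_error(marginalReliability(c(0.3, 0)), "positive")
})

test_that("criterion classification is inclusive at the cutoff", {
  expect_identical(classifyByCriterion(c(75, 74.9, 80, 10)),
                   c(1L, 0L, 1L, 0L))
  set.seed(27)
  scores <- rnorm(1014, 50, 12)
  scores[sample(1014, 40)] <- runif(40, 75, 100)
  scores[scores >= 75][-(1:40)] <- 70   # force exactly 40 positives
  expect_identical(sum(classifyByCriterion(scores)), 40L)
})

test_that("sensitivity/specificity/Youden are consistent identities", {
  # 20 positives (18 above), 40 negatives (37 below): sens .9, spec .925
  scores <- c(rep(80, 18), rep(60, 2), rep(50, 37), rep(90, 3))
  labels <- c(rep(1, 20), rep(0, 40))
  m <- screeningMetrics(scores, labels, 75)
  expect_equal(m$sensitivity, 0.900)
  expect_equal(m$specificity, 0.925)
  expect_equal(m$youden, 0.825, tolerance = 1e-12)
  # identity holds for arbitrary cutpoints
  set.seed(28)
  sc <- rnorm(200)
  lb <- rbinom(200, 1, plogis(sc))
  for (ct in quantile(sc, c(0.2, 0.5, 0.8))) {
    mm <- screeningMetrics(sc, lb, ct)
    expect_equal(mm$youden, mm$sensitivity + mm$specificity - 1,
                 tolerance = 1e-12)
  }
})

test_that("AUC equals exhaustive pair counting and the Mann-Whitney U", {
  expect_equal(screeningMetrics(c(2, 3, 0, 1), c(1, 1, 0, 0), 1.5)$auc, 1)
  expect_equal(screeningMetrics(c(0, 3, 1, 2), c(1, 1, 0, 0), 1.5)$auc, 0.5)
  set.seed(29)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    sc <- sample(0:5, n, TRUE)        # heavy ties on purpose
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    pos <- sc[lb == 1]; neg <- sc[lb == 0]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(screeningMetrics(sc, lb, 2)$auc, mean(pairs),
                 tolerance = 1e-12)
    u <- suppressWarnings(wilcox.test(pos, neg)$statistic)
    expect_equal(screeningMetrics(sc, lb, 2)$auc,
                 unname(u) / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(30)
  sc <- rnorm(100)
  lb <- rbinom(100, 1, plogis(1.5 * sc))
  a1 <- screeningMetrics(sc, lb, 0)$auc
  a2 <- screeningMetrics(exp(sc), lb, 1)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  # cross-check against an independent ROC implementation
  a3 <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                       direction = "<")))
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("optimal cutpoint matches brute force and handles degeneracy", {
  expect_equal(optimalCutpoint(c(1, 2, 10, 11),
                               c(0, 0, 1, 1))$metrics$youden, 1)
  set.seed(31)
  sc <- round(rnorm(60), 1)
  lb <- rbinom(60, 1, plogis(2 * sc))
  if (length(unique(lb)) == 2) {
    oc <- optimalCutpoint(sc, lb)
    brute <- max(vapply(sort(unique(sc)), function(ct)
      screeningMetrics(sc, lb, ct)$youden, numeric(1)))
    expect_equal(oc$metrics$youden, brute, tolerance = 1e-12)
  }
  same <- optimalCutpoint(rep(3, 20), rep(c(0, 1), 10))
  expect_equal(same$metrics$youden, 0, tolerance = 1e-12)
})

test_that("diagnosis curve recovers a generating logistic model", {
  set.seed(32)
  sc <- rnorm(5000)
  lb <- rbinom(5000, 1, plogis(-3 + 2 * sc))
  dc <- diagnosisCurve(sc, lb)
  expect_lt(abs(dc$slope - 2), 0.2)
  expect_equal(dc$p50, -dc$intercept / dc$slope, tolerance = 1e-12)
  expect_lt(abs(dc$percentile(median(sc)) - 50), 1)
  # fitted probabilities are monotone when the slope is positive
  p <- dc$probability(seq(-3, 3, 0.1))
  expect_true(all(diff(p) > 0))
})

test_that("response descriptives use n-1 SD and excess kurtosis", {
  codes <- cbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 1L, 1L, 2L))
  d <- responseDescriptives(codes)
  expect_equal(d$mean[1], 0.5)
  expect_equal(round(d$sd[1], 3), 0.577)
  expect_equal(d$skewness[2], 0)             # symmetric codes
  expect_warning(dc <- responseDescriptives(cbind(k = rep(2L, 10))),
                 "constant")
  expect_true(is.nan(dc$skewness) && is.nan(dc$kurtosis))
  # excess-kurtosis convention: a flat 4-point spread is platykurtic
  d2 <- responseDescriptives(cbind(u = rep(0:3, 25)))
  expect_lt(d2$kurtosis, 0)
})

test_that("looser stopping degrades criterion validity monotonically", {
  bank <- fixtureBank()
  r <- generateRespondents(250, bank, seed = 33)
  set.seed(34)
  criterion <- 40 + 12 * pnorm(r$theta) * 2 + rnorm(250, 0, 3)
  st <- runStudy(r, bank, rules = c(0.3, 0.5), seed = 35)
  c_tight <- cor(st$details[["SE<0.3"]]$theta, criterion)
  c_loose <- cor(st$details[["SE<0.5"]]$theta, criterion)
  expect_gt(c_tight, c_loose)
})
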