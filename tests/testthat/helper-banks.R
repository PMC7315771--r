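# Shared fixtures, built in code.

# small mixed-category GRM bank with realistic slopes/thresholds
tinyBank <- function() {
  itemBank(list(
    grmItem("g1", a = 1.2, b = c(-0.5, 0.8, 1.9)),
    grmItem("g2", a = 0.9, b = c(0.2, 1.5)),
    grmItem("g3", a = 1.8, b = c(-1.0, 0.0, 1.0, 2.0)),
    grmItem("g4", a = 1.5, b = c(0.5, 2.1)),
    grmItem("g5", a = 1.0, b = c(-0.2, 1.1, 2.4))))
}

mixedModelBank <- function() {
  itemBank(list(
    grmItem("g", a = 1.3, b = c(-0.4, 0.9)),
    gpcmItem("p", a = 1.1, d = c(0.3, 1.2)),
    nrmItem("n", a = c(0, 0.7, 1.4), c = c(0, 0.2, -0.5))))
}

# brute-force Fisher information by central differences on the
# category probabilities; independent of categoryProbDeriv()
numericalItemInfo <- function(item, theta, h = 1e-5) {
  vapply(theta, function(th) {
    P <- categoryProbs(item, th)
    dP <- (categoryProbs(item, th + h) - categoryProbs(item, th - h)) /
      (2 * h)
    sum(dP^2 / P)
  }, numeric(1))
}

fixtureBank <- function() exampleBank()

fixtureResponses100 <- function() {
  generateRespondents(100, fixtureBank()[1:5], seed = 99)$responses$codes
}
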