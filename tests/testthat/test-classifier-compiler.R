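test_that("the ideal mapping places inhibitors at amplifier0/|W|", {
  spec <- LinearClassifierSpec(c("up", "down"), c(2.4, -2.6),
                               positiveClass = "HCC",
                               negativeClass = "healthy")
  net <- compileClassifier(spec)
  ini <- initialConc(net)
  expect_equal(unname(ini["Inh_up"]), 100 / 2.4, tolerance = 1e-9)
  expect_equal(unname(ini["Inh_down"]), 100 / 2.6, tolerance = 1e-9)
  # identity weight
  one <- compileClassifier(LinearClassifierSpec("f", 1.0))
  expect_equal(unname(initialConc(one)["Inh_f"]), 100)
  # sign routing: up feeds the positive output strand, down the negative
  outOf <- function(net, inputId) {
    hits <- Filter(function(r) inputId %in% r$reactants &&
                     inputId %in% r$products, reactions(net))
    setdiff(hits[[1]]$products, hits[[1]]$reactants)
  }
  expect_equal(outOf(net, "Input_up"), "OutPos")
  expect_equal(outOf(net, "Input_down"), "OutNeg")
})

test_that("a user calibration table overrides the ideal inhibitor mapping", {
  tab <- data.frame(weight = 2.5, inhibitor0 = 38.5)
  spec <- LinearClassifierSpec("f", 2.5, calibrationTable = tab)
  net <- compileClassifier(spec)
  expect_equal(unname(initialConc(net)["Inh_f"]), 38.5)
})

test_that("compiled network structure matches the size formula", {
  spec <- fiveFeatureSpec()  # five features plus a bias unit
  net <- compileClassifier(spec)
  size <- compiledNetworkSize(spec)
  expect_equal(nrow(net@species), size$nSpecies)
  expect_equal(length(reactions(net)), size$nReactions)
  noBias <- twoFeatureSpec()
  netNB <- compileClassifier(noBias)
  expect_equal(nrow(netNB@species), 3 * 2 + 10)
  expect_equal(length(reactions(netNB)), 2 * 2 + 8)
})

test_that("zero weights are rejected with a warning at construction", {
  expect_warning(spec <- LinearClassifierSpec(c("a", "b"), c(1.5, 0.01)),
                 "zero-weight")
  expect_equal(features(spec), "a")
})

test_that("the linear-regime guard warns when an inhibitor sits below the input range", {
  spec <- LinearClassifierSpec("f", 20)  # inhibitor 5 nM < 6 nM max input
  expect_warning(compileClassifier(spec), "linear regime")
})

test_that("closed-form output follows the ratio law and rejects saturation", {
  expect_equal(closedFormOutput(2, 100, 50), 4)
  expect_equal(closedFormOutput(0, 100, 50), 0)
  expect_equal(closedFormOutput(4, 100, 40), 10)
  expect_error(closedFormOutput(60, 100, 50), "linear regime")
})

test_that("closed-form summation splits channels before annihilation", {
  s <- closedFormSignal(c(1.5, 2.5), c(2, 2))
  expect_equal(s$positive, 8)
  expect_equal(s$negative, 0)
  s2 <- closedFormSignal(c(1.5, -2), c(4, 2))
  expect_equal(s2$positive, 6)
  expect_equal(s2$negative, 4)
  expect_equal(s2$net, 2)
  expect_equal(closedFormSignal(c(1, -1), c(0, 0))$net, 0)
  expect_error(closedFormSignal(c(1, 2), c(1)), "equal length")
})

test_that("ODE endpoints match the closed form across the linear regime", {
  set.seed(7)
  for (i in 1:12) {
    amp <- runif(1, 50, 150)
    inh <- runif(1, 20, 100)
    inp <- runif(1, 0.05, 0.8) * inh
    tr <- simulateNetwork(eqWeightNetwork(inp, amp, inh), tEnd = 4e5)
    expect_equal(endpoint(tr, "Output"), inp * amp / inh,
                 tolerance = 0.005)
  }
})

test_that("past the inhibitor pool the output saturates toward the amplifier", {
  tr <- simulateNetwork(eqWeightNetwork(60, 100, 50), tEnd = 4e5)
  expect_gt(endpoint(tr, "Output"), 99)
})

test_that("multi-unit summation matches the sum of closed forms", {
  spec <- LinearClassifierSpec(c("a", "b", "c"), c(1.0, 1.5, 3.5),
                               positiveClass = "HCC",
                               negativeClass = "healthy")
  inputs <- c(a = 3, b = 2, c = 1.5)
  net <- compileClassifier(spec, inputs = inputs)
  tr <- simulateNetwork(net, tEnd = 8e5)
  ep <- endpoint(tr, warn = FALSE)
  produced <- ep[["FluorHEX"]] + ep[["OutPos"]] + ep[["AnnIntPos"]]
  expected <- sum(vapply(names(inputs), function(f) {
    closedFormOutput(inputs[[f]], 100, 100 / weights(spec)[[f]])
  }, numeric(1)))
  expect_equal(produced, expected, tolerance = 0.01)
})

test_that("annihilation consumes the two channels 1:1 and spares the majority", {
  # survivor totals count the free strand plus the reversibly bound
  # intermediate, which the downstream reporter recovers
  tr <- simulateNetwork(annihilationNetwork(10, 6, 50), tEnd = 4e5)
  ep <- endpoint(tr, warn = FALSE)
  expect_equal(ep[["OutPos"]] + ep[["AnnIntPos"]], 4, tolerance = 0.01)
  expect_lt(ep[["OutNeg"]] + ep[["AnnIntNeg"]], 0.05)

  # diagonal case: equal pools, both channels collapse
  trEq <- simulateNetwork(annihilationNetwork(5, 5, 50), tEnd = 8e5)
  epEq <- endpoint(trEq, warn = FALSE)
  expect_lt(epEq[["OutPos"]] + epEq[["AnnIntPos"]], 0.05)
  expect_lt(epEq[["OutNeg"]] + epEq[["AnnIntNeg"]], 0.05)

  # nothing to annihilate: the lone channel survives intact
  trOne <- simulateNetwork(annihilationNetwork(7, 0, 50), tEnd = 4e5)
  epOne <- endpoint(trOne, warn = FALSE)
  expect_equal(epOne[["OutPos"]] + epOne[["AnnIntPos"]], 7,
               tolerance = 0.01)
})

test_that("an annihilator short of the channel capacity raises a warning", {
  expect_warning(
    buildAnnihilator(AnnihilatorSpec(annihilator0 = 5),
                     posCapacity = 20, negCapacity = 3),
    "excess"
  )
})

test_that("in-silico evaluation signs the score and flags exact ties", {
  spec <- twoFeatureSpec()
  res <- evaluateInSilico(spec, c(Input1 = 2, Input4 = 3))
  expect_equal(res$score, -3)
  expect_equal(res$call, "healthy")
  tie <- evaluateInSilico(spec, c(Input1 = 4, Input4 = 3))
  expect_equal(tie$score, 0)
  expect_equal(tie$call, "indeterminate")
  expect_error(evaluateInSilico(spec, c(Input1 = 2)), "Input4")
})

test_that("molecular and in-silico calls agree for a fixture patient", {
  spec <- fiveFeatureSpec()
  cfg <- GeneratorConfig(seed = 7L)
  panel <- generatePatientPanel(spec, "negative", cfg, seed = 99)
  res <- runSample(panel, spec, sampleId = "fix")
  expect_equal(diagnosticCall(res), "healthy")
  expect_equal(sign(res@margin), sign(res@inSilicoScore))
})
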