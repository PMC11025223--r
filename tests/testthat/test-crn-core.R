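test_that("first-order decay matches its closed form", {
  net <- ReactionNetwork(c("A", "B"),
                         list(reaction("A", "B", k = 0.01)),
                         c(A = 10))
  tr <- simulateNetwork(net, tEnd = 1000, autoExtend = FALSE)
  expect_equal(endpoint(tr, "A", warn = FALSE), 10 * exp(-10),
               tolerance = 1e-6)
  expect_equal(endpoint(tr, "B", warn = FALSE), 10 * (1 - exp(-10)),
               tolerance = 1e-8)
})

test_that("competitive-inhibition endpoint follows the concentration-ratio law", {
  tr <- simulateNetwork(eqWeightNetwork(2, 100, 50))
  expect_true(isSteady(tr))
  expect_equal(endpoint(tr, "Output"), 4, tolerance = 1e-3 / 4)

  # no catalyst, no turnover
  tr0 <- simulateNetwork(eqWeightNetwork(0, 100, 50), autoExtend = FALSE)
  expect_equal(endpoint(tr0, "Output", warn = FALSE), 0)
})

test_that("default integrator agrees with an independent stiff reference", {
  # the printed example triple
  tr <- simulateNetwork(eqWeightNetwork(3, 100, 27.5))
  ref <- oracleWeightUnitOutput(3, 100, 27.5)
  expect_equal(endpoint(tr, "Output"), ref, tolerance = 1e-6)

  # random small networks of order 1-3
  set.seed(42)
  for (i in 1:6) {
    k1 <- runif(1, 1e-4, 1e-2)
    k2 <- runif(1, 1e-5, 1e-3)
    k3 <- runif(1, 1e-6, 1e-4)
    net <- ReactionNetwork(
      c("A", "B", "C", "D"),
      list(
        reaction("A", "B", k = k1),
        reaction(c("A", "B"), c("C"), k = k2),
        reaction(c("B", "B", "C"), c("D"), k = k3)
      ),
      c(A = runif(1, 1, 20), B = runif(1, 1, 20), C = runif(1, 0, 5))
    )
    tr <- simulateNetwork(net, tEnd = 2e4, autoExtend = FALSE)
    ref <- oracleNetworkEndpoint(net, tEnd = 2e4)
    for (s in speciesIds(net)) {
      expect_equal(endpoint(tr, s, warn = FALSE), ref[[s]],
                   tolerance = 1e-6 + 1e-9)
    }
  }
})

test_that("declared conservation laws hold along the whole trace", {
  net <- eqWeightNetwork(2, 100, 50)
  tr <- simulateNetwork(net)
  viol <- checkConservation(net, tr)
  # amplifier + output constant; input and inhibitor consumed 1:1
  expect_lt(viol$maxViolation[1], 1e-6 * 100)
  expect_lt(viol$maxViolation[2], 1e-6 * 2)
})

test_that("conservation checking validates its inputs", {
  net <- eqWeightNetwork(2, 100, 50)
  tr <- simulateNetwork(net)
  bare <- ReactionNetwork(c("A"), list(reaction("A", "A", k = 1)),
                          c(A = 1))
  expect_error(checkConservation(bare, tr), "no conservation laws")
  bad <- net
  bad@conservationLaws <- list(list(coefficients = c(Nope = 1), total = 0))
  expect_error(checkConservation(bad, tr), "unknown species")
})

test_that("endpoint access warns off steady state and rejects unknown ids", {
  net <- eqWeightNetwork(2, 100, 50)
  slow <- simulateNetwork(net, tEnd = 10, autoExtend = FALSE)
  expect_false(isSteady(slow))
  expect_warning(endpoint(slow, "Output"), "steady state")
  tr <- simulateNetwork(net)
  expect_error(endpoint(tr, "NotASpecies"), "unknown species")
})

test_that("time-rescaling symmetry: doubling rates and halving time is a no-op", {
  base <- eqWeightNetwork(3, 100, 40, k = 1e-4)
  fast <- eqWeightNetwork(3, 100, 40, k = 2e-4)
  trBase <- simulateNetwork(base, tEnd = 4e5, autoExtend = FALSE)
  trFast <- simulateNetwork(fast, tEnd = 2e5, autoExtend = FALSE)
  expect_equal(endpoint(trFast, warn = FALSE), endpoint(trBase, warn = FALSE),
               tolerance = 1e-7)
})

test_that("network validation rejects malformed inputs", {
  expect_error(reaction("A", "B", k = -1), "positive")
  expect_error(ReactionNetwork(c("A"),
                               list(reaction(c("A", "A", "A", "A"), "A",
                                             k = 1)),
                               c(A = 1)))
  expect_error(ReactionNetwork(c("A", "A"), list(), c(A = 1)),
               "duplicated")
  expect_error(ReactionNetwork(c("A"), list(reaction("A", "Z", k = 1)),
                               c(A = 1)), "undeclared")
  expect_error(ReactionNetwork(c("A"), list(), c(A = -2)))
  expect_error(simulateNetwork(eqWeightNetwork(1, 10, 10), tEnd = -5),
               "tEnd")
})

test_that("reported concentrations are non-negative with negligible clipping", {
  tr <- simulateNetwork(eqWeightNetwork(4, 100, 25))
  expect_true(all(tr@concentrations >= 0))
  expect_lt(tr@clipMagnitude, 1e-9)
})

test_that("steady-state auto-extension reaches the limit of slow units", {
  # small inhibitor pool: input decays slowly near the end
  tr <- simulateNetwork(eqWeightNetwork(8, 100, 10.5), tEnd = 5e4)
  expect_true(isSteady(tr))
})
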