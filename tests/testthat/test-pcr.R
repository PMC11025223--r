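# toy-unit configuration: template 1 nM, limiting primer 10 nM
toyConfig <- function(nCycles = 10L, excess = 1e4) {
  PCRConfig(efficiency = 1, limitingPrimer = 10, excessPrimer = excess,
            nCycles = nCycles, rtYield = 1, templateDilution = 1)
}

test_that("the two-phase recurrence reproduces the hand-computed toy trace", {
  tr <- simulatePCR(toyConfig(), initialMiRNA = 1000)  # 1000 pM = 1 nM
  tab <- tr@table
  expect_equal(tab$ds[tab$cycle %in% 1:3], c(2, 4, 8))
  # exhaustion cycle: 3 limiting primers left serve 3 of 8 templates;
  # the other 5 are extended by the excess primer into ssDNA
  expect_equal(tab$ds[tab$cycle == 4], 11)
  expect_equal(tab$limiting[tab$cycle == 4], 0)
  expect_equal(tab$ss[tab$cycle == 4], 5)
  # linear phase: 11 templates add 11 ssDNA per cycle
  expect_equal(ssdnaAtReadout(tr), 5 + 6 * 11)
})

test_that("degenerate template equal to the limiting primer exhausts at cycle 1", {
  tr <- simulatePCR(toyConfig(), initialMiRNA = 10 * 1e3)  # 10 nM = L
  tab <- tr@table
  expect_equal(tab$limiting[tab$cycle == 1], 0)
  expect_equal(tab$ss[tab$cycle == 1], 0)
  expect_gt(tab$ss[tab$cycle == 2], 0)
})

test_that("template above the limiting primer violates the model assumptions", {
  expect_error(simulatePCR(toyConfig(), initialMiRNA = 11 * 1e3),
               "limiting primer")
})

test_that("readout within the exponential phase sees no ssDNA", {
  cfg <- toyConfig(nCycles = 3L)
  expect_equal(ssdnaAtReadout(simulatePCR(cfg, 1000)), 0)
})

test_that("ssDNA plateaus when the excess primer is exhausted", {
  cfg <- toyConfig(nCycles = 40L, excess = 30)
  tr <- simulatePCR(cfg, 1000)
  tab <- tr@table
  expect_lt(tab$excess[nrow(tab)], 1e-9)
  expect_lte(max(tab$ss), 30)
  # once capped, ss stops growing
  expect_equal(tab$ss[nrow(tab)], tab$ss[nrow(tab) - 1L])
})

test_that("primer bookkeeping is conserved every cycle", {
  tr <- simulatePCR(PCRConfig(), initialMiRNA = 3.7)
  tab <- tr@table
  consumedLim <- tab$ds - tab$ds[1]
  expect_equal(consumedLim + tab$limiting, rep(25, nrow(tab)),
               tolerance = 1e-12)
  consumedExc <- (tab$ds - tab$ds[1]) + tab$ss
  expect_equal(consumedExc + tab$excess, rep(1000, nrow(tab)),
               tolerance = 1e-12)
})

test_that("readout is monotone in template with equal steps per 10-fold dilution", {
  cfg <- PCRConfig()
  ss <- vapply(c(0.1, 1, 10), function(p) {
    ssdnaAtReadout(simulatePCR(cfg, p))
  }, numeric(1))
  expect_true(all(diff(ss) > 0))
  # equal up to the ripple left by per-cycle quantization of the phase
  # switch (about 4% of a 10-fold step)
  steps <- diff(ss)
  expect_lt(abs(steps[2] - steps[1]) / steps[1], 0.05)
})

test_that("the trace is scale-equivariant in template and primer amounts", {
  base <- simulatePCR(toyConfig(), 1000)@table
  scaled <- simulatePCR(PCRConfig(efficiency = 1, limitingPrimer = 30,
                                  excessPrimer = 3e4, nCycles = 10L,
                                  rtYield = 1, templateDilution = 1),
                        3000)@table
  expect_equal(scaled$ds, 3 * base$ds, tolerance = 1e-12)
  expect_equal(scaled$ss, 3 * base$ss, tolerance = 1e-12)
})

test_that("log-linear fitting behaves at its contract boundaries", {
  concs <- c(0.5, 1, 2, 4)
  fit <- suppressWarnings(fitLogLinear(concs, 3 + 2 * log2(concs)))
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 2, tolerance = 1e-12)

  flat <- fitLogLinear(concs, rep(7, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r.squared, 0)

  expect_error(fitLogLinear(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fitLogLinear(c(-1, 1, 2), c(1, 2, 3)), "> 0")
})

test_that("a dilution panel at the default protocol is log-linear at readout", {
  cfg <- PCRConfig()
  concs <- 10^seq(-1, 1, length.out = 7)
  ss <- vapply(concs, function(p) ssdnaAtReadout(simulatePCR(cfg, p)),
               numeric(1))
  fit <- fitLogLinear(concs, ss)
  expect_gt(fit$r.squared, 0.999)
  expect_gt(fit$slope, 0)
})
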