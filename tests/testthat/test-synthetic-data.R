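test_that("generation is deterministic under a fixed seed", {
  cfg <- smallStudyConfig()
  se1 <- generateExpression(cfg)
  se2 <- generateExpression(cfg)
  expect_identical(SummarizedExperiment::assay(se1, "log2expr"),
                   SummarizedExperiment::assay(se2, "log2expr"))
  p1 <- generatePatientPanel(fiveFeatureSpec(), "positive",
                             GeneratorConfig(seed = 7L), seed = 31)
  p2 <- generatePatientPanel(fiveFeatureSpec(), "positive",
                             GeneratorConfig(seed = 7L), seed = 31)
  expect_identical(as.numeric(p1), as.numeric(p2))
})

test_that("a seed is mandatory and effects below fourfold are rejected", {
  expect_error(GeneratorConfig(), "seed")
  expect_error(GeneratorConfig(
    informative = data.frame(feature = "miR-001", direction = 1,
                             effect = 1.5), seed = 1), "log2")
})

test_that("planted effects are recovered empirically at large n", {
  inf <- data.frame(feature = "miR-010", direction = 1, effect = 4)
  cfg <- GeneratorConfig(nPositive = 500L, nNegative = 500L,
                         nFeatures = 20L, informative = inf,
                         noiseSD = 1.4, seed = 17L)
  de <- differentialExpression(generateExpression(cfg))
  expect_lt(abs(de$log2FC[de$feature == "miR-010"] - 4), 0.2)
})

test_that("a null generator yields nothing for the fourfold screen", {
  cfg <- GeneratorConfig(nPositive = 500L, nNegative = 500L,
                         nFeatures = 100L,
                         informative = data.frame(feature = character(),
                                                  direction = numeric(),
                                                  effect = numeric()),
                         noiseSD = 0.3, seed = 23L)
  de <- differentialExpression(generateExpression(cfg))
  expect_equal(sum(de$retained), 0L)
})

test_that("generated matrices satisfy the expression-matrix contract", {
  se <- generateExpression(smallStudyConfig())
  expect_false(anyNA(SummarizedExperiment::assay(se, "log2expr")))
  expect_setequal(unique(se$class), c("HCC", "healthy"))
  expect_equal(dim(se), c(60L, 150L))
})

test_that("patient panels are class-consistent and stay in the assay range", {
  spec <- fiveFeatureSpec()
  cfg <- GeneratorConfig(seed = 7L)
  cohort <- generateCohortPanels(spec, cfg, nPerClass = 5L, seed = 41L)
  expect_length(cohort$panels, 10L)
  expect_true(all(sign(cohort$scores) ==
                    ifelse(cohort$labels == "HCC", 1, -1)))
  for (p in cohort$panels) {
    expect_true(all(p >= cfg@concRange[1] & p <= cfg@concRange[2]))
  }
  expect_true(all(abs(cohort$scores) >
                    1.2 * indeterminateMargin(spec)))
})

test_that("borderline mode flags near-tie panels", {
  spec <- fiveFeatureSpec()
  cfg <- GeneratorConfig(seed = 7L)
  p <- generatePatientPanel(spec, "positive", cfg, seed = 12,
                            borderline = TRUE)
  expect_true(attr(p, "borderline"))
  expect_lt(abs(attr(p, "score")), indeterminateMargin(spec))
})

test_that("standard curves are positive-slope, invertible and refittable", {
  exact <- generateStandardCurve("HEX", seed = 4, noiseSD = 0)
  fit <- stats::lm(au ~ nM, data = exact@points)
  expect_equal(suppressWarnings(summary(fit)$r.squared), 1,
               tolerance = 1e-12)
  expect_gt(exact@slope, 0)

  noisy <- generateStandardCurve("ROX", seed = 4, noiseSD = 0.02)
  clean <- generateStandardCurve("ROX", seed = 4, noiseSD = 0)
  expect_lt(abs(noisy@slope - clean@slope) / clean@slope, 0.05)

  # round trip nM -> au -> nM through the curve
  nm <- c(0, 3.7, 12)
  au <- exact@slope * nm + exact@intercept
  expect_equal(normalizeFluorescence(au, exact), nm, tolerance = 1e-9)
})
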