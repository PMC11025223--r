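test_that("fold changes are class mean differences on the log2 scale", {
  values <- rbind(
    up = c(rep(6, 4), rep(2, 4)),
    flat = rep(5, 8)
  )
  colnames(values) <- sprintf("s%d", 1:8)
  se <- makeExpressionSE(values, rep(c("HCC", "healthy"), each = 4),
                         "HCC", "healthy")
  de <- differentialExpression(se)
  expect_equal(de$log2FC, c(4, 0))
  expect_equal(de$direction, c("up", "none"))
  expect_equal(de$retained, c(TRUE, FALSE))

  solo <- makeExpressionSE(values[, 1:4], rep("HCC", 4), "HCC", "healthy")
  expect_error(differentialExpression(solo), "both classes")
})

test_that("the fourfold screen recovers planted features on known ground truth", {
  nInf <- 50L
  inf <- data.frame(
    feature = sprintf("miR-%03d", 1:nInf),
    direction = rep(c(1, -1), times = c(20, 30)),
    effect = seq(2.3, 3.0, length.out = nInf)
  )
  cfg <- GeneratorConfig(nPositive = 600L, nNegative = 600L,
                         nFeatures = 150L, informative = inf,
                         noiseSD = 0.5, seed = 21L)
  se <- generateExpression(cfg)
  de <- differentialExpression(se)
  kept <- de$feature[de$retained]
  expect_true(all(inf$feature %in% kept))
  expect_equal(length(kept), nInf)  # no null feature sneaks past the screen
  expect_equal(de$direction[match(inf$feature, de$feature)],
               ifelse(inf$direction > 0, "up", "down"))
})

test_that("permutation importance puts a lone informative feature first", {
  wins <- 0L
  for (s in 1:40) {
    inf <- data.frame(feature = "miR-005", direction = 1, effect = 2.5)
    cfg <- GeneratorConfig(nPositive = 60L, nNegative = 60L,
                           nFeatures = 10L, informative = inf,
                           noiseSD = 0.8, seed = s)
    se <- generateExpression(cfg)
    rk <- rankFeatures(se, featureIds(cfg), seed = s, ntree = 150)
    wins <- wins + (rk$feature[1] == "miR-005")
  }
  expect_gte(wins, 38L)  # >= 95% of seeds
})

test_that("ranking all-null features neither crashes nor drops features", {
  cfg <- GeneratorConfig(nPositive = 40L, nNegative = 40L,
                         nFeatures = 8L,
                         informative = data.frame(feature = character(),
                                                  direction = numeric(),
                                                  effect = numeric()),
                         noiseSD = 1, seed = 3L)
  se <- generateExpression(cfg)
  rk <- rankFeatures(se, featureIds(cfg), seed = 3)
  expect_setequal(rk$feature, featureIds(cfg))
})

test_that("top of the ranking recovers the largest planted effects", {
  cfg <- GeneratorConfig(nPositive = 150L, nNegative = 150L,
                         nFeatures = 100L, seed = 5L)
  se <- generateExpression(cfg)
  de <- differentialExpression(se)
  rk <- rankFeatures(se, de$feature[de$retained], seed = 5)
  expect_setequal(rk$feature[1:5], cfg@informative$feature)
})

test_that("a separable problem trains to AUC 1 and the split is stratified", {
  values <- rbind(
    f1 = c(rnorm(30, 8, 0.1), rnorm(30, 2, 0.1)),
    f2 = c(rnorm(30, 3, 0.1), rnorm(30, 7, 0.1))
  )
  colnames(values) <- sprintf("s%d", 1:60)
  se <- makeExpressionSE(values, rep(c("HCC", "healthy"), each = 30),
                         "HCC", "healthy")
  sp <- trainValidationSplit(se, seed = 2)
  expect_equal(sum(se$class == "HCC") / 2,
               sum(sp$train$class == "HCC"))
  panels <- trainPanels(sp$train, sp$validation, c("f1", "f2"),
                        kRange = 1:2, seed = 2)
  expect_equal(panels[[2]]@trainAUC, 1)
  expect_equal(panels[[2]]@validAUC, 1)
  # the recovered signs match the separation directions
  expect_gt(panels[[2]]@weights[["f1"]], 0)
  expect_lt(panels[[2]]@weights[["f2"]], 0)
})

test_that("doubling the positive-class penalty does not lower sensitivity", {
  cfg <- GeneratorConfig(nPositive = 40L, nNegative = 160L,
                         nFeatures = 30L, noiseSD = 2.5, seed = 13L)
  se <- generateExpression(cfg)
  sp <- trainValidationSplit(se, seed = 13)
  feats <- cfg@informative$feature
  sens <- vapply(c(1, 2), function(ratio) {
    panels <- trainPanels(sp$train, sp$validation, feats, kRange = 5,
                          classPenaltyRatio = ratio, seed = 13)
    p <- panels[[1]]
    x <- SummarizedExperiment::assay(sp$validation, "log2expr")[
      features <- p@features, , drop = FALSE]
    inputs <- 0.753 * (x - rowMeans(
      SummarizedExperiment::assay(sp$train, "log2expr")[features, ,
                                                        drop = FALSE])) +
      3.5
    scores <- as.vector(crossprod(inputs, p@weights)) + p@bias
    truth <- sp$validation$class
    sum(scores > 0 & truth == "HCC") / sum(truth == "HCC")
  }, numeric(1))
  expect_gte(sens[2], sens[1])
})

test_that("panel selection maximizes validation AUC and prefers smaller panels on ties", {
  mkPanel <- function(k, auc) {
    methods::new("PanelModel",
      features = sprintf("f%d", seq_len(k)),
      weights = setNames(rep(1, k), sprintf("f%d", seq_len(k))),
      rawWeights = setNames(rep(1, k), sprintf("f%d", seq_len(k))),
      bias = 0, trainAUC = auc, validAUC = auc, k = as.integer(k))
  }
  spec <- selectClassifier(list(mkPanel(3, 0.98), mkPanel(5, 0.98)))
  expect_equal(spec@metadata$k, 3L)
  single <- selectClassifier(list(mkPanel(2, 0.9)))
  expect_equal(spec@metadata$auc_valid, 0.98)
  expect_equal(single@metadata$k, 2L)
  expect_error(selectClassifier(list()), "at least one")
})

test_that("one-decimal rounding barely moves the validation AUC", {
  cfg <- smallStudyConfig()
  se <- generateExpression(cfg)
  sp <- trainValidationSplit(se, seed = 11)
  de <- differentialExpression(sp$train)
  rk <- rankFeatures(sp$train, de$feature[de$retained], seed = 11,
                     ntree = 200)
  panels <- trainPanels(sp$train, sp$validation, rk, seed = 11)
  spec <- selectClassifier(panels, sp$validation, positiveClass = "HCC",
                           negativeClass = "healthy")
  expect_lt(abs(spec@metadata$auc_valid -
                  spec@metadata$auc_valid_rounded), 0.01)
})

test_that("weights sit exactly on the one-decimal grid", {
  spec <- fiveFeatureSpec()
  w <- weights(spec)
  expect_equal(w, round(w * 10) / 10)
  expect_error(methods::new("LinearClassifierSpec",
    features = "f", weights = c(f = 1.23), bias = 0,
    positiveClass = "a", negativeClass = "b", amplifier0 = 100,
    rateConstant = 1e-4, inputMap = list(), exprOffsets = numeric(),
    converters = list(),
    calibrationTable = data.frame(weight = numeric(0),
                                  inhibitor0 = numeric(0)),
    metadata = list()), "one-decimal")
})
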