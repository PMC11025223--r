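#' @include classifier-compiler.R
NULL

#' Generator configuration constructor
#'
#' @param nPositive,nNegative samples per class (defaults 345 and 958,
#'   the class structure of a serum miRNA HCC profiling study).
#' @param nFeatures number of miRNA features; ids are `miR-001` ...
#' @param informative data.frame (`feature`, `direction` in +1/-1, `effect`
#'   >= 2 log2 units). The default plants five informative miRNAs with
#'   effects 2.3-3.0 (5- to 8-fold) in alternating directions; the smallest
#'   planted effect sits about three sampling standard errors above the
#'   fourfold screen so the "informative" designation survives estimation
#'   noise at the default sample sizes.
#' @param noiseSD within-class SD on the log2 scale (default 1.4; see the
#'   class documentation for the rationale).
#' @param baselineRange baseline log2 abundance range (default 6-10).
#' @param concRange plasma concentration range in pM (default 0.1-10, the
#'   validated range of the PCR front end).
#' @param seed mandatory integer seed.
#' @return A validated [GeneratorConfig-class].
#' @export
GeneratorConfig <- function(nPositive = 345L, nNegative = 958L,
                            nFeatures = 200L, informative = NULL,
                            noiseSD = 1.4, baselineRange = c(6, 10),
                            concRange = c(0.1, 10), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  nFeatures <- as.integer(nFeatures)
  if (is.null(informative)) {
    idx <- round(seq(11, max(nFeatures - 10, 11), length.out = 5))
    informative <- data.frame(
      feature = sprintf("miR-%03d", idx),
      direction = c(1, -1, 1, -1, 1),
      effect = c(2.3, 2.5, 2.6, 2.8, 3.0),
      stringsAsFactors = FALSE
    )
  }
  methods::new("GeneratorConfig",
    nPositive = as.integer(nPositive), nNegative = as.integer(nNegative),
    nFeatures = nFeatures, informative = informative, noiseSD = noiseSD,
    baselineRange = baselineRange, concRange = concRange,
    seed = as.integer(seed))
}

#' @export
#' @rdname GeneratorConfig
featureIds <- function(config) {
  sprintf("miR-%03d", seq_len(config@nFeatures))
}

# deterministic per-config ground truth: baselines and class means
.generatorTruth <- function(config) {
  feats <- featureIds(config)
  set.seed(config@seed)
  baselines <- stats::setNames(
    stats::runif(config@nFeatures, config@baselineRange[1],
                 config@baselineRange[2]), feats)
  delta <- stats::setNames(numeric(config@nFeatures), feats)
  inf <- config@informative
  if (nrow(inf)) {
    missing <- setdiff(inf$feature, feats)
    if (length(missing)) {
      stop("informative features outside the feature set: ",
           paste(missing, collapse = ", "))
    }
    delta[inf$feature] <- inf$direction * inf$effect
  }
  list(
    features = feats,
    baselines = baselines,
    log2FC = delta,
    meanPositive = baselines + delta / 2,
    meanNegative = baselines - delta / 2,
    informative = inf
  )
}

#' Assemble an expression SummarizedExperiment from a matrix and labels
#'
#' @param values features x samples matrix of log2 expression (no missing
#'   values).
#' @param labels character/factor of per-sample class labels (binary).
#' @param positiveClass,negativeClass class labels.
#' @return SummarizedExperiment with assay `log2expr`.
#' @export
makeExpressionSE <- function(values, labels, positiveClass, negativeClass) {
  if (anyNA(values)) stop("expression values must not contain NA")
  labels <- as.character(labels)
  if (!all(labels %in% c(positiveClass, negativeClass))) {
    stop("labels must be one of the two declared classes")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = values),
    colData = S4Vectors::DataFrame(class = labels)
  )
  S4Vectors::metadata(se)$positiveClass <- positiveClass
  S4Vectors::metadata(se)$negativeClass <- negativeClass
  se
}

#' Generate a two-class expression matrix with planted fold changes
#'
#' Log-normal expression model: each feature's log2 value is its
#' class-dependent mean (baseline +/- half the planted effect) plus Gaussian
#' noise. The ground truth (baselines, planted effects, class means) is
#' stored in `metadata(se)$groundTruth`.
#'
#' @param config a [GeneratorConfig-class].
#' @param positiveClass,negativeClass class labels used in `colData`.
#' @return SummarizedExperiment (features x samples, assay `log2expr`).
#' @examples
#' se <- generateExpression(GeneratorConfig(nPositive = 20, nNegative = 30,
#'                                          nFeatures = 50, seed = 1))
#' dim(se)
#' @export
generateExpression <- function(config, positiveClass = "HCC",
                               negativeClass = "healthy") {
  methods::validObject(config)
  truth <- .generatorTruth(config)
  nP <- config@nPositive
  nN <- config@nNegative
  # .generatorTruth consumed the seed-defined stream head; continue from it
  noise <- matrix(stats::rnorm(config@nFeatures * (nP + nN),
                               sd = config@noiseSD),
                  nrow = config@nFeatures)
  means <- cbind(
    matrix(truth$meanPositive, config@nFeatures, nP),
    matrix(truth$meanNegative, config@nFeatures, nN)
  )
  values <- means + noise
  rownames(values) <- truth$features
  colnames(values) <- c(sprintf("%s_%03d", positiveClass, seq_len(nP)),
                        sprintf("%s_%03d", negativeClass, seq_len(nN)))
  labels <- c(rep(positiveClass, nP), rep(negativeClass, nN))
  se <- makeExpressionSE(values, labels, positiveClass, negativeClass)
  S4Vectors::metadata(se)$groundTruth <- truth
  S4Vectors::metadata(se)$seed <- config@seed
  se
}

#' Generate one synthetic patient's miRNA concentration panel
#'
#' Draws the classifier's features from the class-conditional expression
#' model, converts them to plasma concentrations through the spec's
#' expression offsets (log2 conc_pM = expression - offset), clamps to the
#' generator's concentration range, and accepts the draw when the in-silico
#' score has the class-consistent sign with a margin comfortably above the
#' indeterminate threshold (or, in borderline mode, below it). Deterministic
#' given `seed`.
#'
#' @param spec a [LinearClassifierSpec-class] whose features belong to the
#'   generator's feature set.
#' @param class "positive" or "negative" (relative to the spec's labels).
#' @param config a [GeneratorConfig-class].
#' @param seed integer seed.
#' @param borderline logical; draw a near-tie panel (|score| below the
#'   indeterminate margin) for indeterminate-call testing.
#' @param marginFactor accepted draws must satisfy |score| >
#'   marginFactor x indeterminate margin (ignored in borderline mode).
#' @param maxTries rejection-sampling budget.
#' @return named numeric of concentrations (pM) with attributes `score`
#'   (in-silico score), `class` and `borderline`.
#' @export
generatePatientPanel <- function(spec, class = c("positive", "negative"),
                                 config, seed = config@seed,
                                 borderline = FALSE, marginFactor = 1.2,
                                 maxTries = 200L) {
  class <- match.arg(class)
  truth <- .generatorTruth(config)
  missing <- setdiff(spec@features, truth$features)
  if (length(missing)) {
    stop("classifier features unknown to the generator: ",
         paste(missing, collapse = ", "))
  }
  mu <- if (class == "positive") truth$meanPositive else truth$meanNegative
  mu <- mu[spec@features]
  offsets <- if (length(spec@exprOffsets)) {
    spec@exprOffsets[spec@features]
  } else {
    truth$baselines[spec@features]
  }
  delta <- indeterminateMargin(spec)
  wantSign <- if (class == "positive") 1 else -1
  set.seed(seed)
  best <- NULL
  bestGap <- -Inf
  for (i in seq_len(maxTries)) {
    x <- stats::rnorm(length(mu), mean = mu, sd = config@noiseSD)
    conc <- pmin(pmax(2^(x - offsets), config@concRange[1]),
                 config@concRange[2])
    names(conc) <- spec@features
    inputs <- spec@inputMap$slope * log2(conc) + spec@inputMap$intercept
    score <- evaluateInSilico(spec, inputs)$score
    ok <- if (borderline) {
      abs(score) < delta
    } else {
      sign(score) == wantSign && abs(score) > marginFactor * delta
    }
    gap <- if (borderline) -abs(score) else wantSign * score
    if (gap > bestGap) {
      bestGap <- gap
      best <- list(conc = conc, score = score)
    }
    if (ok) break
  }
  out <- best$conc
  attr(out, "score") <- best$score
  attr(out, "class") <- class
  attr(out, "borderline") <- borderline
  out
}

#' Generate a cohort of synthetic patient panels
#'
#' @param spec a [LinearClassifierSpec-class].
#' @param config a [GeneratorConfig-class].
#' @param nPerClass panels per class (default 10, i.e. a 10 + 10 cohort).
#' @param seed integer seed.
#' @return list with `panels` (list of named concentration vectors),
#'   `labels` (true class labels, in spec label vocabulary) and `scores`
#'   (in-silico scores).
#' @export
generateCohortPanels <- function(spec, config, nPerClass = 10L,
                                 seed = config@seed) {
  classes <- rep(c("positive", "negative"), each = nPerClass)
  panels <- lapply(seq_along(classes), function(i) {
    generatePatientPanel(spec, classes[i], config, seed = seed + i)
  })
  names(panels) <- sprintf("patient_%02d", seq_along(panels))
  list(
    panels = panels,
    labels = ifelse(classes == "positive", spec@positiveClass,
                    spec@negativeClass),
    scores = vapply(panels, function(p) attr(p, "score"), numeric(1))
  )
}

#' Generate a reporter standard curve
#'
#' Draws a linear fluorescence-vs-concentration curve, simulates calibration
#' points with optional Gaussian instrument noise, and refits the line; the
#' refit determines the stored slope/intercept, as on a real instrument.
#'
#' @param channel "HEX" or "ROX".
#' @param seed integer seed.
#' @param noiseSD instrument noise as a fraction of the full-scale signal
#'   (default 0: exact curve).
#' @param nPoints number of calibration concentrations (0 to `maxNM`).
#' @param maxNM top calibration concentration (nM).
#' @return A [StandardCurve-class].
#' @export
generateStandardCurve <- function(channel = c("HEX", "ROX"), seed = 1L,
                                  noiseSD = 0, nPoints = 8L, maxNM = 50) {
  channel <- match.arg(channel)
  set.seed(seed + match(channel, c("HEX", "ROX")))
  slope <- stats::runif(1, 0.8, 1.5)        # a.u. per nM
  intercept <- stats::runif(1, 2, 20)       # baseline a.u.
  nM <- seq(0, maxNM, length.out = nPoints)
  au <- slope * nM + intercept +
    stats::rnorm(nPoints, sd = noiseSD * (slope * maxNM + intercept))
  fit <- stats::lm(au ~ nM)
  methods::new("StandardCurve",
    channel = channel,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    points = data.frame(nM = nM, au = au))
}

#' Worked-example HCC classifier over the default synthetic study
#'
#' Builds a five-miRNA classifier on the generator's informative features,
#' with signed weights in the wet-lab-validated range, expression offsets
#' taken from the generator's baselines, the bias centered on the midpoint
#' of the two class means, and a calibrated molecular front end attached.
#' Used by the examples and the end-to-end fixtures.
#'
#' @param config a [GeneratorConfig-class] with five informative features.
#' @param weights signed one-decimal weights, one per informative feature;
#'   signs should match the planted directions.
#' @param pcrConfig,converter front-end configuration for calibration.
#' @return A calibrated [LinearClassifierSpec-class].
#' @export
demoClassifier <- function(config,
                           weights = c(2.4, -2.6, 1.8, -1.2, 2.0) *
                             sign(config@informative$direction) *
                             sign(c(2.4, -2.6, 1.8, -1.2, 2.0)),
                           pcrConfig = PCRConfig(),
                           converter = ConverterSpec()) {
  truth <- .generatorTruth(config)
  feats <- config@informative$feature
  stopifnot(length(weights) == length(feats))
  spec <- LinearClassifierSpec(
    features = feats, weights = weights,
    positiveClass = "HCC", negativeClass = "healthy",
    exprOffsets = truth$baselines[feats]
  )
  spec <- calibrateClassifier(spec, pcrConfig, converter)
  toInput <- function(x) {
    spec@inputMap$slope * (x - truth$baselines[feats]) +
      spec@inputMap$intercept
  }
  mid <- (toInput(truth$meanPositive[feats]) +
            toInput(truth$meanNegative[feats])) / 2
  spec@bias <- -sum(weights(spec) * mid)
  spec
}
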