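#' @include classifier-compiler.R
NULL

.assayMatrix <- function(se) {
  SummarizedExperiment::assay(se, "log2expr")
}

.classLabels <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  if (!"class" %in% names(cd)) stop("colData must carry a 'class' column")
  as.character(cd$class)
}

.classPair <- function(se, positiveClass = NULL) {
  labels <- .classLabels(se)
  if (is.null(positiveClass)) {
    positiveClass <- S4Vectors::metadata(se)$positiveClass
  }
  classes <- unique(labels)
  if (length(classes) < 2L) {
    stop("both classes must be represented; found only: ",
         paste(classes, collapse = ", "))
  }
  if (length(classes) > 2L) stop("labels must be binary")
  if (is.null(positiveClass)) positiveClass <- classes[1]
  list(positive = positiveClass,
       negative = setdiff(classes, positiveClass))
}

#' Differential-expression screen
#'
#' Per-feature log2 fold change between the two classes (mean in the positive
#' class minus mean in the negative class, on the log2 scale already used by
#' the expression matrix). Features are retained when the absolute fold
#' change reaches `lfcThreshold` (default 2, i.e. a fourfold difference).
#'
#' @param se SummarizedExperiment with assay `log2expr` and a binary
#'   `class` column in `colData`.
#' @param positiveClass label of the positive (disease) class; defaults to
#'   `metadata(se)$positiveClass`.
#' @param lfcThreshold |log2 FC| retention threshold.
#' @return data.frame with columns `feature`, `log2FC`, `direction`
#'   ("up"/"down"/"none") and `retained`.
#' @export
differentialExpression <- function(se, positiveClass = NULL,
                                   lfcThreshold = 2) {
  pair <- .classPair(se, positiveClass)
  x <- .assayMatrix(se)
  labels <- .classLabels(se)
  fc <- rowMeans(x[, labels == pair$positive, drop = FALSE]) -
    rowMeans(x[, labels == pair$negative, drop = FALSE])
  retained <- abs(fc) >= lfcThreshold
  data.frame(
    feature = rownames(x),
    log2FC = unname(fc),
    direction = ifelse(!retained, "none", ifelse(fc > 0, "up", "down")),
    retained = unname(retained),
    stringsAsFactors = FALSE
  )
}

#' Random-forest importance ranking
#'
#' Fits a random forest on the retained features and ranks them by permutation
#' importance (Mean Decrease Accuracy), with impurity importance (Mean
#' Decrease Gini) as the tiebreaker. Deterministic given `seed`.
#'
#' @param se SummarizedExperiment (see [differentialExpression()]).
#' @param retained character vector of feature ids to rank (non-empty).
#' @param seed integer seed.
#' @param ntree number of trees.
#' @param positiveClass positive class label (see [differentialExpression()]).
#' @return data.frame sorted by rank, columns `feature`,
#'   `MeanDecreaseAccuracy`, `MeanDecreaseGini`.
#' @export
rankFeatures <- function(se, retained, seed = 1L, ntree = 500L,
                         positiveClass = NULL) {
  if (!length(retained)) stop("retained feature set must be non-empty")
  pair <- .classPair(se, positiveClass)
  x <- t(.assayMatrix(se)[retained, , drop = FALSE])
  y <- factor(.classLabels(se), levels = c(pair$negative, pair$positive))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                   importance = TRUE)
  imp <- randomForest::importance(rf)
  ord <- order(-imp[, "MeanDecreaseAccuracy"], -imp[, "MeanDecreaseGini"])
  data.frame(
    feature = rownames(imp)[ord],
    MeanDecreaseAccuracy = unname(imp[ord, "MeanDecreaseAccuracy"]),
    MeanDecreaseGini = unname(imp[ord, "MeanDecreaseGini"]),
    stringsAsFactors = FALSE
  )
}

#' Stratified train/validation split
#'
#' @param se SummarizedExperiment.
#' @param fraction training fraction per class (default 0.5).
#' @param seed integer seed.
#' @return list with SummarizedExperiments `train` and `validation`.
#' @export
trainValidationSplit <- function(se, fraction = 0.5, seed = 1L) {
  labels <- .classLabels(se)
  set.seed(seed)
  idx <- unlist(lapply(unique(labels), function(cl) {
    i <- which(labels == cl)
    sample(i, size = round(length(i) * fraction))
  }))
  list(train = se[, sort(idx)], validation = se[, -sort(idx)])
}

.aucOf <- function(scores, labels, positive, negative) {
  as.numeric(pROC::auc(
    pROC::roc(response = factor(labels, levels = c(negative, positive)),
              predictor = scores, levels = c(negative, positive),
              direction = "<", quiet = TRUE)))
}

.mapExprWeights <- function(wExpr, bExpr, inputMap, exprOffsets) {
  # input_i = slope * (x_i - offset_i) + intercept, per feature
  a <- inputMap$slope
  b <- inputMap$intercept
  wIn <- wExpr / a
  bIn <- bExpr - sum(wIn * (b - a * exprOffsets[names(wExpr)]))
  list(weights = wIn, bias = bIn)
}

.panelScores <- function(se, w, b) {
  x <- .assayMatrix(se)[names(w), , drop = FALSE]
  as.vector(crossprod(x, w)) + b
}

#' Train class-weighted linear SVM panels of increasing size
#'
#' For each panel size k, fits a linear-kernel support-vector machine on the
#' top-k ranked features with the positive-class misclassification penalty
#' `classPenaltyRatio` times the negative-class penalty (2:1 by default, so
#' false negatives on the disease class are penalized more). Features are
#' standardized before fitting and the weight vector is mapped back to the
#' raw expression scale, then to the classifier's nM input space through the
#' affine input map, rescaled so the largest |weight| is 2.5 (a common
#' positive rescaling of weights and bias leaves the decision unchanged), and
#' rounded to one decimal. The stored AUCs are computed from the unrounded
#' decision function; [selectClassifier()] re-checks the AUC after rounding.
#'
#' @param seTrain,seValid training and validation SummarizedExperiments.
#' @param ranking data.frame from [rankFeatures()] (or a character vector).
#' @param kRange panel sizes to fit (truncated to the ranking length).
#' @param classPenaltyRatio positive:negative misclassification penalty.
#' @param cost SVM regularization parameter C.
#' @param seed integer seed.
#' @param inputMap,exprOffsets affine map into the nM input space; defaults
#'   to slope 0.7530 nM per log2 unit and intercept 3.5 nM (the 1-6 nM input
#'   window over a 0.1-10 pM concentration range) with per-feature offsets
#'   set to the pooled training means.
#' @param positiveClass positive class label.
#' @return list of [PanelModel-class], one per k.
#' @export
trainPanels <- function(seTrain, seValid, ranking, kRange = 1:10,
                        classPenaltyRatio = 2, cost = 1, seed = 1L,
                        inputMap = NULL, exprOffsets = NULL,
                        positiveClass = NULL) {
  pair <- .classPair(seTrain, positiveClass)
  if (is.data.frame(ranking)) ranking <- ranking$feature
  kRange <- kRange[kRange <= length(ranking)]
  if (!length(kRange)) stop("ranking is shorter than every requested k")
  if (is.null(inputMap)) {
    inputMap <- list(slope = 5 / log2(10 / 0.1), intercept = 3.5,
                     concRange = c(0.1, 10), inputRange = c(1, 6))
  }
  xtr <- .assayMatrix(seTrain)
  if (is.null(exprOffsets)) {
    exprOffsets <- rowMeans(xtr)
  }
  ytr <- factor(.classLabels(seTrain),
                levels = c(pair$negative, pair$positive))
  if (nlevels(droplevels(ytr)) < 2L) {
    stop("degenerate split: training data contain a single class")
  }
  cw <- stats::setNames(c(1, classPenaltyRatio),
                        c(pair$negative, pair$positive))
  panels <- lapply(kRange, function(k) {
    feats <- ranking[seq_len(k)]
    xk <- t(xtr[feats, , drop = FALSE])
    mu <- colMeans(xk)
    sd <- apply(xk, 2, stats::sd)
    sd[sd == 0] <- 1
    z <- scale(xk, center = mu, scale = sd)
    set.seed(seed)
    fit <- e1071::svm(x = z, y = ytr, kernel = "linear", cost = cost,
                      class.weights = cw, scale = FALSE)
    wz <- as.vector(t(fit$coefs) %*% fit$SV)
    names(wz) <- colnames(z)
    bz <- -fit$rho
    # e1071 orients the decision value towards the first factor level;
    # flip so positive scores mean the positive class
    dec <- as.vector(z %*% wz) + bz
    if (.aucOf(dec, .classLabels(seTrain), pair$positive, pair$negative) <
        0.5) {
      wz <- -wz
      bz <- -bz
    }
    wExpr <- wz / sd
    bExpr <- bz - sum(wz * mu / sd)
    mapped <- .mapExprWeights(wExpr, bExpr, inputMap, exprOffsets)
    scl <- 2.5 / max(abs(mapped$weights))
    wIn <- mapped$weights * scl
    bIn <- mapped$bias * scl
    wRound <- round(wIn * 10) / 10
    methods::new("PanelModel",
      features = feats,
      weights = stats::setNames(wRound, feats),
      rawWeights = stats::setNames(wIn, feats),
      bias = bIn,
      trainAUC = .aucOf(.panelScores(seTrain, wExpr, bExpr),
                        .classLabels(seTrain), pair$positive,
                        pair$negative),
      validAUC = .aucOf(.panelScores(seValid, wExpr, bExpr),
                        .classLabels(seValid), pair$positive,
                        pair$negative),
      k = as.integer(k))
  })
  # the map and offsets the weights were expressed in travel with the
  # panels so selectClassifier() can store them in the emitted spec
  attr(panels, "inputMap") <- inputMap
  attr(panels, "exprOffsets") <- exprOffsets
  panels
}

#' Select the minimal best panel and emit a classifier specification
#'
#' The panel with the highest validation AUC wins; ties (within 1e-9) are
#' broken in favour of the smaller panel, preferring a minimal miRNA set.
#' Weights are the one-decimal roundings of the winning panel's input-space
#' weights; the AUC is re-checked after rounding and both values are stored
#' in the spec metadata.
#'
#' @param panels list of [PanelModel-class] from [trainPanels()].
#' @param seValid optional validation SummarizedExperiment for the
#'   post-rounding AUC re-check.
#' @param positiveClass,negativeClass class labels for the emitted spec.
#' @param inputMap,exprOffsets affine input map and per-feature offsets the
#'   panel weights are expressed in; by default taken from the attributes
#'   [trainPanels()] attaches to its result, so the emitted spec is
#'   consistent with the training-time mapping.
#' @param converters optional named list of [ConverterSpec-class].
#' @param seed seed recorded in the spec metadata.
#' @return A [LinearClassifierSpec-class].
#' @export
selectClassifier <- function(panels, seValid = NULL,
                             positiveClass = "positive",
                             negativeClass = "negative",
                             inputMap = NULL, exprOffsets = NULL,
                             converters = list(), seed = NA_integer_) {
  if (!length(panels)) stop("need at least one panel")
  aucs <- vapply(panels, function(p) p@validAUC, numeric(1))
  ks <- vapply(panels, function(p) p@k, integer(1))
  best <- max(aucs)
  winner <- panels[[which(aucs > best - 1e-9)[
    which.min(ks[aucs > best - 1e-9])]]]
  if (is.null(inputMap)) inputMap <- attr(panels, "inputMap")
  if (is.null(exprOffsets)) exprOffsets <- attr(panels, "exprOffsets")
  if (is.null(inputMap)) {
    inputMap <- list(slope = 5 / log2(10 / 0.1), intercept = 3.5,
                     concRange = c(0.1, 10), inputRange = c(1, 6))
  }
  if (is.null(exprOffsets)) {
    exprOffsets <- stats::setNames(numeric(length(winner@features)),
                                   winner@features)
  }
  meta <- list(
    format_version = "1.0",
    k = winner@k,
    auc_train = winner@trainAUC,
    auc_valid = winner@validAUC,
    seed = seed
  )
  spec <- LinearClassifierSpec(
    features = winner@features,
    weights = unname(winner@weights),
    bias = round(winner@bias * 10) / 10,
    positiveClass = positiveClass,
    negativeClass = negativeClass,
    inputMap = inputMap,
    exprOffsets = exprOffsets[winner@features],
    converters = converters,
    metadata = meta
  )
  if (!is.null(seValid)) {
    pair <- list(positive = positiveClass, negative = negativeClass)
    x <- .assayMatrix(seValid)[spec@features, , drop = FALSE]
    inputs <- spec@inputMap$slope *
      (x - spec@exprOffsets[spec@features]) + spec@inputMap$intercept
    scores <- as.vector(crossprod(inputs, spec@weights)) + spec@bias
    spec@metadata$auc_valid_rounded <-
      .aucOf(scores, .classLabels(seValid), positiveClass, negativeClass)
  }
  spec
}
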