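#' @include signal-transformation.R classifier-compiler.R
NULL

#' Calibrate the pipeline's affine input map
#'
#' Runs the asymmetric-PCR model followed by strand-displacement conversion
#' on the endpoints of the target concentration range, and solves for the
#' post-PCR dilution and the converter-stage threshold that place the
#' produced input concentrations exactly on the target input window
#' (default 1-6 nM over 0.1-10 pM). The fitted affine map
#' input = slope x log2(conc_pM) + intercept is what makes molecular and
#' in-silico scores comparable; it is stored in the classifier JSON.
#'
#' @param pcrConfig a [PCRConfig-class].
#' @param converter a template [ConverterSpec-class]; its yield enters the
#'   calibration, and its threshold is overwritten.
#' @param concRange target concentration range (pM).
#' @param inputRange target input window (nM).
#' @param nPoints points used for the log-linear map fit.
#' @return list with `slope`, `intercept` (nM per log2 pM; nM), `dilution`,
#'   `threshold` (nM), `concRange`, `inputRange`, and `r.squared` of the
#'   map fit.
#' @export
calibrateInputMap <- function(pcrConfig = PCRConfig(),
                              converter = ConverterSpec(),
                              concRange = c(0.1, 10),
                              inputRange = c(1, 6), nPoints = 5L) {
  concs <- 2^seq(log2(concRange[1]), log2(concRange[2]),
                 length.out = nPoints)
  ss <- vapply(concs, function(cc) {
    ssdnaAtReadout(simulatePCR(pcrConfig, cc))
  }, numeric(1))
  g <- converter@yield
  dilution <- diff(inputRange) / (g * (ss[nPoints] - ss[1]))
  threshold <- dilution * g * ss[1] - inputRange[1]
  inputs <- pmax(0, dilution * g * ss - threshold)
  fit <- stats::lm(inputs ~ log2(concs))
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    dilution = dilution, threshold = threshold,
    concRange = concRange, inputRange = inputRange,
    r.squared = summary(fit)$r.squared
  )
}

#' Attach a calibrated molecular front end to a classifier spec
#'
#' Replaces the spec's input map with the calibrated pipeline map and builds
#' one converter per feature carrying the calibrated threshold.
#'
#' @param spec a [LinearClassifierSpec-class].
#' @param pcrConfig a [PCRConfig-class].
#' @param converter template [ConverterSpec-class].
#' @param ... passed to [calibrateInputMap()].
#' @return The updated spec (weights and bias are re-expressed on the new
#'   input scale if a previous map existed).
#' @export
calibrateClassifier <- function(spec, pcrConfig = PCRConfig(),
                                converter = ConverterSpec(), ...) {
  cal <- calibrateInputMap(pcrConfig, converter, ...)
  old <- spec@inputMap
  if (length(old) && (abs(old$slope - cal$slope) > 1e-9 ||
                      abs(old$intercept - cal$intercept) > 1e-9)) {
    # re-express weights on the new input scale: input_new = (a2/a1) *
    # input_old + (b2 - a2/a1 * b1); a common positive rescaling plus a
    # bias shift keeps the decision identical
    r <- old$slope / cal$slope
    wNew <- round(spec@weights * r * 10) / 10
    bNew <- spec@bias + sum(spec@weights * old$intercept) -
      sum(wNew * cal$intercept)
    spec@weights[] <- wNew
    spec@bias <- bNew
  }
  spec@inputMap <- cal[c("slope", "intercept", "dilution", "threshold",
                         "concRange", "inputRange", "r.squared")]
  conv <- lapply(spec@features, function(f) {
    ConverterSpec(
      target = paste0("ss_", f), output = paste0("Input_", f),
      converter0 = converter@converter0, yield = converter@yield,
      leakRate = converter@leakRate,
      rateConstant = converter@rateConstant,
      threshold = cal$threshold
    )
  })
  names(conv) <- spec@features
  spec@converters <- conv
  spec
}

#' Normalize instrument fluorescence to concentration
#'
#' Inverts the reporter standard curve: nM = (au - intercept) / slope,
#' clipped at zero.
#'
#' @param rawAU fluorescence in arbitrary units.
#' @param curve a [StandardCurve-class] or a list with `slope` and
#'   `intercept`.
#' @return concentration (nM).
#' @export
normalizeFluorescence <- function(rawAU, curve) {
  slope <- if (is(curve, "StandardCurve")) curve@slope else curve$slope
  intercept <- if (is(curve, "StandardCurve")) curve@intercept
               else curve$intercept
  if (!is.numeric(slope) || slope <= 0) {
    stop("standard-curve slope must be > 0")
  }
  pmax(0, (rawAU - intercept) / slope)
}

#' Classify one sample through the full molecular pipeline
#'
#' Deterministic composition of the stages a sample goes through: asymmetric
#' PCR of each miRNA, post-PCR dilution, associative strand-displacement
#' conversion (with the calibrated threshold), compilation of the classifier
#' network with the produced inputs, mass-action simulation to steady state,
#' fluorophore endpoints, instrument read-out through the reporter standard
#' curves, normalization back to concentrations, and the diagnostic call
#' from the HEX - ROX margin against the indeterminate threshold.
#'
#' @param panel named numeric of miRNA concentrations (pM) covering the
#'   classifier features.
#' @param spec a calibrated [LinearClassifierSpec-class] (see
#'   [calibrateClassifier()]).
#' @param pcrConfig a [PCRConfig-class].
#' @param curves list with elements `HEX` and `ROX` ([StandardCurve-class]);
#'   defaults to exact unit curves.
#' @param sampleId sample identifier.
#' @param tEnd classifier-network integration horizon (s).
#' @return A [ClassificationResult-class].
#' @export
runSample <- function(panel, spec, pcrConfig = PCRConfig(), curves = NULL,
                      sampleId = "sample", tEnd = 4e5) {
  missing <- setdiff(spec@features, names(panel))
  if (length(missing)) {
    stop("panel does not cover classifier feature(s): ",
         paste(missing, collapse = ", "))
  }
  if (!length(spec@inputMap) || is.null(spec@inputMap$dilution)) {
    stop("classifier spec has no calibrated input map; ",
         "run calibrateClassifier() first")
  }
  if (is.null(curves)) {
    curves <- list(
      HEX = methods::new("StandardCurve", channel = "HEX", slope = 1,
                         intercept = 0, points = data.frame()),
      ROX = methods::new("StandardCurve", channel = "ROX", slope = 1,
                         intercept = 0, points = data.frame())
    )
  }
  warns <- character()
  dil <- spec@inputMap$dilution

  .logStage("pcr", sampleId, ": ", length(spec@features), " features")
  inputs <- numeric(length(spec@features))
  names(inputs) <- spec@features
  for (f in spec@features) {
    conc <- unname(panel[[f]])
    tr <- withCallingHandlers(
      simulatePCR(pcrConfig, conc),
      warning = function(w) {
        warns <<- c(warns, paste0("pcr[", f, "]: ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    tab <- tr@table
    if (tab$excess[nrow(tab)] < 1e-6) {
      warns <- c(warns, paste0("pcr[", f, "]: excess primer exhausted; ",
                               "ssDNA readout saturated"))
    }
    ss <- ssdnaAtReadout(tr) * dil
    cv <- spec@converters[[f]]
    if (is.null(cv)) stop("no converter for feature ", f)
    inputs[f] <- withCallingHandlers(
      as.numeric(convertSSDNA(cv, ss)),
      warning = function(w) {
        warns <<- c(warns, paste0("convert[", f, "]: ",
                                  conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }

  .logStage("simulate", sampleId, ": inputs ",
            paste(sprintf("%.2f", inputs), collapse = "/"))
  net <- compileClassifier(spec, inputs = inputs)
  trace <- simulateNetwork(net, tEnd = tEnd)
  if (!isSteady(trace)) {
    warns <- c(warns, "classifier network did not reach steady state")
  }
  raw <- endpoint(trace, c("FluorHEX", "FluorROX"), warn = FALSE)
  names(raw) <- c("HEX", "ROX")

  au <- c(
    HEX = curves$HEX@slope * raw[["HEX"]] + curves$HEX@intercept,
    ROX = curves$ROX@slope * raw[["ROX"]] + curves$ROX@intercept
  )
  nm <- c(HEX = normalizeFluorescence(au[["HEX"]], curves$HEX),
          ROX = normalizeFluorescence(au[["ROX"]], curves$ROX))
  margin <- nm[["HEX"]] - nm[["ROX"]]
  delta <- indeterminateMargin(spec)
  call <- if (abs(margin) < delta) {
    "indeterminate"
  } else if (margin > 0) {
    spec@positiveClass
  } else {
    spec@negativeClass
  }

  logConc <- log2(pmin(pmax(panel[spec@features],
                            spec@inputMap$concRange[1]),
                       spec@inputMap$concRange[2]))
  silico <- evaluateInSilico(
    spec, stats::setNames(spec@inputMap$slope * logConc +
                            spec@inputMap$intercept, spec@features))

  methods::new("ClassificationResult",
    sampleId = sampleId, raw = raw, normalizedAU = au, normalizedNM = nm,
    margin = margin, call = call, inSilicoScore = silico$score,
    warnings = warns)
}

#' Classify a cohort of panels
#'
#' @param panels named list of concentration panels (pM).
#' @param spec,pcrConfig,curves,tEnd see [runSample()].
#' @return list of [ClassificationResult-class], named like `panels`.
#' @export
classifyCohort <- function(panels, spec, pcrConfig = PCRConfig(),
                           curves = NULL, tEnd = 4e5) {
  ids <- names(panels)
  if (is.null(ids)) ids <- sprintf("sample_%02d", seq_along(panels))
  res <- lapply(seq_along(panels), function(i) {
    runSample(panels[[i]], spec, pcrConfig, curves, sampleId = ids[i],
              tEnd = tEnd)
  })
  names(res) <- ids
  res
}

#' Confusion statistics for a classified cohort
#'
#' Indeterminate calls are conservatively counted as misclassifications
#' (a false negative on a true positive, a false positive on a true
#' negative). Counts are integers and the three fractions are exact; they
#' are only rounded when printed.
#'
#' @param calls character vector of calls (class labels or
#'   "indeterminate"), or a list of [ClassificationResult-class].
#' @param truth character vector of true labels.
#' @param positiveClass,negativeClass the two labels.
#' @return A [ConfusionSummary-class].
#' @examples
#' calls <- c(rep("HCC", 15), rep("healthy", 2),
#'            rep("healthy", 15), rep("HCC", 3))
#' truth <- c(rep("HCC", 17), rep("healthy", 18))
#' confusionStats(calls, truth, "HCC", "healthy")
#' @export
confusionStats <- function(calls, truth, positiveClass, negativeClass) {
  if (is.list(calls)) {
    calls <- vapply(calls, diagnosticCall, character(1))
  }
  if (length(calls) != length(truth)) {
    stop("calls and truth must have equal length")
  }
  if (!all(truth %in% c(positiveClass, negativeClass))) {
    stop("truth labels must be binary over the declared classes")
  }
  isPos <- truth == positiveClass
  tp <- sum(isPos & calls == positiveClass)
  fn <- sum(isPos & calls != positiveClass)
  tn <- sum(!isPos & calls == negativeClass)
  fp <- sum(!isPos & calls != negativeClass)
  methods::new("ConfusionSummary",
    tp = as.integer(tp), fn = as.integer(fn), tn = as.integer(tn),
    fp = as.integer(fp),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
    accuracy = (tp + tn) / length(truth))
}

#' @rdname accessors
#' @export
setMethod("diagnosticCall", "ClassificationResult", function(x) x@call)

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf(
    "ClassificationResult '%s': call=%s (margin %+.3f nM, HEX=%.3f, ROX=%.3f nM)\n",
    object@sampleId, object@call, object@margin,
    object@normalizedNM[["HEX"]], object@normalizedNM[["ROX"]]))
  if (length(object@inSilicoScore) && !is.na(object@inSilicoScore)) {
    cat(sprintf("  in-silico reference score: %+.3f\n",
                object@inSilicoScore))
  }
  if (length(object@warnings)) {
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "ConfusionSummary", function(object) {
  cat(sprintf("ConfusionSummary: TP=%d FN=%d TN=%d FP=%d\n",
              object@tp, object@fn, object@tn, object@fp))
  cat(sprintf("  sensitivity %s, specificity %s, accuracy %s\n",
              formatPercent(object@sensitivity),
              formatPercent(object@specificity),
              formatPercent(object@accuracy)))
  invisible(NULL)
})

## tabular I/O ---------------------------------------------------------------

#' Panel, expression and result file formats
#'
#' Concentration panels are CSV with columns `sample_id`, `mirna_id`,
#' `concentration_pM`; expression matrices are CSV with samples in rows, one
#' `sample_id` column, one `class` label column and one column per miRNA;
#' per-sample results are TSV.
#'
#' @param path file path.
#' @param panels named list of named concentration vectors (pM).
#' @param results list of [ClassificationResult-class].
#' @param se SummarizedExperiment as produced by [generateExpression()].
#' @param positiveClass,negativeClass class labels (reader).
#' @name tabular-io
NULL

#' @rdname tabular-io
#' @export
readPanelCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "mirna_id", "concentration_pM")
  if (!all(need %in% names(df))) {
    stop("panel CSV '", path, "' must have columns ",
         paste(need, collapse = ", "))
  }
  if (any(df$concentration_pM <= 0)) {
    bad <- which(df$concentration_pM <= 0)[1]
    stop("panel CSV '", path, "' line ", bad + 1L,
         ": concentration_pM must be > 0")
  }
  split(stats::setNames(df$concentration_pM, df$mirna_id), df$sample_id)
}

#' @rdname tabular-io
#' @export
writePanelCSV <- function(panels, path) {
  df <- do.call(rbind, lapply(names(panels), function(id) {
    data.frame(sample_id = id, mirna_id = names(panels[[id]]),
               concentration_pM = as.numeric(panels[[id]]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tabular-io
#' @export
writeResultsTSV <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r@sampleId,
               hex_nM = r@raw[["HEX"]], rox_nM = r@raw[["ROX"]],
               hex_au = r@normalizedAU[["HEX"]],
               rox_au = r@normalizedAU[["ROX"]],
               margin_nM = r@margin, call = r@call,
               in_silico_score = r@inSilicoScore,
               warnings = paste(r@warnings, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname tabular-io
#' @export
writeExpressionCSV <- function(se, path) {
  x <- t(.assayMatrix(se))
  df <- data.frame(sample_id = rownames(x),
                   class = .classLabels(se), x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tabular-io
#' @export
readExpressionCSV <- function(path, positiveClass = NULL,
                              negativeClass = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(df))) {
    stop("expression CSV '", path,
         "' must have 'sample_id' and 'class' columns")
  }
  labels <- df$class
  classes <- unique(labels)
  if (length(classes) != 2L) {
    stop("expression CSV '", path, "' must contain exactly two classes")
  }
  if (is.null(positiveClass)) positiveClass <- classes[1]
  if (is.null(negativeClass)) negativeClass <- setdiff(classes,
                                                       positiveClass)
  values <- t(as.matrix(df[, setdiff(names(df), c("sample_id", "class")),
                           drop = FALSE]))
  colnames(values) <- df$sample_id
  if (anyNA(values)) stop("expression CSV '", path, "' contains NA values")
  makeExpressionSE(values, labels, positiveClass, negativeClass)
}

#' Adapter for a user-exported series-matrix style CSV/TSV
#'
#' Reads a features-in-rows, samples-in-columns matrix export (first column
#' feature ids) together with a separate two-column label table
#' (`sample_id`, `class`). Intended for user-supplied exports of public
#' expression series; nothing is downloaded.
#'
#' @param matrixPath path to the matrix file (CSV or TSV by extension).
#' @param labelPath path to the label CSV.
#' @param positiveClass,negativeClass class labels.
#' @return SummarizedExperiment.
#' @export
readSeriesMatrixCSV <- function(matrixPath, labelPath,
                                positiveClass = NULL,
                                negativeClass = NULL) {
  sep <- if (grepl("\\.tsv$|\\.txt$", matrixPath)) "\t" else ","
  m <- utils::read.table(matrixPath, sep = sep, header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(m[, -1, drop = FALSE])
  rownames(values) <- m[[1]]
  lab <- utils::read.csv(labelPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(lab))) {
    stop("label CSV must have 'sample_id' and 'class' columns")
  }
  idx <- match(colnames(values), lab$sample_id)
  if (anyNA(idx)) {
    stop("label CSV missing sample(s): ",
         paste(colnames(values)[is.na(idx)], collapse = ", "))
  }
  labels <- lab$class[idx]
  classes <- unique(labels)
  if (is.null(positiveClass)) positiveClass <- classes[1]
  if (is.null(negativeClass)) negativeClass <- setdiff(classes,
                                                       positiveClass)
  makeExpressionSE(values, labels, positiveClass, negativeClass)
}
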