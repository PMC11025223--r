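#' @include crn-core.R
NULL

#' Linear classifier specification constructor
#'
#' Features with |weight| below 0.05 (i.e. weights that round to 0.0 at the
#' one-decimal resolution) are rejected with a warning. Weights are snapped
#' to exact multiples of 0.1.
#'
#' @param features ordered miRNA ids.
#' @param weights signed numeric weights (one value per feature); stored at
#'   one-decimal resolution.
#' @param bias signed scalar, classifier input space (nM).
#' @param positiveClass,negativeClass class labels.
#' @param amplifier0 default amplifier concentration for compilation (nM).
#' @param rateConstant default strand-displacement rate constant
#'   (nM^-1 s^-1); 1e-4 nM^-1 s^-1 (1e5 M^-1 s^-1) is a typical
#'   toehold-mediated displacement rate.
#' @param inputMap affine map from log2(concentration pM) to input nM; see
#'   [calibrateInputMap()].
#' @param exprOffsets named numeric per-feature expression-to-concentration
#'   offsets.
#' @param converters named list of [ConverterSpec-class].
#' @param calibrationTable optional data.frame (`weight`, `inhibitor0`)
#'   of bench-calibrated inhibitor concentrations; when supplied,
#'   [compileClassifier()] uses it instead of the ideal
#'   inhibitor0 = amplifier0/|W| mapping.
#' @param metadata free-form provenance list.
#' @return A validated [LinearClassifierSpec-class].
#' @examples
#' spec <- LinearClassifierSpec(
#'   features = c("miR-1", "miR-4"), weights = c(1.5, -2),
#'   positiveClass = "HCC", negativeClass = "healthy"
#' )
#' weights(spec)
#' @export
LinearClassifierSpec <- function(features, weights, bias = 0,
                                 positiveClass = "positive",
                                 negativeClass = "negative",
                                 amplifier0 = 100, rateConstant = 1e-4,
                                 inputMap = list(), exprOffsets = numeric(),
                                 converters = list(),
                                 calibrationTable = NULL,
                                 metadata = list()) {
  stopifnot(length(features) == length(weights))
  drop <- abs(weights) < 0.05
  if (any(drop)) {
    warning("rejecting zero-weight feature(s): ",
            paste(features[drop], collapse = ", "))
    features <- features[!drop]
    weights <- weights[!drop]
  }
  weights <- round(weights * 10) / 10
  if (is.null(calibrationTable)) {
    calibrationTable <- data.frame(weight = numeric(0),
                                   inhibitor0 = numeric(0))
  }
  methods::new("LinearClassifierSpec",
    features = features,
    weights = stats::setNames(weights, features),
    bias = bias, positiveClass = positiveClass,
    negativeClass = negativeClass, amplifier0 = amplifier0,
    rateConstant = rateConstant, inputMap = inputMap,
    exprOffsets = exprOffsets, converters = converters,
    calibrationTable = calibrationTable, metadata = metadata)
}

#' @rdname accessors
#' @export
setMethod("features", "LinearClassifierSpec", function(x) x@features)

#' @rdname accessors
#' @param object a [LinearClassifierSpec-class] (for the `weights` method).
#' @export
setMethod("weights", "LinearClassifierSpec", function(object, ...) {
  object@weights
})

#' @rdname accessors
#' @export
setMethod("bias", "LinearClassifierSpec", function(x) x@bias)

setMethod("show", "LinearClassifierSpec", function(object) {
  cat(sprintf("LinearClassifierSpec: %d features, %s vs %s\n",
              length(object@features), object@positiveClass,
              object@negativeClass))
  w <- object@weights
  cat("  score =",
      paste(sprintf("%+.1f*[%s]", w, names(w)), collapse = " "),
      sprintf("%+.3g\n", object@bias))
  invisible(NULL)
})

#' Annihilator constructor
#'
#' @param annihilator0 annihilator complex concentration (nM).
#' @param kOn,kOff,k2 toehold binding, unbinding and irreversible collapse
#'   rates of the cooperative-hybridization gate. Single-output binding is
#'   fast but weak (large kOff), so a lone majority strand is not
#'   sequestered, while the two-output collapse is fast and irreversible;
#'   together with a reporter an order of magnitude slower this makes the
#'   subtraction run to completion before reporting.
#' @return An [AnnihilatorSpec-class].
#' @export
AnnihilatorSpec <- function(annihilator0 = 100, kOn = 2e-3, kOff = 0.05,
                            k2 = 1e-2) {
  methods::new("AnnihilatorSpec", annihilator0 = annihilator0, kOn = kOn,
               kOff = kOff, k2 = k2)
}

#' Reporter constructor
#'
#' @param channel "HEX" (positive channel) or "ROX" (negative channel).
#' @param reporter0 reporter duplex concentration (nM).
#' @param rateConstant displacement rate (nM^-1 s^-1); deliberately about
#'   three orders of magnitude below the annihilation rates (a short reporter
#'   toehold) so reporting reads out the finished computation rather than
#'   racing it.
#' @param curveSlope,curveIntercept linear standard curve (a.u. = slope * nM
#'   + intercept).
#' @return A [ReporterSpec-class].
#' @export
ReporterSpec <- function(channel = c("HEX", "ROX"), reporter0 = 150,
                         rateConstant = 2e-6, curveSlope = 1,
                         curveIntercept = 0) {
  channel <- match.arg(channel)
  methods::new("ReporterSpec", channel = channel, reporter0 = reporter0,
               rateConstant = rateConstant, curveSlope = curveSlope,
               curveIntercept = curveIntercept)
}

#' Closed-form limiting output of one competitive-inhibition unit
#'
#' In the linear regime (input0 <= inhibitor0) the output of the
#' catalytic-amplification/competitive-inhibition pair converges to
#' input0 * amplifier0 / inhibitor0 as t -> infinity.
#'
#' @param input0,amplifier0,inhibitor0 initial concentrations (nM).
#' @return Limiting output concentration (nM).
#' @examples
#' closedFormOutput(2, 100, 50)  # 4
#' @export
closedFormOutput <- function(input0, amplifier0, inhibitor0) {
  stopifnot(input0 >= 0, amplifier0 > 0, inhibitor0 > 0)
  if (input0 > inhibitor0) {
    stop("input0 (", input0, " nM) exceeds inhibitor0 (", inhibitor0,
         " nM): outside the linear regime, the closed form is invalid")
  }
  input0 * amplifier0 / inhibitor0
}

#' Closed-form weighted summation before annihilation
#'
#' The limiting signal of a multi-unit classifier is the weighted sum of the
#' inputs; positive- and negative-weight units feed the shared positive and
#' negative output strands respectively, which are reported here before the
#' annihilation step.
#'
#' @param weights signed numeric weights.
#' @param inputs input concentrations (nM), same length.
#' @return list with `positive` and `negative` channel totals (nM) and the
#'   post-annihilation `net` margin (positive - negative).
#' @examples
#' closedFormSignal(c(1.5, -2), c(4, 2))  # pos 6, neg 4, net +2
#' @export
closedFormSignal <- function(weights, inputs) {
  if (length(weights) != length(inputs)) {
    stop("weights and inputs must have equal length")
  }
  pos <- sum(weights[weights > 0] * inputs[weights > 0])
  neg <- sum(-weights[weights < 0] * inputs[weights < 0])
  list(positive = pos, negative = neg, net = pos - neg)
}

#' Annihilation reactions via cooperative hybridization
#'
#' Symmetric two-step scheme consuming the positive- and negative-channel
#' output strands at a 1:1 stoichiometric ratio: either output binds the
#' annihilator reversibly through a toehold, and the resulting intermediate
#' collapses irreversibly with an output of the opposite channel into two
#' waste molecules. Because single-strand binding is reversible and weak, a
#' surviving majority strand is released rather than sequestered.
#'
#' @param spec an [AnnihilatorSpec-class].
#' @param outPos,outNeg ids of the shared output species.
#' @param posCapacity,negCapacity optional channel capacities (nM); if the
#'   annihilator is not in excess of the larger one, a warning is raised
#'   (minority species may survive).
#' @return list with `species` (data.frame rows to append) and `reactions`.
#' @export
buildAnnihilator <- function(spec, outPos = "OutPos", outNeg = "OutNeg",
                             posCapacity = NULL, negCapacity = NULL) {
  methods::validObject(spec)
  if (!is.null(posCapacity) && !is.null(negCapacity) &&
      spec@annihilator0 < max(posCapacity, negCapacity)) {
    warning("annihilator (", spec@annihilator0,
            " nM) is not in excess of the larger channel capacity (",
            signif(max(posCapacity, negCapacity), 4),
            " nM); minority species may survive annihilation")
  }
  list(
    species = data.frame(
      id = c("Annihilator", "AnnIntPos", "AnnIntNeg"),
      role = c("annihilator", "other", "other"), stringsAsFactors = FALSE
    ),
    reactions = list(
      reaction(c(outPos, "Annihilator"), "AnnIntPos", k = spec@kOn),
      reaction("AnnIntPos", c(outPos, "Annihilator"), k = spec@kOff),
      reaction(c(outNeg, "Annihilator"), "AnnIntNeg", k = spec@kOn),
      reaction("AnnIntNeg", c(outNeg, "Annihilator"), k = spec@kOff),
      reaction(c("AnnIntPos", outNeg), c("Waste", "Waste"), k = spec@k2),
      reaction(c("AnnIntNeg", outPos), c("Waste", "Waste"), k = spec@k2)
    )
  )
}

.inhibitorFor <- function(spec, w) {
  tab <- spec@calibrationTable
  if (nrow(tab)) {
    hit <- which(abs(tab$weight - abs(w)) < 1e-9)
    if (length(hit)) return(tab$inhibitor0[hit[1]])
  }
  spec@amplifier0 / abs(w)
}

#' Maximum classifier input concentration (nM)
#'
#' Upper end of the calibrated input range; 6 nM when no map is stored.
#' @param spec a [LinearClassifierSpec-class].
#' @export
maxInputConc <- function(spec) {
  if (!is.null(spec@inputMap$inputRange)) max(spec@inputMap$inputRange) else 6
}

#' Channel capacities and the indeterminate margin
#'
#' The capacity of a channel is the largest output it can accumulate when
#' every input sits at the top of the calibrated input range (plus the bias
#' unit on its side). `indeterminateMargin` is 5% of the total capacity:
#' normalized |HEX - ROX| margins below it are called "indeterminate",
#' mirroring the both-channels-low behaviour of near-tie inputs.
#'
#' @param spec a [LinearClassifierSpec-class].
#' @param maxInput largest expected input concentration (nM).
#' @return `channelCapacities`: list with `positive`, `negative`, `total`;
#'   `indeterminateMargin`: numeric (nM).
#' @export
channelCapacities <- function(spec, maxInput = maxInputConc(spec)) {
  w <- spec@weights
  pos <- sum(w[w > 0]) * maxInput + max(spec@bias, 0)
  neg <- sum(-w[w < 0]) * maxInput + max(-spec@bias, 0)
  list(positive = pos, negative = neg, total = pos + neg)
}

#' @rdname channelCapacities
#' @export
indeterminateMargin <- function(spec, maxInput = maxInputConc(spec)) {
  0.05 * channelCapacities(spec, maxInput)$total
}

#' Compile a linear classifier into a strand-displacement reaction network
#'
#' Per feature, a competitive-inhibition weight unit is emitted with the
#' ideal mapping inhibitor0 = amplifier0 / |W| (or a bench calibration table
#' if the spec carries one); the unit's output strand is routed to the shared
#' positive or negative output species according to the weight's sign. The
#' bias is realized as a constant auxiliary input of |bias| nM on a weight-1
#' unit on the sign(bias) side. A cooperative-hybridization annihilator and
#' the two channel reporters (HEX for the positive class, ROX for the
#' negative) complete the network.
#'
#' @param spec a [LinearClassifierSpec-class].
#' @param inputs optional named numeric of initial input concentrations (nM)
#'   per feature (defaults to 0; set by the pipeline).
#' @param amplifier0 amplifier concentration per unit (nM).
#' @param k rate constant for amplification and inhibition (nM^-1 s^-1).
#' @param maxInput largest expected input (nM), used for the linear-regime
#'   guard and default annihilator/reporter sizing.
#' @param annihilator an [AnnihilatorSpec-class]; by default sized at twice
#'   the larger channel capacity.
#' @param reporters list of two [ReporterSpec-class] (HEX, ROX); by default
#'   sized at twice the matching channel capacity.
#' @return A [ReactionNetwork-class] ready for [simulateNetwork()].
#' @examples
#' spec <- LinearClassifierSpec(c("miR-1", "miR-4"), c(1.5, -2))
#' net <- compileClassifier(spec, inputs = c("miR-1" = 4, "miR-4" = 2))
#' net
#' @export
compileClassifier <- function(spec, inputs = NULL,
                              amplifier0 = spec@amplifier0,
                              k = spec@rateConstant,
                              maxInput = maxInputConc(spec),
                              annihilator = NULL, reporters = NULL) {
  methods::validObject(spec)
  stopifnot(amplifier0 > 0)
  w <- spec@weights
  feats <- spec@features
  caps <- channelCapacities(spec, maxInput)
  if (is.null(annihilator)) {
    annihilator <- AnnihilatorSpec(
      annihilator0 = 2 * max(caps$positive, caps$negative, 1))
  }
  if (is.null(reporters)) {
    reporters <- list(
      ReporterSpec("HEX", reporter0 = 2 * max(caps$positive, 1)),
      ReporterSpec("ROX", reporter0 = 2 * max(caps$negative, 1))
    )
  }
  chans <- vapply(reporters, function(r) r@channel, character(1))
  if (!setequal(chans, c("HEX", "ROX"))) {
    stop("reporters must cover exactly the HEX and ROX channels")
  }
  hex <- reporters[[match("HEX", chans)]]
  rox <- reporters[[match("ROX", chans)]]

  safe <- gsub("[^A-Za-z0-9]", "_", feats)
  species <- data.frame(
    id = c("OutPos", "OutNeg", "Waste"),
    role = c("output_pos", "output_neg", "waste"), stringsAsFactors = FALSE
  )
  reacts <- list()
  initial <- c(OutPos = 0, OutNeg = 0, Waste = 0)

  addUnit <- function(label, inputConc, weight) {
    inh <- .inhibitorFor(spec, weight)
    if (inh <= maxInput) {
      warning("inhibitor for '", label, "' (", signif(inh, 4),
              " nM) is not above the maximum expected input (", maxInput,
              " nM); the unit may leave its linear regime")
    }
    inId <- paste0("Input_", label)
    ampId <- paste0("Amp_", label)
    inhId <- paste0("Inh_", label)
    outId <- if (weight > 0) "OutPos" else "OutNeg"
    species <<- rbind(species, data.frame(
      id = c(inId, ampId, inhId),
      role = c("input", "amplifier", "inhibitor"), stringsAsFactors = FALSE))
    reacts[[length(reacts) + 1L]] <<-
      reaction(c(inId, ampId), c(inId, outId), k = k)
    reacts[[length(reacts) + 1L]] <<-
      reaction(c(inId, inhId), "Waste", k = k)
    initial[c(inId, ampId, inhId)] <<- c(inputConc, amplifier0, inh)
  }

  for (i in seq_along(feats)) {
    x <- if (!is.null(inputs) && feats[i] %in% names(inputs)) {
      inputs[[feats[i]]]
    } else 0
    if (x > maxInput + 1e-9) {
      warning("input for '", feats[i], "' (", signif(x, 4),
              " nM) exceeds the calibrated maximum (", maxInput, " nM)")
    }
    addUnit(safe[i], x, w[i])
  }
  if (abs(spec@bias) > 1e-12) {
    addUnit("bias", abs(spec@bias), sign(spec@bias) * 1)
  }

  ann <- buildAnnihilator(annihilator,
                          posCapacity = caps$positive,
                          negCapacity = caps$negative)
  species <- rbind(species, ann$species, data.frame(
    id = c("RepHEX", "FluorHEX", "RepROX", "FluorROX"),
    role = c("reporter", "fluorophore", "reporter", "fluorophore"),
    stringsAsFactors = FALSE))
  reacts <- c(reacts, ann$reactions, list(
    reaction(c("OutPos", "RepHEX"), c("FluorHEX", "Waste"),
             k = hex@rateConstant),
    reaction(c("OutNeg", "RepROX"), c("FluorROX", "Waste"),
             k = rox@rateConstant)
  ))
  initial[c("Annihilator", "AnnIntPos", "AnnIntNeg", "RepHEX", "FluorHEX",
            "RepROX", "FluorROX")] <-
    c(annihilator@annihilator0, 0, 0, hex@reporter0, 0, rox@reporter0, 0)

  ReactionNetwork(
    species = species, reactions = reacts, initial = initial,
    conservationLaws = list(
      list(coefficients = c(Annihilator = 1, AnnIntPos = 1, AnnIntNeg = 1),
           total = annihilator@annihilator0),
      list(coefficients = c(RepHEX = 1, FluorHEX = 1),
           total = hex@reporter0),
      list(coefficients = c(RepROX = 1, FluorROX = 1),
           total = rox@reporter0)
    )
  )
}

#' Expected species/reaction counts of a compiled classifier
#'
#' Bookkeeping used for structural audits: a classifier with n weighted
#' features (plus one bias unit when bias != 0) compiles to 3n (+3) feature
#' species, 10 shared species, and 2n (+2) weight-unit reactions plus 8 for
#' annihilation and reporting.
#'
#' @param spec a [LinearClassifierSpec-class].
#' @return list with `nSpecies` and `nReactions`.
#' @export
compiledNetworkSize <- function(spec) {
  n <- length(spec@features) + as.integer(abs(spec@bias) > 1e-12)
  list(nSpecies = 3L * n + 10L, nReactions = 2L * n + 8L)
}

#' Evaluate the classifier in silico
#'
#' @param spec a [LinearClassifierSpec-class].
#' @param featureValues named numeric of input-space feature values (nM);
#'   must cover every feature.
#' @return list with `score` (sum of weights times values plus bias) and
#'   `call` (positive class when score > 0, negative when score < 0,
#'   "indeterminate" at exactly 0).
#' @examples
#' spec <- LinearClassifierSpec(c("miR-1", "miR-4"), c(1.5, -2))
#' evaluateInSilico(spec, c("miR-1" = 2, "miR-4" = 3))  # score -3
#' @export
evaluateInSilico <- function(spec, featureValues) {
  missing <- setdiff(spec@features, names(featureValues))
  if (length(missing)) {
    stop("missing value(s) for feature(s): ", paste(missing, collapse = ", "))
  }
  score <- sum(spec@weights * featureValues[spec@features]) + spec@bias
  call <- if (score > 0) {
    spec@positiveClass
  } else if (score < 0) {
    spec@negativeClass
  } else {
    "indeterminate"
  }
  list(score = unname(score), call = call)
}

#' Competitive-inhibition network realizing one signed weight
#'
#' Convenience wrapper around [eqWeightNetwork()] using the compiler's ideal
#' inhibitor mapping inhibitor0 = amplifier0 / |weight|.
#'
#' @param weight signed weight (only its magnitude matters here).
#' @param input0 input concentration (nM).
#' @param amplifier0 amplifier concentration (nM).
#' @param k rate constant (nM^-1 s^-1).
#' @return A [ReactionNetwork-class].
#' @export
weightUnitNetwork <- function(weight, input0, amplifier0 = 100, k = 1e-4) {
  stopifnot(abs(weight) > 0)
  eqWeightNetwork(input0 = input0, amplifier0 = amplifier0,
                  inhibitor0 = amplifier0 / abs(weight), k = k)
}
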