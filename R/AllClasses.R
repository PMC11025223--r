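#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## crn_core classes
## ---------------------------------------------------------------------------

#' Mass-action chemical reaction network
#'
#' A `ReactionNetwork` holds the species table, the mass-action reactions and
#' the initial condition of a strand-displacement circuit (or any other
#' well-mixed chemistry). Concentrations are in nM, time in seconds, and a
#' reaction of order n has a rate constant in nM^(1-n)/s. Species roles
#' (`input`, `amplifier`, `inhibitor`, `output_pos`, `output_neg`,
#' `annihilator`, `reporter`, `fluorophore`, `waste`, `other`) are purely
#' informational tags; the integrator treats all species identically.
#'
#' @slot species data.frame with columns `id` (unique character) and `role`.
#' @slot reactions list of reactions, each a list with `reactants` (character,
#'   1-3 ids counted with multiplicity), `products` (character, 0-3 ids) and
#'   `k` (positive rate constant).
#' @slot initial named numeric vector of initial concentrations (nM, >= 0),
#'   one entry per species.
#' @slot conservationLaws list of linear invariants, each a list with
#'   `coefficients` (named numeric over species ids) and `total` (expected
#'   conserved value).
#'
#' @seealso [ReactionNetwork()], [simulateNetwork()], [checkConservation()]
#' @export
setClass("ReactionNetwork",
  representation(
    species = "data.frame",
    reactions = "list",
    initial = "numeric",
    conservationLaws = "list"
  )
)

setValidity("ReactionNetwork", function(object) {
  sp <- object@species
  if (!all(c("id", "role") %in% names(sp))) {
    return("species must have columns 'id' and 'role'")
  }
  ids <- sp$id
  if (anyDuplicated(ids)) {
    return(sprintf("duplicated species id: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (i in seq_along(object@reactions)) {
    r <- object@reactions[[i]]
    if (!all(c("reactants", "products", "k") %in% names(r))) {
      return(sprintf("reaction %d lacks reactants/products/k", i))
    }
    ord <- length(r$reactants)
    if (ord < 1L || ord > 3L) {
      return(sprintf("reaction %d has order %d; must be 1-3", i, ord))
    }
    if (length(r$products) > 3L) {
      return(sprintf("reaction %d has more than 3 products", i))
    }
    if (!is.numeric(r$k) || length(r$k) != 1L || !is.finite(r$k) || r$k <= 0) {
      return(sprintf("reaction %d: rate constant must be a positive finite scalar", i))
    }
    unknown <- setdiff(unique(c(r$reactants, r$products)), ids)
    if (length(unknown)) {
      return(sprintf("reaction %d references undeclared species: %s",
                     i, paste(unknown, collapse = ", ")))
    }
  }
  ini <- object@initial
  if (length(ini) != length(ids) || !setequal(names(ini), ids)) {
    return("initial must be a named vector covering exactly the declared species")
  }
  if (any(!is.finite(ini)) || any(ini < 0)) {
    return("initial concentrations must be finite and >= 0")
  }
  for (j in seq_along(object@conservationLaws)) {
    law <- object@conservationLaws[[j]]
    if (!all(c("coefficients", "total") %in% names(law))) {
      return(sprintf("conservation law %d lacks coefficients/total", j))
    }
    unknown <- setdiff(names(law$coefficients), ids)
    if (length(unknown)) {
      return(sprintf("conservation law %d references unknown species: %s",
                     j, paste(unknown, collapse = ", ")))
    }
  }
  TRUE
})

#' Time course of a simulated reaction network
#'
#' Returned by [simulateNetwork()]. Concentrations below zero by less than the
#' clipping tolerance are clipped to zero; the largest clipped magnitude is
#' recorded in `clipMagnitude`.
#'
#' @slot times numeric, strictly increasing time grid starting at 0 (s).
#' @slot concentrations matrix (time x species, nM).
#' @slot steadyState logical; TRUE iff max |d[s]/dt| < steadyTol at the final
#'   time point.
#' @slot endpoint named numeric; concentrations at the final time.
#' @slot clipMagnitude largest negative excursion removed by clipping (nM).
#' @export
setClass("KineticsTrace",
  representation(
    times = "numeric",
    concentrations = "matrix",
    steadyState = "logical",
    endpoint = "numeric",
    clipMagnitude = "numeric"
  )
)

setValidity("KineticsTrace", function(object) {
  tt <- object@times
  if (length(tt) < 2L || tt[1] != 0) return("times must start at 0 and have >= 2 points")
  if (any(diff(tt) <= 0)) return("times must be strictly increasing")
  if (nrow(object@concentrations) != length(tt)) {
    return("concentration matrix rows must match times")
  }
  if (any(object@concentrations < 0)) return("concentrations must be >= 0 after clipping")
  TRUE
})

## ---------------------------------------------------------------------------
## pcr_frontend classes
## ---------------------------------------------------------------------------

#' Asymmetric PCR configuration
#'
#' Parameters of the reverse-transcription + asymmetric-PCR front end. The
#' defaults follow a standard asymmetric qPCR protocol: 25 nM limiting
#' (universal) primer, 1 uM excess (miRNA-specific) primer, 52 thermal cycles
#' with readout at cycle 52, per-cycle efficiency 1, complete reverse
#' transcription, and a 10-fold dilution of the RT product into the PCR
#' (2 uL cDNA in a 20 uL reaction).
#'
#' @slot efficiency per-cycle amplification efficiency E in (0, 1].
#' @slot limitingPrimer limiting (universal) primer, nM.
#' @slot excessPrimer excess (specific) primer, nM; must exceed the limiting
#'   primer.
#' @slot nCycles total number of cycles.
#' @slot readoutCycle cycle at which ssDNA is read out (<= nCycles).
#' @slot rtYield fraction of miRNA converted to first-strand cDNA, (0, 1].
#' @slot templateDilution dilution of the RT product into the PCR mix.
#' @export
setClass("PCRConfig",
  representation(
    efficiency = "numeric",
    limitingPrimer = "numeric",
    excessPrimer = "numeric",
    nCycles = "integer",
    readoutCycle = "integer",
    rtYield = "numeric",
    templateDilution = "numeric"
  )
)

setValidity("PCRConfig", function(object) {
  if (object@efficiency <= 0 || object@efficiency > 1) {
    return("efficiency must lie in (0, 1]")
  }
  if (!(object@excessPrimer > object@limitingPrimer &&
        object@limitingPrimer > 0)) {
    return("primer amounts must satisfy excess > limiting > 0")
  }
  if (object@readoutCycle < 1L || object@readoutCycle > object@nCycles) {
    return("readoutCycle must lie in [1, nCycles]")
  }
  if (object@rtYield <= 0 || object@rtYield > 1) return("rtYield must lie in (0, 1]")
  if (object@templateDilution <= 0 || object@templateDilution > 1) {
    return("templateDilution must lie in (0, 1]")
  }
  TRUE
})

#' Cycle-by-cycle asymmetric PCR trace
#'
#' @slot table data.frame with one row per cycle (plus cycle 0) and columns
#'   `cycle`, `ds` (double-stranded amplicon, nM), `ss` (excess-strand ssDNA,
#'   nM), `limiting` and `excess` (remaining primers, nM).
#' @slot config the [PCRConfig-class] used.
#' @slot initialTemplate effective cDNA template entering the reaction (nM).
#' @export
setClass("PCRTrace",
  representation(
    table = "data.frame",
    config = "PCRConfig",
    initialTemplate = "numeric"
  )
)

setValidity("PCRTrace", function(object) {
  tab <- object@table
  need <- c("cycle", "ds", "ss", "limiting", "excess")
  if (!all(need %in% names(tab))) {
    return(sprintf("trace table needs columns %s", paste(need, collapse = ", ")))
  }
  if (any(unlist(tab[need[-1]]) < -1e-9)) return("trace amounts must be >= 0")
  if (any(diff(tab$limiting) > 1e-9)) return("limiting primer must be non-increasing")
  if (any(diff(tab$ss) < -1e-9)) return("ssDNA must be non-decreasing")
  TRUE
})

## ---------------------------------------------------------------------------
## signal_transformation classes
## ---------------------------------------------------------------------------

#' Associative strand-displacement converter
#'
#' Concentration-level description of the module that converts one miRNA's
#' amplified ssDNA into the universal classifier input strand. The two-splint
#' association and downstream toehold displacement are collapsed into one
#' effective bimolecular step; sequence-level optimizations enter only through
#' the conversion yield and a zeroth-order leak. An optional thresholding
#' stage (a fast stoichiometric sink run after conversion) subtracts a
#' constant from the produced input, which is how the pipeline realizes the
#' affine map from log-concentration onto the classifier's nM input range.
#'
#' @slot target id of the consumed ssDNA species.
#' @slot output id of the produced universal input species.
#' @slot converter0 converter complex concentration (nM, > 0).
#' @slot yield conversion yield gamma in (0, 1].
#' @slot leakRate zeroth-order leak lambda (nM/s, >= 0).
#' @slot rateConstant effective bimolecular rate (nM^-1 s^-1).
#' @slot threshold nM of input removed by the post-conversion threshold sink.
#' @export
setClass("ConverterSpec",
  representation(
    target = "character",
    output = "character",
    converter0 = "numeric",
    yield = "numeric",
    leakRate = "numeric",
    rateConstant = "numeric",
    threshold = "numeric"
  )
)

setValidity("ConverterSpec", function(object) {
  if (object@converter0 <= 0) return("converter0 must be > 0")
  if (object@yield <= 0 || object@yield > 1) return("yield must lie in (0, 1]")
  if (object@leakRate < 0) return("leakRate must be >= 0")
  if (object@rateConstant <= 0) return("rateConstant must be > 0")
  if (object@threshold < 0) return("threshold must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## classifier_compiler classes
## ---------------------------------------------------------------------------

#' Linear classifier specification
#'
#' The object compiled into chemistry: ordered miRNA features, signed weights
#' at one-decimal resolution, a bias, the two class labels, and the affine
#' input map that places measured quantities onto the classifier's nM input
#' scale. `inputMap` is a list with elements `slope` and `intercept` (input nM
#' per log2 pM) plus bookkeeping of the calibrated pipeline (`dilution`,
#' `threshold`, `concRange`, `inputRange`); `exprOffsets` links each feature's
#' log2 expression scale to its plasma concentration
#' (log2 conc_pM = expression - offset).
#'
#' @slot features character, ordered miRNA ids.
#' @slot weights named numeric, signed, exact multiples of 0.1.
#' @slot bias numeric scalar (classifier input space, nM).
#' @slot positiveClass,negativeClass class labels (e.g. "HCC", "healthy").
#' @slot amplifier0 default amplifier concentration for compilation (nM).
#' @slot rateConstant default strand-displacement rate (nM^-1 s^-1).
#' @slot inputMap list; affine map from log2(concentration pM) to input nM.
#' @slot exprOffsets named numeric; per-feature expression-to-concentration
#'   offsets (may be empty).
#' @slot converters list of [ConverterSpec-class], one per feature (may be
#'   empty until the pipeline is calibrated).
#' @slot calibrationTable optional data.frame (`weight`, `inhibitor0`)
#'   overriding the ideal inhibitor mapping; zero rows means the ideal
#'   mapping is used.
#' @slot metadata free-form list (training provenance, seed, format version).
#' @export
setClass("LinearClassifierSpec",
  representation(
    features = "character",
    weights = "numeric",
    bias = "numeric",
    positiveClass = "character",
    negativeClass = "character",
    amplifier0 = "numeric",
    rateConstant = "numeric",
    inputMap = "list",
    exprOffsets = "numeric",
    converters = "list",
    calibrationTable = "data.frame",
    metadata = "list"
  )
)

setValidity("LinearClassifierSpec", function(object) {
  w <- object@weights
  if (length(w) != length(object@features)) {
    return("weights and features must have equal length")
  }
  if (!identical(names(w), object@features)) {
    return("weights must be named by the features, in order")
  }
  if (any(abs(w) < 0.05)) return("retained features must have |weight| > 0")
  if (any(abs(w * 10 - round(w * 10)) > 1e-9)) {
    return("weights must be exact multiples of 0.1 (one-decimal resolution)")
  }
  if (object@amplifier0 <= 0) return("amplifier0 must be > 0")
  if (object@rateConstant <= 0) return("rateConstant must be > 0")
  if (identical(object@positiveClass, object@negativeClass)) {
    return("positive and negative class labels must differ")
  }
  TRUE
})

#' One compiled competitive-inhibition weight unit
#'
#' @slot feature miRNA id the unit weighs.
#' @slot amplifier0 catalytic amplifier concentration (nM).
#' @slot inhibitor0 inhibitor concentration (nM); the realized |weight| is
#'   amplifier0 / inhibitor0.
#' @slot sign +1 (positive channel) or -1 (negative channel).
#' @slot outputSpecies id of the shared output strand the unit feeds.
#' @slot rateConstant reaction rate (nM^-1 s^-1).
#' @export
setClass("WeightUnit",
  representation(
    feature = "character",
    amplifier0 = "numeric",
    inhibitor0 = "numeric",
    sign = "numeric",
    outputSpecies = "character",
    rateConstant = "numeric"
  )
)

setValidity("WeightUnit", function(object) {
  if (!(object@sign %in% c(-1, 1))) return("sign must be +1 or -1")
  if (object@amplifier0 <= 0 || object@inhibitor0 <= 0) {
    return("amplifier0 and inhibitor0 must be > 0")
  }
  TRUE
})

#' Cooperative-hybridization annihilator parameters
#'
#' Two-step scheme: the negative output strand binds the annihilator
#' reversibly through a toehold; the positive output strand then collapses
#' the intermediate irreversibly into waste, consuming the two outputs 1:1.
#'
#' @slot annihilator0 annihilator complex (nM); should exceed the larger
#'   channel capacity.
#' @slot kOn toehold binding rate (nM^-1 s^-1).
#' @slot kOff unbinding rate (s^-1).
#' @slot k2 irreversible collapse rate (nM^-1 s^-1).
#' @export
setClass("AnnihilatorSpec",
  representation(
    annihilator0 = "numeric", kOn = "numeric",
    kOff = "numeric", k2 = "numeric"
  )
)

setValidity("AnnihilatorSpec", function(object) {
  if (object@annihilator0 <= 0) return("annihilator0 must be > 0")
  if (object@kOn <= 0 || object@k2 <= 0 || object@kOff < 0) {
    return("rates must be positive (kOff may be 0)")
  }
  TRUE
})

#' Fluorescent reporter parameters
#'
#' @slot channel "HEX" (positive class) or "ROX" (negative class).
#' @slot reporter0 reporter duplex concentration (nM).
#' @slot rateConstant displacement rate (nM^-1 s^-1).
#' @slot curveSlope,curveIntercept standard curve mapping concentration (nM)
#'   to arbitrary fluorescence units: au = slope * nM + intercept; slope > 0.
#' @export
setClass("ReporterSpec",
  representation(
    channel = "character", reporter0 = "numeric",
    rateConstant = "numeric", curveSlope = "numeric",
    curveIntercept = "numeric"
  )
)

setValidity("ReporterSpec", function(object) {
  if (!(object@channel %in% c("HEX", "ROX"))) return("channel must be HEX or ROX")
  if (object@reporter0 <= 0 || object@rateConstant <= 0) {
    return("reporter0 and rateConstant must be > 0")
  }
  if (object@curveSlope <= 0) return("standard-curve slope must be > 0")
  TRUE
})

## ---------------------------------------------------------------------------
## ml_training classes
## ---------------------------------------------------------------------------

#' Trained SVM panel of a given size
#'
#' @slot features panel feature ids (ranked order).
#' @slot weights named numeric, classifier-input-space weights (one-decimal).
#' @slot rawWeights named numeric, unrounded input-space weights.
#' @slot bias numeric, input-space bias.
#' @slot trainAUC,validAUC area under the ROC curve on the training and
#'   held-out splits (after weight rounding).
#' @slot k panel size.
#' @export
setClass("PanelModel",
  representation(
    features = "character", weights = "numeric", rawWeights = "numeric",
    bias = "numeric", trainAUC = "numeric", validAUC = "numeric",
    k = "integer"
  )
)

setValidity("PanelModel", function(object) {
  if (object@k < 1L || object@k > 10L) return("panel size k must lie in 1..10")
  if (length(object@features) != object@k) return("features must have length k")
  TRUE
})

## ---------------------------------------------------------------------------
## pipeline classes
## ---------------------------------------------------------------------------

#' Result of classifying one sample
#'
#' @slot sampleId sample identifier.
#' @slot raw named numeric: endpoint fluorophore concentrations (nM) for the
#'   HEX and ROX channels.
#' @slot normalizedAU named numeric: instrument-scale signals (a.u.).
#' @slot normalizedNM named numeric: signals converted back to nM through the
#'   reporter standard curves.
#' @slot margin HEX - ROX margin on the normalized nM scale.
#' @slot call one of the two class labels or "indeterminate".
#' @slot inSilicoScore reference linear-classifier score (NA if not computed).
#' @slot warnings character vector of stage warnings (e.g. PCR saturation).
#' @export
setClass("ClassificationResult",
  representation(
    sampleId = "character", raw = "numeric", normalizedAU = "numeric",
    normalizedNM = "numeric", margin = "numeric", call = "character",
    inSilicoScore = "numeric", warnings = "character"
  )
)

#' Confusion-matrix summary of a classified cohort
#'
#' Counts are exact integers; sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP) and accuracy = (TP+TN)/total are kept as exact fractions and
#' only rounded (half-up, one decimal) when printed as percentages.
#'
#' @slot tp,fn,tn,fp integer counts.
#' @slot sensitivity,specificity,accuracy fractions in [0, 1].
#' @export
setClass("ConfusionSummary",
  representation(
    tp = "integer", fn = "integer", tn = "integer", fp = "integer",
    sensitivity = "numeric", specificity = "numeric", accuracy = "numeric"
  )
)

setValidity("ConfusionSummary", function(object) {
  cnt <- c(object@tp, object@fn, object@tn, object@fp)
  if (any(cnt < 0L)) return("counts must be non-negative")
  TRUE
})

## ---------------------------------------------------------------------------
## synthetic_data classes
## ---------------------------------------------------------------------------

#' Synthetic two-class expression study configuration
#'
#' Defaults emulate the structure of a serum miRNA profiling study of
#' hepatocellular carcinoma: 345 positive (HCC) and 958 negative (healthy)
#' samples, a few hundred miRNA features on a log2 microarray-like scale,
#' a small set of informative miRNAs whose between-class differences are at
#' least fourfold (|log2 FC| >= 2), and Gaussian within-class noise in log2
#' space. The noise standard deviation (default 1.4 log2 units) is set so
#' that a five-marker panel separates the classes at an AUC near 0.99 --
#' i.e. informative single markers are good but imperfect, as in serum
#' miRNA data.
#'
#' @slot nPositive,nNegative sample counts per class.
#' @slot nFeatures total number of miRNA features.
#' @slot informative data.frame with columns `feature` (id), `direction`
#'   (+1 up in positive class, -1 down) and `effect` (|log2 FC|, >= 2).
#' @slot noiseSD within-class standard deviation (log2 units).
#' @slot baselineRange range of baseline log2 abundances.
#' @slot concRange plasma-concentration range the panel generator targets
#'   (pM); also the validated range of the PCR front end.
#' @slot seed mandatory integer seed.
#' @export
setClass("GeneratorConfig",
  representation(
    nPositive = "integer", nNegative = "integer", nFeatures = "integer",
    informative = "data.frame", noiseSD = "numeric",
    baselineRange = "numeric", concRange = "numeric", seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  inf <- object@informative
  if (nrow(inf) &&
      !all(c("feature", "direction", "effect") %in% names(inf))) {
    return("informative needs columns feature, direction, effect")
  }
  if (nrow(inf) && any(abs(inf$effect) < 2)) {
    return("informative effects must be >= 2 log2 units (fourfold)")
  }
  if (nrow(inf) && !all(inf$direction %in% c(-1, 1))) {
    return("informative direction must be +1 or -1")
  }
  if (length(object@seed) != 1L || is.na(object@seed)) {
    return("a scalar seed is mandatory")
  }
  if (object@noiseSD <= 0) return("noiseSD must be > 0")
  TRUE
})

#' Reporter standard curve
#'
#' Linear map between reporter-released fluorophore concentration (nM) and
#' instrument fluorescence (a.u.): au = slope * nM + intercept, slope > 0.
#'
#' @slot channel "HEX" or "ROX".
#' @slot slope,intercept curve parameters (a.u. per nM; a.u.).
#' @slot points data.frame of (noisy) calibration points used for the fit,
#'   columns `nM` and `au`.
#' @export
setClass("StandardCurve",
  representation(
    channel = "character", slope = "numeric", intercept = "numeric",
    points = "data.frame"
  )
)

setValidity("StandardCurve", function(object) {
  if (object@slope <= 0) return("slope must be > 0")
  TRUE
})
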