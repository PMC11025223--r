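#' @include AllGenerics.R
NULL

#' Accessors for reaction networks, traces and classifier specifications
#'
#' Small family of generics used across the package: `speciesIds()`,
#' `reactions()`, `initialConc()` and `conservationLaws()` read the slots of a
#' [ReactionNetwork-class]; `endpoint()`, `traceTimes()` and `isSteady()` read a
#' [KineticsTrace-class]; `features()` and `bias()` read a
#' [LinearClassifierSpec-class] (weights are read with the [stats::weights()]
#' generic); `diagnosticCall()` reads a [ClassificationResult-class].
#'
#' @param x object to access.
#' @param ... further arguments for methods.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases speciesIds reactions initialConc conservationLaws endpoint
#'   traceTimes isSteady features bias diagnosticCall
#' @examples
#' net <- eqWeightNetwork(input0 = 2, amplifier0 = 100, inhibitor0 = 50)
#' speciesIds(net)
#' length(reactions(net))
NULL

#' @rdname accessors
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname accessors
#' @export
setGeneric("initialConc", function(x) standardGeneric("initialConc"))

#' @rdname accessors
#' @export
setGeneric("conservationLaws", function(x) standardGeneric("conservationLaws"))

#' @rdname accessors
#' @param species optional species id(s) to extract.
#' @export
setGeneric("endpoint", function(x, species, ...) standardGeneric("endpoint"))

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname accessors
#' @export
setGeneric("isSteady", function(x) standardGeneric("isSteady"))

#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("bias", function(x) standardGeneric("bias"))

#' @rdname accessors
#' @export
setGeneric("diagnosticCall", function(x) standardGeneric("diagnosticCall"))
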