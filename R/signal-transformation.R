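#' @include crn-core.R
NULL

#' Converter constructor
#'
#' @param target consumed ssDNA species id.
#' @param output produced universal input species id.
#' @param converter0 converter complex concentration (nM).
#' @param yield conversion yield gamma in (0, 1] (default 1, the optimized
#'   splint design).
#' @param leakRate zeroth-order leak (nM/s, default 0).
#' @param rateConstant effective bimolecular rate (nM^-1 s^-1).
#' @param threshold nM subtracted by the post-conversion threshold sink
#'   (default 0).
#' @return A validated [ConverterSpec-class].
#' @export
ConverterSpec <- function(target = "ssDNA", output = "Input",
                          converter0 = 100, yield = 1, leakRate = 0,
                          rateConstant = 1e-4, threshold = 0) {
  methods::new("ConverterSpec",
    target = target, output = output, converter0 = converter0,
    yield = yield, leakRate = leakRate, rateConstant = rateConstant,
    threshold = threshold)
}

#' Convert amplified ssDNA into the universal classifier input
#'
#' Simulates the associative strand-displacement conversion as a mass-action
#' network (ssDNA + Converter -> Input + Waste at yield gamma, with the
#' complementary unproductive branch at 1 - gamma), then applies the
#' zeroth-order leak contribution `leakRate * tEnd` and finally the
#' threshold sink (run-to-completion limit of a fast stoichiometric
#' Input + Threshold -> Waste stage): the returned concentration is
#' max(0, gamma * min(ssdna, converter0) + leak - threshold).
#' Below converter saturation and with no leak or threshold the endpoint is
#' linear in the ssDNA input.
#'
#' @param spec a [ConverterSpec-class].
#' @param ssdna initial ssDNA concentration (nM, >= 0).
#' @param tEnd integration horizon (s); auto-extended to steady state.
#' @return Endpoint input concentration (nM). If the converter saturates
#'   (`ssdna > converter0`) a warning is raised and the attribute
#'   `saturated` is set on the result.
#' @export
convertSSDNA <- function(spec, ssdna, tEnd = 2e5) {
  methods::validObject(spec)
  if (!is.numeric(ssdna) || length(ssdna) != 1L || ssdna < 0) {
    stop("ssdna must be a single concentration >= 0")
  }
  saturated <- ssdna > spec@converter0
  if (saturated) {
    warning("ssDNA (", signif(ssdna, 4), " nM) exceeds converter0 (",
            signif(spec@converter0, 4), " nM): converter saturated")
  }
  if (ssdna == 0) {
    inputRaw <- 0
  } else {
    reacts <- list(
      reaction(c(spec@target, "Converter"), c(spec@output, "ConvWaste"),
               k = spec@rateConstant * spec@yield)
    )
    if (spec@yield < 1) {
      reacts <- c(reacts, list(
        reaction(c(spec@target, "Converter"), "ConvWaste",
                 k = spec@rateConstant * (1 - spec@yield))
      ))
    }
    net <- ReactionNetwork(
      species = data.frame(
        id = c(spec@target, "Converter", spec@output, "ConvWaste"),
        role = c("input", "other", "output_pos", "waste"),
        stringsAsFactors = FALSE
      ),
      reactions = reacts,
      initial = stats::setNames(c(ssdna, spec@converter0),
                                c(spec@target, "Converter"))
    )
    tr <- simulateNetwork(net, tEnd = tEnd)
    inputRaw <- endpoint(tr, spec@output, warn = FALSE)
  }
  out <- max(0, inputRaw + spec@leakRate * tEnd - spec@threshold)
  attr(out, "saturated") <- saturated
  out
}

#' Convert a panel of per-feature ssDNA amounts
#'
#' Elementwise [convertSSDNA()] over a named panel.
#'
#' @param specs named list of [ConverterSpec-class], one per feature.
#' @param ssdna named numeric vector of ssDNA concentrations (nM); names must
#'   all have a converter in `specs`.
#' @param tEnd integration horizon per conversion (s).
#' @return named numeric vector of input concentrations (nM).
#' @export
transformPanel <- function(specs, ssdna, tEnd = 2e5) {
  if (!length(ssdna)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(ssdna)) || anyNA(names(ssdna))) {
    stop("ssdna panel must be named by feature")
  }
  missing <- setdiff(names(ssdna), names(specs))
  if (length(missing)) {
    stop("no converter specified for feature(s): ",
         paste(missing, collapse = ", "))
  }
  vapply(names(ssdna), function(f) {
    as.numeric(convertSSDNA(specs[[f]], unname(ssdna[[f]]), tEnd = tEnd))
  }, numeric(1))
}
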