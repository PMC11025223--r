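#' @include AllClasses.R
NULL

#' Asymmetric PCR configuration constructor
#'
#' @param efficiency per-cycle amplification efficiency E in (0, 1].
#' @param limitingPrimer limiting (universal) primer, nM.
#' @param excessPrimer excess (specific) primer, nM.
#' @param nCycles total thermal cycles.
#' @param readoutCycle cycle at which ssDNA is read (defaults to the last).
#' @param rtYield reverse-transcription yield in (0, 1].
#' @param templateDilution dilution of the RT product into the PCR mix
#'   (default 0.1: 2 uL cDNA carried into a 20 uL reaction).
#' @return A validated [PCRConfig-class].
#' @examples
#' cfg <- PCRConfig()
#' tr <- simulatePCR(cfg, initialMiRNA = 1)  # 1 pM
#' ssdnaAtReadout(tr)
#' @export
PCRConfig <- function(efficiency = 1, limitingPrimer = 25,
                      excessPrimer = 1000, nCycles = 52L,
                      readoutCycle = nCycles, rtYield = 1,
                      templateDilution = 0.1) {
  methods::new("PCRConfig",
    efficiency = efficiency, limitingPrimer = limitingPrimer,
    excessPrimer = excessPrimer, nCycles = as.integer(nCycles),
    readoutCycle = as.integer(readoutCycle), rtYield = rtYield,
    templateDilution = templateDilution)
}

#' Simulate reverse transcription plus asymmetric PCR, cycle by cycle
#'
#' Discrete per-cycle recurrence. While the limiting primer lasts, each cycle
#' copies a fraction E of the double-stranded amplicon pool, consuming one
#' limiting and one excess primer per copy (exponential phase). In the cycle
#' where the limiting primer runs out, templates that cannot be served by the
#' limiting primer are still extended by the excess primer and contribute
#' single-stranded product. Thereafter each cycle adds E x (amplicon pool)
#' ssDNA until the excess primer is exhausted (linear phase). Amounts are
#' concentrations, so fractional strands are allowed. At a fixed readout
#' cycle the accumulated ssDNA is approximately linear in log2 of the initial
#' miRNA concentration.
#'
#' @param config a [PCRConfig-class].
#' @param initialMiRNA initial miRNA concentration in pM (> 0).
#' @return A [PCRTrace-class].
#' @export
simulatePCR <- function(config, initialMiRNA) {
  methods::validObject(config)
  if (!is.numeric(initialMiRNA) || initialMiRNA <= 0) {
    stop("initialMiRNA must be > 0 (pM)")
  }
  n0 <- initialMiRNA * 1e-3 * config@rtYield * config@templateDilution  # nM
  if (n0 > config@limitingPrimer) {
    stop("initial template (", signif(n0, 4),
         " nM) exceeds the limiting primer; the two-phase model assumes ",
         "exponential amplification before primer exhaustion")
  }
  E <- config@efficiency
  nC <- config@nCycles
  ds <- numeric(nC + 1L); ss <- numeric(nC + 1L)
  lim <- numeric(nC + 1L); exc <- numeric(nC + 1L)
  ds[1] <- n0; lim[1] <- config@limitingPrimer; exc[1] <- config@excessPrimer
  for (cyc in seq_len(nC)) {
    canCopy <- E * ds[cyc]
    newDS <- min(canCopy, lim[cyc], exc[cyc])
    # templates unserved by the limiting primer still get the excess primer
    ssNew <- max(0, min(canCopy - newDS, exc[cyc] - newDS))
    ds[cyc + 1L] <- ds[cyc] + newDS
    ss[cyc + 1L] <- ss[cyc] + ssNew
    lim[cyc + 1L] <- lim[cyc] - newDS
    exc[cyc + 1L] <- exc[cyc] - newDS - ssNew
  }
  methods::new("PCRTrace",
    table = data.frame(cycle = 0:nC, ds = ds, ss = ss,
                       limiting = lim, excess = exc),
    config = config, initialTemplate = n0)
}

#' Single-stranded DNA at the readout cycle
#'
#' @param trace a [PCRTrace-class].
#' @return ssDNA concentration (nM) at the configured readout cycle.
#' @export
ssdnaAtReadout <- function(trace) {
  stopifnot(is(trace, "PCRTrace"))
  cyc <- trace@config@readoutCycle
  trace@table$ss[trace@table$cycle == cyc]
}

#' Ordinary least squares of a readout on log2 concentration
#'
#' Fits `values ~ log2(concs)` and reports slope, intercept and R^2. Constant
#' readouts are a degenerate fit and return slope 0 with R^2 = 0 by
#' convention.
#'
#' @param concs concentrations (pM, > 0), length >= 3.
#' @param values readout values (e.g. ssDNA nM), same length.
#' @return list with `slope`, `intercept`, `r.squared`.
#' @export
fitLogLinear <- function(concs, values) {
  if (length(concs) < 3L || length(values) != length(concs)) {
    stop("need >= 3 matched (concentration, value) points")
  }
  if (any(concs <= 0)) stop("concentrations must be > 0")
  if (stats::var(values) == 0) {
    return(list(slope = 0, intercept = values[1], r.squared = 0))
  }
  fit <- stats::lm(values ~ log2(concs))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r.squared = summary(fit)$r.squared)
}

#' Export a PCR trace as TSV
#'
#' @param trace a [PCRTrace-class].
#' @param path file path.
#' @export
writePCRTraceTSV <- function(trace, path) {
  utils::write.table(trace@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

setMethod("show", "PCRTrace", function(object) {
  cat(sprintf(
    "PCRTrace: %d cycles, template %.4g nM, ss at readout (cycle %d) = %.4g nM\n",
    object@config@nCycles, object@initialTemplate,
    object@config@readoutCycle, ssdnaAtReadout(object)))
  invisible(NULL)
})
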