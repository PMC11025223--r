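#' @include AllClasses.R
NULL

# round-half-up at one decimal, matching the convention used for reported
# percentages (e.g. 85.714 -> 85.7, 88.235 -> 88.2, 0.25 -> 0.3 at ndec=1)
roundHalfUp <- function(x, ndec = 1L) {
  f <- 10^ndec
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a fraction as a percentage string
#'
#' One decimal, round half up ("85.7%" style).
#' @param frac fraction in \[0, 1\].
#' @return character.
#' @export
formatPercent <- function(frac) {
  sprintf("%.1f%%", roundHalfUp(100 * frac, 1L))
}

.logStage <- function(stage, ..., verbose = getOption("DNAclassify.verbose",
                                                      FALSE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  invisible(NULL)
}
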