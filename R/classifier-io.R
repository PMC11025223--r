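#' @include classifier-compiler.R
NULL

#' Read and write classifier specifications as JSON
#'
#' The schema carries the feature panel, signed one-decimal weights, bias,
#' class labels, compilation defaults (amplifier concentration and rate
#' constant), the calibrated affine input map, per-feature converter
#' parameters, expression offsets, an optional bench calibration table and
#' free-form metadata, under a `format_version` field.
#'
#' @param spec a [LinearClassifierSpec-class].
#' @param path file path.
#' @return `readClassifierJSON` returns a [LinearClassifierSpec-class];
#'   `writeClassifierJSON` returns `path` invisibly.
#' @name classifier-io
NULL

#' @rdname classifier-io
#' @export
writeClassifierJSON <- function(spec, path) {
  methods::validObject(spec)
  obj <- list(
    format_version = "1.0",
    positive_class = spec@positiveClass,
    negative_class = spec@negativeClass,
    features = I(spec@features),
    weights = I(unname(spec@weights)),
    bias = spec@bias,
    amplifier0 = spec@amplifier0,
    rate_constant = spec@rateConstant,
    input_map = spec@inputMap,
    expr_offsets = as.list(spec@exprOffsets),
    converters = lapply(spec@converters, function(cv) {
      list(target = cv@target, output = cv@output,
           converter0 = cv@converter0, yield = cv@yield,
           leak_rate = cv@leakRate, rate_constant = cv@rateConstant,
           threshold = cv@threshold)
    }),
    calibration_table = spec@calibrationTable,
    metadata = spec@metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname classifier-io
#' @export
readClassifierJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- unlist(obj$features)
  conv <- lapply(obj$converters, function(cv) {
    ConverterSpec(target = cv$target, output = cv$output,
                  converter0 = cv$converter0, yield = cv$yield,
                  leakRate = cv$leak_rate, rateConstant = cv$rate_constant,
                  threshold = cv$threshold)
  })
  names(conv) <- names(obj$converters)
  tab <- NULL
  if (length(obj$calibration_table)) {
    tab <- data.frame(
      weight = vapply(obj$calibration_table, function(r) r$weight,
                      numeric(1)),
      inhibitor0 = vapply(obj$calibration_table, function(r) r$inhibitor0,
                          numeric(1))
    )
  }
  im <- lapply(obj$input_map, function(x) {
    if (is.list(x)) unlist(x) else x
  })
  LinearClassifierSpec(
    features = feats,
    weights = unlist(obj$weights),
    bias = obj$bias,
    positiveClass = obj$positive_class,
    negativeClass = obj$negative_class,
    amplifier0 = obj$amplifier0,
    rateConstant = obj$rate_constant,
    inputMap = im,
    exprOffsets = if (length(obj$expr_offsets)) unlist(obj$expr_offsets)
                  else numeric(),
    converters = conv,
    calibrationTable = tab,
    metadata = obj$metadata
  )
}
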