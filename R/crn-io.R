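#' @include crn-core.R
NULL

#' Read and write reaction networks as JSON, kinetics traces as TSV
#'
#' Networks are serialized with a `format_version` field, species (id/role),
#' reactions (reactant and product id lists plus rate constant), initial
#' concentrations and any conservation laws. Traces are written as TSV with a
#' `time` column followed by one column per species.
#'
#' @param network a [ReactionNetwork-class].
#' @param trace a [KineticsTrace-class].
#' @param path file path.
#' @return `readNetworkJSON` returns a [ReactionNetwork-class];
#'   `readTraceTSV` returns a data.frame; the writers return `path`
#'   invisibly.
#' @name crn-io
NULL

#' @rdname crn-io
#' @export
writeNetworkJSON <- function(network, path) {
  methods::validObject(network)
  obj <- list(
    format_version = "1.0",
    species = network@species,
    reactions = lapply(network@reactions, function(r) {
      list(reactants = I(r$reactants), products = I(r$products), k = r$k)
    }),
    initial = as.list(network@initial),
    conservation_laws = lapply(network@conservationLaws, function(l) {
      list(coefficients = as.list(l$coefficients), total = l$total)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname crn-io
#' @export
readNetworkJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  species <- data.frame(
    id = vapply(obj$species, function(s) s$id, character(1)),
    role = vapply(obj$species, function(s) s$role, character(1)),
    stringsAsFactors = FALSE
  )
  reactions <- lapply(obj$reactions, function(r) {
    reaction(unlist(r$reactants),
             if (length(r$products)) unlist(r$products) else character(0),
             k = r$k)
  })
  laws <- lapply(obj$conservation_laws, function(l) {
    list(coefficients = unlist(l$coefficients), total = l$total)
  })
  ReactionNetwork(
    species = species,
    reactions = reactions,
    initial = unlist(obj$initial),
    conservationLaws = laws
  )
}

#' @rdname crn-io
#' @export
writeTraceTSV <- function(trace, path) {
  df <- data.frame(time = trace@times, trace@concentrations,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname crn-io
#' @export
readTraceTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
}
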