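#' @include AllClasses.R
NULL

#' Construct a reaction network
#'
#' @param species either a character vector of species ids (all roles set to
#'   "other") or a data.frame with columns `id` and `role`.
#' @param reactions list of reactions built with [reaction()].
#' @param initial named numeric vector of initial concentrations (nM). Species
#'   missing from `initial` start at 0.
#' @param conservationLaws optional list of laws, each a list with
#'   `coefficients` (named numeric) and `total`.
#' @return A validated [ReactionNetwork-class].
#' @examples
#' net <- ReactionNetwork(
#'   species = c("A", "B"),
#'   reactions = list(reaction("A", "B", k = 0.01)),
#'   initial = c(A = 10)
#' )
#' net
#' @export
ReactionNetwork <- function(species, reactions = list(), initial = numeric(),
                            conservationLaws = list()) {
  if (is.character(species)) {
    species <- data.frame(id = species, role = "other",
                          stringsAsFactors = FALSE)
  }
  full <- stats::setNames(numeric(nrow(species)), species$id)
  if (length(initial)) {
    unknown <- setdiff(names(initial), species$id)
    if (length(unknown)) {
      stop("initial concentrations given for undeclared species: ",
           paste(unknown, collapse = ", "))
    }
    full[names(initial)] <- initial
  }
  methods::new("ReactionNetwork", species = species, reactions = reactions,
               initial = full, conservationLaws = conservationLaws)
}

#' Construct a single mass-action reaction
#'
#' @param reactants character vector of reactant ids (1-3, multiplicity by
#'   repetition).
#' @param products character vector of product ids (0-3); use `character(0)`
#'   for pure degradation.
#' @param k positive rate constant, nM^(1-order) s^-1.
#' @return list suitable for [ReactionNetwork()].
#' @export
reaction <- function(reactants, products = character(0), k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("rate constant must be a positive finite scalar")
  }
  list(reactants = as.character(reactants),
       products = as.character(products), k = as.numeric(k))
}

#' A single competitive-inhibition weight unit as a reaction network
#'
#' The canonical two-reaction motif: the input strand catalyses release of
#' output from the amplifier while being consumed, at the same rate constant,
#' by the inhibitor:
#' \deqn{Input + Amplifier \rightarrow Input + Output}
#' \deqn{Input + Inhibitor \rightarrow Waste}
#' In the linear regime (input0 <= inhibitor0) the limiting output is
#' input0 * amplifier0 / inhibitor0, so the amplifier/inhibitor ratio acts as
#' the unit's weight.
#'
#' @param input0,amplifier0,inhibitor0 initial concentrations (nM).
#' @param k rate constant shared by both reactions (nM^-1 s^-1).
#' @param ids optional named character vector renaming the five species
#'   (names `input`, `amplifier`, `inhibitor`, `output`, `waste`).
#' @return [ReactionNetwork-class] with conservation laws for the
#'   amplifier+output and input/inhibitor bookkeeping attached.
#' @examples
#' net <- eqWeightNetwork(input0 = 2, amplifier0 = 100, inhibitor0 = 50)
#' tr <- simulateNetwork(net)
#' endpoint(tr, "Output")  # ~ 2 * 100 / 50 = 4 nM
#' @export
eqWeightNetwork <- function(input0, amplifier0, inhibitor0, k = 1e-4,
                            ids = NULL) {
  nm <- c(input = "Input", amplifier = "Amplifier", inhibitor = "Inhibitor",
          output = "Output", waste = "Waste")
  if (!is.null(ids)) nm[names(ids)] <- ids
  sp <- data.frame(
    id = unname(nm),
    role = c("input", "amplifier", "inhibitor", "output_pos", "waste"),
    stringsAsFactors = FALSE
  )
  ReactionNetwork(
    species = sp,
    reactions = list(
      reaction(c(nm[["input"]], nm[["amplifier"]]),
               c(nm[["input"]], nm[["output"]]), k = k),
      reaction(c(nm[["input"]], nm[["inhibitor"]]), nm[["waste"]], k = k)
    ),
    initial = stats::setNames(c(input0, amplifier0, inhibitor0),
                              nm[c("input", "amplifier", "inhibitor")]),
    conservationLaws = list(
      list(coefficients = stats::setNames(c(1, 1),
             nm[c("amplifier", "output")]), total = amplifier0),
      list(coefficients = stats::setNames(c(-1, 1),
             nm[c("input", "inhibitor")]), total = inhibitor0 - input0)
    )
  )
}

## internal: stoichiometry and rate machinery -------------------------------

.networkDeriv <- function(net) {
  ids <- net@species$id
  n <- length(ids)
  m <- length(net@reactions)
  stoich <- matrix(0, nrow = n, ncol = max(m, 1L),
                   dimnames = list(ids, NULL))
  rIdx <- vector("list", m)
  ks <- numeric(m)
  for (j in seq_len(m)) {
    r <- net@reactions[[j]]
    ri <- match(r$reactants, ids)
    pi <- match(r$products, ids)
    rIdx[[j]] <- ri
    ks[j] <- r$k
    for (i in ri) stoich[i, j] <- stoich[i, j] - 1
    for (i in pi) stoich[i, j] <- stoich[i, j] + 1
  }
  function(t, y, parms) {
    rates <- ks
    for (j in seq_len(m)) rates[j] <- ks[j] * prod(y[rIdx[[j]]])
    list(as.vector(stoich %*% rates))
  }
}

#' Simulate a reaction network by deterministic mass-action ODEs
#'
#' Integrates d\[s\]/dt = sum_r nu_(s,r) k_r prod(reactant concentrations)
#' with a stiff-capable solver. A steady state is declared when the largest
#' |d\[s\]/dt| at the final time falls below `steadyTol`; if it has not been
#' reached and `autoExtend` is TRUE, the horizon is doubled (up to 8 times the
#' requested `tEnd`) and the network re-integrated, because the weight
#' identity of the competitive-inhibition motif is a t -> infinity limit.
#'
#' @param network a [ReactionNetwork-class].
#' @param tEnd integration horizon (s, > 0).
#' @param rtol,atol relative/absolute solver tolerances.
#' @param steadyTol steady-state threshold on max |d\[s\]/dt| (nM/s).
#' @param autoExtend logical; double `tEnd` (up to 8x) until steady.
#' @param nOut number of output time points per integration.
#' @param method deSolve integration method (default "lsoda").
#' @return A [KineticsTrace-class].
#' @examples
#' net <- ReactionNetwork(c("A", "B"),
#'   list(reaction("A", "B", k = 0.01)), c(A = 10))
#' tr <- simulateNetwork(net, tEnd = 1000)
#' endpoint(tr, "B")
#' @export
simulateNetwork <- function(network, tEnd = 1e5, rtol = 1e-8, atol = 1e-10,
                            steadyTol = 1e-6, autoExtend = TRUE, nOut = 201L,
                            method = "lsoda") {
  stopifnot(is(network, "ReactionNetwork"))
  methods::validObject(network)
  if (!is.numeric(tEnd) || tEnd <= 0) stop("tEnd must be > 0")
  deriv <- .networkDeriv(network)
  y0 <- network@initial
  horizon <- tEnd
  repeat {
    times <- seq(0, horizon, length.out = nOut)
    out <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    conc <- out[, -1, drop = FALSE]
    if (any(!is.finite(conc))) {
      bad <- which(!is.finite(conc), arr.ind = TRUE)
      stop("integration failure: non-finite concentration for species '",
           colnames(conc)[bad[1, 2]], "' (rate blow-up?)")
    }
    yEnd <- conc[nrow(conc), ]
    dEnd <- deriv(horizon, yEnd, NULL)[[1]]
    steady <- max(abs(dEnd)) < steadyTol
    if (steady || !autoExtend || horizon >= 8 * tEnd - 1e-12) break
    horizon <- horizon * 2
  }
  clip <- max(0, -min(conc))
  if (clip > 1e-6) {
    warning(sprintf("negative excursion of %.3g nM clipped; tighten tolerances",
                    clip))
  }
  conc[conc < 0] <- 0
  methods::new("KineticsTrace",
    times = as.numeric(out[, 1]), concentrations = conc,
    steadyState = steady,
    endpoint = stats::setNames(as.numeric(conc[nrow(conc), ]),
                               colnames(conc)),
    clipMagnitude = clip)
}

#' Check declared conservation laws against a simulated trace
#'
#' For each declared linear combination sum_i c_i \[s_i\](t) = total, reports
#' the maximum absolute violation over the whole trace.
#'
#' @param network [ReactionNetwork-class] with non-empty `conservationLaws`.
#' @param trace [KineticsTrace-class] from [simulateNetwork()].
#' @return data.frame with columns `law` (index), `total` (expected value)
#'   and `maxViolation`.
#' @export
checkConservation <- function(network, trace) {
  laws <- network@conservationLaws
  if (!length(laws)) stop("network declares no conservation laws")
  conc <- trace@concentrations
  res <- lapply(seq_along(laws), function(j) {
    law <- laws[[j]]
    unknown <- setdiff(names(law$coefficients), colnames(conc))
    if (length(unknown)) {
      stop("conservation law ", j, " references unknown species: ",
           paste(unknown, collapse = ", "))
    }
    lhs <- as.vector(conc[, names(law$coefficients), drop = FALSE] %*%
                       law$coefficients)
    data.frame(law = j, total = law$total,
               maxViolation = max(abs(lhs - law$total)))
  })
  do.call(rbind, res)
}

## accessors -----------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("speciesIds", "ReactionNetwork", function(x) x@species$id)

#' @rdname accessors
#' @export
setMethod("reactions", "ReactionNetwork", function(x) x@reactions)

#' @rdname accessors
#' @export
setMethod("initialConc", "ReactionNetwork", function(x) x@initial)

#' @rdname accessors
#' @export
setMethod("conservationLaws", "ReactionNetwork",
          function(x) x@conservationLaws)

#' @rdname accessors
#' @param warn logical; warn when the trace did not reach steady state.
#' @export
setMethod("endpoint", "KineticsTrace", function(x, species, warn = TRUE) {
  ep <- x@endpoint
  if (warn && !x@steadyState) {
    warning("trace did not reach steady state; endpoint is the final value")
  }
  if (missing(species)) return(ep)
  unknown <- setdiff(species, names(ep))
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  if (length(species) == 1L) unname(ep[species]) else ep[species]
})

#' @rdname accessors
#' @export
setMethod("traceTimes", "KineticsTrace", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("isSteady", "KineticsTrace", function(x) x@steadyState)

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d species, %d reactions\n",
              nrow(object@species), length(object@reactions)))
  nz <- object@initial[object@initial > 0]
  if (length(nz)) {
    cat("  initial (nM):",
        paste(sprintf("%s=%g", names(nz), nz), collapse = ", "), "\n")
  }
  if (length(object@conservationLaws)) {
    cat(sprintf("  %d conservation law(s) declared\n",
                length(object@conservationLaws)))
  }
  invisible(NULL)
})

setMethod("show", "KineticsTrace", function(object) {
  cat(sprintf(
    "KineticsTrace: %d time points over %g s, %d species, steady=%s\n",
    length(object@times), max(object@times),
    ncol(object@concentrations), object@steadyState))
  ep <- sort(object@endpoint, decreasing = TRUE)
  ep <- ep[ep > 1e-6]
  if (length(ep)) {
    cat("  endpoint (nM):",
        paste(sprintf("%s=%.4g", names(ep), ep), collapse = ", "), "\n")
  }
  invisible(NULL)
})
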