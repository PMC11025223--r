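# Independent reference integrations used as oracles. These build their
# derivative functions by hand (or by walking the reaction list with a
# different code path than the package's integrator machinery) and use the
# radau solver at tightened tolerances.

# competitive-inhibition motif, hand-coded ODEs:
#   d[In]/dt  = -k [In][Inh]
#   d[Amp]/dt = -k [In][Amp]
#   d[Out]/dt =  k [In][Amp]
#   d[Inh]/dt = -k [In][Inh]
oracleWeightUnitOutput <- function(input0, amplifier0, inhibitor0,
                                   k = 1e-4, tEnd = 2e6) {
  deriv <- function(t, y, p) {
    list(c(
      In = -k * y[["In"]] * y[["Inh"]],
      Amp = -k * y[["In"]] * y[["Amp"]],
      Inh = -k * y[["In"]] * y[["Inh"]],
      Out = k * y[["In"]] * y[["Amp"]]
    ))
  }
  y0 <- c(In = input0, Amp = amplifier0, Inh = inhibitor0, Out = 0)
  out <- deSolve::ode(y0, times = c(0, tEnd), func = deriv, parms = NULL,
                      method = "radau", rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), "Out"])
}

# generic oracle: independent mass-action derivative assembled by explicit
# looping over named concentration vectors (no stoichiometry matrix)
oracleNetworkEndpoint <- function(net, tEnd) {
  rxns <- reactions(net)
  deriv <- function(t, y, p) {
    dy <- y * 0
    for (r in rxns) {
      flux <- r$k
      for (s in r$reactants) flux <- flux * y[[s]]
      for (s in r$reactants) dy[[s]] <- dy[[s]] - flux
      for (s in r$products) dy[[s]] <- dy[[s]] + flux
    }
    list(dy)
  }
  out <- deSolve::ode(initialConc(net), times = c(0, tEnd), func = deriv,
                      parms = NULL, method = "radau", rtol = 1e-10,
                      atol = 1e-12)
  ep <- out[nrow(out), -1]
  setNames(as.numeric(ep), names(ep))
}
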