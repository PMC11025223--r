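# Shared fixtures, built in code.

# the printed two-input example classifier: score = 1.5*I1 - 2*I4
twoFeatureSpec <- function() {
  LinearClassifierSpec(
    features = c("Input1", "Input4"), weights = c(1.5, -2),
    positiveClass = "HCC", negativeClass = "healthy"
  )
}

# small synthetic study used by the end-to-end tests
smallStudyConfig <- function(seed = 11L) {
  GeneratorConfig(nPositive = 60L, nNegative = 90L, nFeatures = 60L,
                  seed = seed)
}

# calibrated five-feature classifier over the default study; cached because
# calibration re-runs the PCR model
.fixtureEnv <- new.env()
fiveFeatureSpec <- function(seed = 7L) {
  key <- paste0("spec", seed)
  if (is.null(.fixtureEnv[[key]])) {
    .fixtureEnv[[key]] <- demoClassifier(GeneratorConfig(seed = seed))
  }
  .fixtureEnv[[key]]
}

# annihilator test network: preformed output pools plus the annihilation
# reactions, no upstream units or reporters
annihilationNetwork <- function(pos0, neg0, ann0, kOn = 2e-3, kOff = 0.05,
                                k2 = 1e-2) {
  ann <- buildAnnihilator(AnnihilatorSpec(ann0, kOn, kOff, k2))
  sp <- rbind(
    data.frame(id = c("OutPos", "OutNeg", "Waste"),
               role = c("output_pos", "output_neg", "waste"),
               stringsAsFactors = FALSE),
    ann$species
  )
  ReactionNetwork(
    species = sp, reactions = ann$reactions,
    initial = c(OutPos = pos0, OutNeg = neg0, Annihilator = ann0)
  )
}
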