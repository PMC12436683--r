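# shared fixtures: built once per test run

builtinSet <- loadBuiltinPropertySet()

# a small deterministic labeled window set (no planted signal)
makeNullSet <- function(n, seed = 1) {
  generateNull(syntheticConfig(n = n, seed = seed))
}

# identity-ish ScaleStats for closed-form checks
manualStats <- function(mean = 0, sd = 1) {
  new("ScaleStats",
      mean = setNames(rep(mean, 8), propertyIds()),
      sd = setNames(rep(sd, 8), propertyIds()),
      n = 1L)
}

polyAWindow <- function() {
  PeptideSet(sequence = paste0(strrep("A", 15), "K", strrep("A", 15)),
             label = 1, id = "polyA")
}

# small fast model configuration for smoke tests
tinyConfig <- function(inputWidth = 2L, seed = 1L, ...) {
  modelConfig(inputWidth = inputWidth, lstm1 = 4L, lstm2 = 4L, dense = 4L,
              dropout1 = 0.1, dropout2 = 0.1, dropout3 = 0.1, l2 = 1e-4,
              learningRate = 2e-3, batchSize = 32L, maxEpochs = 2L,
              patience = 1L, seed = seed, ...)
}

# reduced training protocol used for the planted-recovery experiments:
# smallest stack that can represent the planted linear statistic
reducedConfig <- function(inputWidth = 2L, seed = 1L) {
  modelConfig(inputWidth = inputWidth, lstm1 = 16L, lstm2 = 8L, dense = 8L,
              dropout1 = 0.1, dropout2 = 0.1, dropout3 = 0.1, l2 = 1e-4,
              learningRate = 2e-3, batchSize = 64L, maxEpochs = 15L,
              patience = 5L, seed = seed)
}

encodeSplit <- function(split, spec, propertySet = builtinSet) {
  stats <- fitScaleStats(split$train, propertySet)
  list(train = encodeDataset(split$train, spec, propertySet, stats),
       validation = encodeDataset(split$validation, spec, propertySet, stats),
       test = encodeDataset(split$test, spec, propertySet, stats),
       stats = stats)
}
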