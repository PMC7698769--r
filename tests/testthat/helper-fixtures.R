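## Shared fixtures, built once per test run. Desk-scale sizes: 16 x 16
## fields with 16 px tiles keep the full suite fast while preserving the
## statistical structure (clustered stress, ~90% separable tiles).

.fixtureCache <- new.env(parent = emptyenv())

scoutFixtures <- function() {
  if (!is.null(.fixtureCache$models)) return(.fixtureCache$models)
  spec <- syntheticFieldSpec(rows = 16L, cols = 16L, tilePx = 16L,
                             seed = 11L)
  data <- makeScoutingDataset(spec, nTrainFields = 3L, nTestFields = 1L,
                              nReferenceTiles = 150L)
  data$train <- lapply(data$train, computeTileFeatures)
  data$test <- lapply(data$test, computeTileFeatures)
  ens <- trainDirectional(data$train)
  ref <- buildReference(data$referenceTiles, ens)
  rl <- buildRLDataset(data$train[1:2], coverage = 0.4, windowSize = 7L,
                       nPaths = 4L, ensemble = ens, ref = ref, seed = 5L)
  .fixtureCache$models <- list(spec = spec, data = data, ens = ens,
                               ref = ref, rl = rl)
  .fixtureCache$models
}

scoutLocalDataset <- function() {
  if (!is.null(.fixtureCache$rlLocal)) return(.fixtureCache$rlLocal)
  fx <- scoutFixtures()
  .fixtureCache$rlLocal <- buildRLDataset(
    fx$data$train[1:2], coverage = 0.4, windowSize = 7L, nPaths = 2L,
    ensemble = fx$ens, ref = fx$ref, encoding = "local", seed = 6L)
  .fixtureCache$rlLocal
}

## a filled 3 x 3 window on a 3 x 3 all-healthy field, center visited;
## used to exercise the action rules with controlled models
makeToyWindow <- function(p = 0.5) {
  field <- FieldGrid(matrix(1L, 3, 3))
  part <- partitionField(rbind(c(2L, 2L)), c(3L, 3L))
  win <- extractWindow(field, part, c(2L, 2L), 3L)
  fillWindow(win, constantEnsemble(p), ReferenceSet(p))
}

## RLDataset built directly from components (tests construct tiny
## hand-crafted datasets)
makeToyDataset <- function(states, actions, gains, nextLabels, w = 3L,
                           k = nrow(states), encoding = "window") {
  new("RLDataset", states = states, actions = as.integer(actions),
      gains = gains, nextLabels = nextLabels, windowSize = as.integer(w),
      coverage = 0.4, k = as.integer(k), encoding = encoding,
      stateNormSq = rowSums(states^2))
}
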