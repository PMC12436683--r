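# small encoded fixtures shared by the model tests
sepSplit <- makeSplit(
  generateSeparable(syntheticConfig(n = 1200, plantedProperties = "IEP",
                                    seed = 21), builtinSet),
  sizes = c(800, 200, 200), seed = 21)
sepEnc <- encodeSplit(sepSplit, caseSpec(1, "IEP"))

test_that("model building is seeded and parameter count depends only on width", {
  cfg <- tinyConfig(seed = 9L)
  m1 <- buildModel(cfg)
  m2 <- buildModel(cfg)
  expect_identical(m1$weights, m2$weights)
  m3 <- buildModel(tinyConfig(seed = 10L))
  expect_false(identical(m1$weights$W1, m3$weights$W1))

  # cases 1 and 2 share width 2, hence identical parameter counts
  full <- modelConfig(inputWidth = 2L)
  expect_identical(countParams(full), countParams(modelConfig(inputWidth = 2L, seed = 99L)))
  # audit the closed form against the actual initialized matrices
  w <- buildModel(cfg)$weights
  expect_identical(countParams(cfg),
                   as.integer(sum(vapply(w[1:10], length, 1L))))
})

test_that("configuration invariants are enforced", {
  expect_error(modelConfig(dropout1 = 1.0), "dropout")
  expect_error(modelConfig(patience = 0L), "patience")
  expect_error(modelConfig(inputWidth = 3L), "inputWidth")
  expect_s4_class(modelConfig(inputWidth = 3L, allowAnyWidth = TRUE), "ModelConfig")
})

test_that("training learns a separable planted signal and early-stops", {
  cfg <- reducedConfig(seed = 5L)
  model <- trainModel(sepEnc$train, sepEnc$validation, cfg, sepEnc$stats)
  expect_lte(nrow(model@history), cfg@maxEpochs)
  expect_gte(max(model@history$val_accuracy), 0.9)
  expect_identical(model@bestEpoch,
                   which.max(model@history$val_accuracy))
  # independent capacity oracle: the planted statistic alone separates the
  # classes, so a linear fit on it must do at least as well
  z <- colMeans(sepEnc$test@data[c(1:15, 17:31), 1, ])
  oracleAcc <- mean(as.integer(z > median(z)) == sepEnc$test@label)
  expect_gte(oracleAcc, 0.9)
})

test_that("training is deterministic and width-checked", {
  cfg <- tinyConfig(seed = 3L)
  m1 <- trainModel(sepEnc$train, sepEnc$validation, cfg, sepEnc$stats)
  m2 <- trainModel(sepEnc$train, sepEnc$validation, cfg, sepEnc$stats)
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@history, m2@history)
  wide <- encodeDataset(sepSplit$train, caseSpec(3), builtinSet, sepEnc$stats)
  expect_error(trainModel(wide, sepEnc$validation, cfg), "width")
  expect_error(trainModel(sepEnc$train, sepEnc$validation,
                          tinyConfig(inputWidth = 8L)), "width")
})

test_that("optimization decreases loss on clean separable data", {
  cfg <- modelConfig(inputWidth = 2L, lstm1 = 8L, lstm2 = 4L, dense = 4L,
                     dropout1 = 0, dropout2 = 0, dropout3 = 0, l2 = 0,
                     learningRate = 2e-3, batchSize = 32L, maxEpochs = 8L,
                     patience = 8L, seed = 2L)
  model <- trainModel(sepEnc$train, sepEnc$validation, cfg, sepEnc$stats)
  losses <- model@history$loss
  expect_lt(losses[length(losses)], losses[1])
  expect_lt(losses[3], losses[1])
})

test_that("a label-independent dataset trains to chance-level validation accuracy", {
  nullSplit <- makeSplit(makeNullSet(600, seed = 31), sizes = c(400, 100, 100),
                         seed = 31)
  enc <- encodeSplit(nullSplit, caseSpec(1, "IEP"))
  model <- trainModel(enc$train, enc$validation, tinyConfig(seed = 8L), enc$stats)
  finalAcc <- model@history$val_accuracy[nrow(model@history)]
  expect_gte(finalAcc, 0.40)
  expect_lte(finalAcc, 0.60)
})

test_that("inference is normalized, deterministic and order-preserving", {
  model <- trainModel(sepEnc$train, sepEnc$validation, tinyConfig(seed = 4L),
                      sepEnc$stats)
  p <- predictProba(model, sepEnc$test)
  expect_identical(nrow(p), length(sepEnc$test@id))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predictProba(model, sepEnc$test))
  expect_identical(rownames(p), sepEnc$test@id)
  # scoring a subset preserves per-example probabilities (batch independence)
  sub <- new("EncodedSet", data = sepEnc$test@data[, , 1:5, drop = FALSE],
             label = sepEnc$test@label[1:5], id = sepEnc$test@id[1:5],
             caseSpec = sepEnc$test@caseSpec)
  expect_equal(predictProba(model, sub), p[1:5, ], tolerance = 1e-6)
})

test_that("classification uses argmax with ties called nonglycated", {
  expect_identical(classify(rbind(c(0.8, 0.2))), 1L)
  expect_identical(classify(rbind(c(0.5, 0.5))), 0L)
  expect_identical(classify(rbind(c(0.2, 0.8))), 0L)
  expect_error(classify(rbind(c(0.9, 0.3))), "sum to 1")
})

test_that("models round-trip through the JSON checkpoint with identical scores", {
  model <- trainModel(sepEnc$train, sepEnc$validation, tinyConfig(seed = 6L),
                      sepEnc$stats)
  path <- tempfile(fileext = ".json")
  saveModel(model, path)
  reloaded <- loadModel(path)
  expect_equal(predictProba(reloaded, sepEnc$test),
               predictProba(model, sepEnc$test), tolerance = 1e-12)
  expect_identical(reloaded@caseSpec@properties, model@caseSpec@properties)
  expect_equal(reloaded@stats@mean, model@stats@mean)
  bogus <- tempfile(fileext = ".json")
  writeLines('{"weights": []}', bogus)
  expect_error(loadModel(bogus), "not a glycLSTM")
})
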