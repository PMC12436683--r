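# a fixed small split shared across the orchestration smoke tests
smokeSplit <- makeSplit(makeNullSet(240, seed = 51), sizes = c(160, 40, 40),
                        seed = 51)
smokePlan <- experimentPlan(repeats = 1L, baseSeed = 51L,
                            modelConfig = tinyConfig())

test_that("case runners produce the expected subcase tables", {
  res1 <- runCase1(smokeSplit, builtinSet, smokePlan)
  expect_identical(nrow(res1@summary), 8L)
  expect_identical(res1@summary$subcase, propertyIds())
  expect_setequal(res1@ranking, propertyIds())

  res2 <- runCase2(smokeSplit, builtinSet, smokePlan,
                   properties = c("SoA", "Mass", "IEP"))
  expect_identical(nrow(res2@summary), 3L)
  expect_identical(res2@summary$subcase, c("SoA+Mass", "SoA+IEP", "Mass+IEP"))
  # unordered pairs: no reversed duplicates
  expect_false(any(c("Mass+SoA", "IEP+SoA", "IEP+Mass") %in% res2@summary$subcase))

  res3 <- runCase3(smokeSplit, builtinSet, smokePlan)
  expect_identical(nrow(res3@summary), 1L)
  expect_identical(res3@summary$subcase, "All8")
  expect_identical(res3@provenance$propertyOrder, propertyIds())
})

test_that("subcase ranking sorts by the chosen metric with canonical tie-break", {
  fake <- new("ExperimentResult",
              summary = data.frame(subcase = c("IEP", "Mass", "ToA"),
                                   accuracy_mean = c(0.596, 0.58, 0.576),
                                   mcc_mean = c(0.1, 0.3, 0.2)),
              repeats = data.frame(), ranking = character(0), roc = list(),
              provenance = list())
  expect_identical(rankProperties(fake, "accuracy"), c("IEP", "Mass", "ToA"))
  expect_identical(rankProperties(fake, "mcc"), c("Mass", "ToA", "IEP"))
  ties <- new("ExperimentResult",
              summary = data.frame(subcase = c("SoA", "Hyd", "Mass"),
                                   accuracy_mean = c(0.5, 0.5, 0.5)),
              repeats = data.frame(), ranking = character(0), roc = list(),
              provenance = list())
  expect_identical(rankProperties(ties, "accuracy"), c("SoA", "Hyd", "Mass"))
  expect_error(rankProperties(fake, "f1"), "unknown metric")
})

test_that("cross-validation covers every record exactly once per fold plan", {
  pep <- makeNullSet(200, seed = 53)
  plan <- experimentPlan(repeats = 1L, baseSeed = 53L,
                         modelConfig = tinyConfig())
  cv <- crossValidate(pep, k = 2L, plan, caseSpec(1, "IEP"), builtinSet)
  expect_identical(nrow(cv$perFold), 2L)
  expect_identical(sum(cv$perFold$n_held), 200L)
  expect_setequal(unlist(cv$folds$folds), peptideIds(pep))
  expect_s4_class(cv$bestConfig, "ModelConfig")
  # the grid hook prefers the higher-sensitivity configuration
  fakeSumm <- data.frame(config = 1:2, sensitivity = c(0.4, 0.6),
                         accuracy = c(0.9, 0.5))
  best <- fakeSumm$config[order(-fakeSumm$sensitivity, -fakeSumm$accuracy)][1]
  expect_identical(best, 2L)
})

test_that("test-set corruption cannot leak into training or normalization", {
  corrupted <- smokeSplit
  corrupted$test <- PeptideSet(sequence = peptideSequences(smokeSplit$test),
                               label = 1L - peptideLabels(smokeSplit$test),
                               id = peptideIds(smokeSplit$test))
  a <- runCase1(smokeSplit, builtinSet, smokePlan, properties = "IEP")
  b <- runCase1(corrupted, builtinSet, smokePlan, properties = "IEP")
  # identical trained weights and scale statistics; only test metrics move
  expect_identical(a@repeats$weight_sum, b@repeats$weight_sum)
  expect_identical(a@provenance$scaleMean, b@provenance$scaleMean)
  expect_identical(a@provenance$scaleSd, b@provenance$scaleSd)
  expect_equal(a@summary$accuracy_mean + b@summary$accuracy_mean, 1)
})

test_that("identical plan, seed and data reproduce byte-identical exports", {
  runOnce <- function(dir) {
    res <- runCase1(smokeSplit, builtinSet, smokePlan,
                    properties = c("Mass", "IEP"))
    exportResults(res, dir)
    dir
  }
  d1 <- runOnce(file.path(tempdir(), "exp-a"))
  d2 <- runOnce(file.path(tempdir(), "exp-b"))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = f)
  }
  expect_true(file.exists(file.path(d1, "metrics.tsv")))
  expect_identical(length(list.files(d1, pattern = "^roc_")), 2L)
  prov <- jsonlite::read_json(file.path(d1, "provenance.json"),
                              simplifyVector = TRUE)
  expect_identical(prov$baseSeed, 51L)
  expect_identical(prov$subcases, c("Mass", "IEP"))
})
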