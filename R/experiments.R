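#' Create an experiment plan
#'
#' Bundles the evaluation protocol: number of training repeats per subcase
#' (20 in the full protocol), the model configuration template, the base
#' seed, and the metric used for ranking subcases. Repeat `r` of subcase
#' `s` trains with seed `baseSeed + 1000*s + r`, so every subcase/repeat
#' is independently reproducible; all repeats reuse the one fixed split
#' they are given.
#'
#' @param repeats Training repeats per subcase (>= 1).
#' @param baseSeed Integer base seed.
#' @param modelConfig A [ModelConfig-class] template (its `inputWidth` and
#'   `seed` are overridden per subcase/repeat).
#' @param rankMetric Metric name used by [rankProperties()] by default.
#' @return An `ExperimentPlan` list.
#' @export
experimentPlan <- function(repeats = 20L, baseSeed = 1L,
                           modelConfig = glycLSTM::modelConfig(),
                           rankMetric = "accuracy") {
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop("repeats must be >= 1")
  structure(list(repeats = repeats, baseSeed = as.integer(baseSeed),
                 modelConfig = modelConfig, rankMetric = rankMetric),
            class = "ExperimentPlan")
}

METRIC_NAMES <- c("accuracy", "precision", "sensitivity", "specificity",
                  "mcc", "auc")

# cheap order-sensitive fingerprint of a dataset (provenance only)
datasetFingerprint <- function(peptides) {
  s <- paste(peptideIds(peptides), peptideSequences(peptides),
             peptideLabels(peptides), sep = ":")
  sprintf("n%d-%x", length(peptides),
          sum(vapply(s, function(x) sum(utf8ToInt(x)), 0)) %% 2^28)
}

# run one plan over a list of CaseSpecs on a fixed split
runExperiment <- function(split, propertySet, plan, specs) {
  stopifnot(inherits(plan, "ExperimentPlan"))
  stats <- fitScaleStats(split$train, propertySet)
  rows <- list(); roc <- list()
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    name <- subcaseName(spec)
    encTrain <- encodeDataset(split$train, spec, propertySet, stats)
    encVal <- encodeDataset(split$validation, spec, propertySet, stats)
    encTest <- encodeDataset(split$test, spec, propertySet, stats)
    for (r in seq_len(plan$repeats)) {
      seed <- plan$baseSeed + 1000L * s + r
      cfg <- reconfig(plan$modelConfig, inputWidth = caseWidth(spec),
                      seed = as.integer(seed))
      model <- trainModel(encTrain, encVal, cfg, stats)
      probs <- predictProba(model, encTest)
      met <- scorePredictions(peptideLabels(split$test), probs)
      rows[[length(rows) + 1L]] <- data.frame(
        subcase = name, repeat_ = r, seed = seed,
        epochs = nrow(model@history), best_epoch = model@bestEpoch,
        t(as.numeric(met)),
        weight_sum = sum(vapply(model@weights[1:10],
                                function(w) sum(abs(w)), 0)))
      if (r == 1L) roc[[name]] <- rocCurve(peptideLabels(split$test),
                                           probs[, 1])
    }
  }
  repeats <- do.call(rbind, rows)
  colnames(repeats)[6:11] <- METRIC_NAMES
  subcases <- vapply(specs, subcaseName, "")
  summ <- do.call(rbind, lapply(subcases, function(nm) {
    sub <- repeats[repeats$subcase == nm, METRIC_NAMES, drop = FALSE]
    means <- colMeans(sub)
    sds <- if (nrow(sub) > 1) apply(sub, 2, sd)
           else setNames(rep(0, ncol(sub)), colnames(sub))
    out <- data.frame(subcase = nm)
    for (mname in METRIC_NAMES) {
      out[[paste0(mname, "_mean")]] <- means[[mname]]
      out[[paste0(mname, "_sd")]] <- sds[[mname]]
    }
    out
  }))
  result <- new("ExperimentResult", summary = summ, repeats = repeats,
                ranking = character(0), roc = roc,
                provenance = list(
                  baseSeed = plan$baseSeed, repeats = plan$repeats,
                  propertyOrder = propertyIds(),
                  subcases = subcases,
                  trainFingerprint = datasetFingerprint(split$train),
                  testFingerprint = datasetFingerprint(split$test),
                  scaleMean = as.list(stats@mean),
                  scaleSd = as.list(stats@sd)))
  result@ranking <- rankProperties(result, plan$rankMetric)
  result
}

#' Run case 1: each scale alone
#'
#' Trains `plan$repeats` models per scale on 31 x 2 inputs (the scale
#' column duplicated) and aggregates test-set metrics per subcase.
#'
#' @param split List with `train`, `validation`, `test` [PeptideSet-class]
#'   objects (see [makeSplit()]).
#' @param propertySet A [PropertySet-class].
#' @param plan An [experimentPlan()].
#' @param properties Scale ids to include (default: all eight).
#' @return An [ExperimentResult-class] with one subcase per scale.
#' @export
runCase1 <- function(split, propertySet, plan,
                     properties = propertyIds()) {
  specs <- lapply(properties, function(p) caseSpec(1L, p))
  runExperiment(split, propertySet, plan, specs)
}

#' Run case 2: all unordered scale pairs
#'
#' One subcase per unordered pair (28 for the full scale set), each a
#' 31 x 2 input with one scale per column.
#'
#' @inheritParams runCase1
#' @return An [ExperimentResult-class] with `choose(p, 2)` subcases.
#' @export
runCase2 <- function(split, propertySet, plan,
                     properties = propertyIds()) {
  specs <- lapply(enumeratePairs(properties),
                  function(pr) caseSpec(2L, pr))
  runExperiment(split, propertySet, plan, specs)
}

#' Run case 3: all eight scales together
#'
#' A single subcase on 31 x 8 inputs, columns in canonical scale order.
#'
#' @inheritParams runCase1
#' @return An [ExperimentResult-class] with one subcase.
#' @export
runCase3 <- function(split, propertySet, plan) {
  runExperiment(split, propertySet, plan, list(caseSpec(3L)))
}

#' Rank subcases by a repeat-averaged metric
#'
#' Descending by the mean of the chosen metric; ties keep the canonical
#' subcase order.
#'
#' @param result An [ExperimentResult-class].
#' @param metric One of `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `mcc`, `auc`.
#' @return Character vector of subcase names, best first.
#' @export
rankProperties <- function(result, metric = "accuracy") {
  stopifnot(is(result, "ExperimentResult"))
  if (!metric %in% METRIC_NAMES)
    stop("unknown metric '", metric, "'; choose from: ",
         paste(METRIC_NAMES, collapse = ", "))
  means <- result@summary[[paste0(metric, "_mean")]]
  result@summary$subcase[order(-means, seq_along(means))]
}

setMethod("show", "ExperimentResult", function(object) {
  cat(sprintf("ExperimentResult: %d subcase(s) x %d repeat(s)\n",
              nrow(object@summary), object@provenance$repeats))
  best <- object@ranking[1]
  row <- object@summary[object@summary$subcase == best, ]
  cat(sprintf("  best subcase: %s (mean accuracy %.3f, mean MCC %.3f)\n",
              best, row$accuracy_mean, row$mcc_mean))
})

#' 10-fold cross-validation with a configuration grid hook
#'
#' Partitions the records into `k` stratified folds; for every candidate
#' configuration and every fold, trains on the other k-1 folds (carving a
#' stratified internal validation subset for early stopping) and scores
#' the held-out fold. The selected configuration maximizes mean held-out
#' sensitivity, with mean accuracy as tiebreaker, mirroring a calibration
#' protocol that prioritizes recovering true glycation sites.
#'
#' @param peptides A labeled [PeptideSet-class].
#' @param k Number of folds (default 10).
#' @param plan An [experimentPlan()]; its `modelConfig` is the default
#'   candidate when `configs` is not given.
#' @param spec A [CaseSpec-class] naming the encoding under evaluation.
#' @param propertySet A [PropertySet-class].
#' @param configs List of candidate [ModelConfig-class] objects.
#' @param valFraction Fraction of the training folds held out internally
#'   for early stopping (default 0.15).
#' @return List with `perFold` (data frame of fold x config metrics),
#'   `summary` (per-config means), `bestConfig` (selected
#'   [ModelConfig-class]) and `folds` (the fold plan).
#' @export
crossValidate <- function(peptides, k = 10L, plan, spec, propertySet,
                          configs = list(plan$modelConfig),
                          valFraction = 0.15) {
  stopifnot(is(peptides, "PeptideSet"), inherits(plan, "ExperimentPlan"))
  foldPlan <- makeFolds(peptides, k, plan$baseSeed)
  ids <- peptideIds(peptides)
  rows <- list()
  for (ci in seq_along(configs)) {
    for (f in seq_len(foldPlan$k)) {
      heldIds <- foldPlan$folds[[f]]
      held <- peptides[match(heldIds, ids)]
      rest <- peptides[-match(heldIds, ids)]
      nval <- max(2L, round(length(rest) * valFraction))
      inner <- makeSplit(rest, sizes = c(length(rest) - nval, nval, 0L),
                         seed = plan$baseSeed + f)
      stats <- fitScaleStats(inner$train, propertySet)
      cfg <- reconfig(configs[[ci]], inputWidth = caseWidth(spec),
                      seed = as.integer(plan$baseSeed + 31L * f + ci))
      model <- trainModel(
        encodeDataset(inner$train, spec, propertySet, stats),
        encodeDataset(inner$validation, spec, propertySet, stats),
        cfg, stats)
      probs <- predictProba(model, encodeDataset(held, spec, propertySet, stats))
      met <- scorePredictions(peptideLabels(held), probs)
      rows[[length(rows) + 1L]] <- data.frame(
        config = ci, fold = f, n_held = length(held), t(as.numeric(met)))
    }
  }
  perFold <- do.call(rbind, rows)
  colnames(perFold)[4:9] <- METRIC_NAMES
  summ <- do.call(rbind, lapply(seq_along(configs), function(ci) {
    sub <- perFold[perFold$config == ci, METRIC_NAMES, drop = FALSE]
    data.frame(config = ci, t(colMeans(sub)))
  }))
  best <- summ$config[order(-summ$sensitivity, -summ$accuracy)][1]
  list(perFold = perFold, summary = summ,
       bestConfig = configs[[best]], bestIndex = best, folds = foldPlan)
}

#' Export an experiment result to delimited files
#'
#' Writes `metrics.tsv` (one row per subcase: mean and sd of the six
#' metrics), one `roc_<subcase>.csv` per subcase (fpr/tpr points of the
#' first repeat), and `provenance.json` (seeds, plan settings, scale
#' statistics and dataset fingerprints). Re-exporting the same result is
#' byte-identical.
#'
#' @param result An [ExperimentResult-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportResults <- function(result, dir) {
  stopifnot(is(result, "ExperimentResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- result@summary
  num <- vapply(summ, is.numeric, TRUE)
  summ[num] <- lapply(summ[num], function(x) sprintf("%.6f", x))
  con <- file(file.path(dir, "metrics.tsv"), open = "wb")
  writeLines(paste(colnames(summ), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(summ)), sep = "\t")), con)
  close(con)
  for (nm in names(result@roc)) {
    curve <- result@roc[[nm]]
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    con <- file(file.path(dir, sprintf("roc_%s.csv", safe)), open = "wb")
    writeLines("fpr,tpr", con)
    writeLines(sprintf("%.6f,%.6f", curve$fpr, curve$tpr), con)
    close(con)
  }
  jsonlite::write_json(
    c(result@provenance, list(ranking = result@ranking)),
    file.path(dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
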