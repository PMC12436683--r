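#' Confusion counts (positive class = glycated = 1)
#'
#' @param truth,predicted Integer 0/1 vectors of equal length.
#' @return Named list with `tp`, `fp`, `tn`, `fn` and `n`.
#' @export
confusionCounts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop(sprintf("length mismatch: %d true vs %d predicted labels",
                 length(truth), length(predicted)))
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop("labels must be 0 or 1")
  list(tp = sum(truth == 1 & predicted == 1),
       fp = sum(truth == 0 & predicted == 1),
       tn = sum(truth == 0 & predicted == 0),
       fn = sum(truth == 1 & predicted == 0),
       n = length(truth))
}

# a ratio that reports 0 (flagged) when its denominator vanishes
safeRatio <- function(num, den) {
  if (den == 0) structure(0, undefined = TRUE) else num / den
}

#' The five classification metrics from confusion counts
#'
#' Accuracy `(tp+tn)/n`, precision `tp/(tp+fp)`, sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)` and the Matthews correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. A metric whose
#' denominator vanishes is reported as 0 and listed in the `undefined`
#' attribute (so repeat averaging stays total while staying auditable).
#' MCC ranges over [-1, 1]: 1 for perfect classification, -1 for perfect
#' misclassification, 0 expected for a coin-tossing classifier.
#'
#' @param counts Result of [confusionCounts()].
#' @return Named numeric vector `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `mcc`, with an `undefined` character attribute naming
#'   any zero-denominator metrics.
#' @export
metricSuite <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop("cannot compute metrics on zero evaluated examples")
  undef <- character(0)
  prec <- safeRatio(tp, tp + fp)
  if (isTRUE(attr(prec, "undefined"))) undef <- c(undef, "precision")
  sens <- safeRatio(tp, tp + fn)
  if (isTRUE(attr(sens, "undefined"))) undef <- c(undef, "sensitivity")
  spec <- safeRatio(tn, tn + fp)
  if (isTRUE(attr(spec, "undefined"))) undef <- c(undef, "specificity")
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) { undef <- c(undef, "mcc"); 0 }
         else (tp * tn - fp * fn) / denom
  out <- c(accuracy = (tp + tn) / n, precision = as.numeric(prec),
           sensitivity = as.numeric(sens), specificity = as.numeric(spec),
           mcc = mcc)
  attr(out, "undefined") <- undef
  attr(out, "n") <- n
  out
}

#' ROC curve by threshold sweep
#'
#' Standard staircase over the distinct values of the positive-class
#' scores (ties grouped), from (0, 0) to (1, 1).
#'
#' @param truth Integer 0/1 vector; both classes must be present.
#' @param scores Numeric vector of `p_glycated` scores.
#' @return Data frame with columns `fpr`, `tpr`, both non-decreasing.
#' @export
rocCurve <- function(truth, scores) {
  if (length(truth) != length(scores)) stop("length mismatch")
  if (!all(truth %in% c(0, 1))) stop("labels must be 0 or 1")
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0 || nneg == 0)
    stop("ROC requires both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)  # group tied thresholds
  data.frame(fpr = c(0, fp[last_of_tie] / nneg),
             tpr = c(0, tp[last_of_tie] / npos))
}

#' Area under a ROC curve (trapezoidal)
#'
#' @param curve Data frame from [rocCurve()].
#' @return AUC in [0, 1]; 0.5 for the diagonal (random) reference.
#' @export
aucTrapezoid <- function(curve) {
  fpr <- curve$fpr; tpr <- curve$tpr
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Score a model's predictions with all metrics plus AUC
#'
#' @param truth Integer 0/1 vector.
#' @param probabilities Matrix with columns `(p_glycated, p_nonglycated)`.
#' @return Metric vector as in [metricSuite()] with an added `auc` entry.
#' @export
scorePredictions <- function(truth, probabilities) {
  pred <- classify(probabilities)
  m <- metricSuite(confusionCounts(truth, pred))
  auc <- aucTrapezoid(rocCurve(truth, probabilities[, 1]))
  out <- c(m, auc = auc)
  attr(out, "undefined") <- attr(m, "undefined")
  attr(out, "n") <- attr(m, "n")
  out
}

#' Null calibration: MCC of a coin-tossing classifier
#'
#' Simulates a classifier that assigns labels by a fair coin flip on
#' balanced binary labels and returns the per-simulation MCC values. Their
#' mean estimates the chance-level expectation (0) and is a calibration
#' check for the metric implementation.
#'
#' @param nSims Number of simulations.
#' @param n Labels per simulation (half positive, half negative).
#' @param seed Integer seed; simulation `i` uses `seed + i`.
#' @return Numeric vector of `nSims` MCC values.
#' @export
simulateNullMcc <- function(nSims = 50L, n = 10000L, seed = 1L) {
  vapply(seq_len(nSims), function(i) {
    withLocalSeed(seed + i, {
      truth <- sample(rep(c(0L, 1L), length.out = n))
      pred <- rbinom(n, 1L, 0.5)
    })
    metricSuite(confusionCounts(truth, pred))[["mcc"]]
  }, 0)
}

#' Average metric reports over repeats
#'
#' Arithmetic mean and sample (n-1) standard deviation per metric over
#' repeated training runs.
#'
#' @param reports List of metric vectors (from [metricSuite()] or
#'   [scorePredictions()]).
#' @return List with `mean`, `sd` (named numeric vectors) and `repeats`.
#' @export
aggregateRepeats <- function(reports) {
  if (length(reports) == 0L) stop("no reports to aggregate")
  mat <- do.call(rbind, lapply(reports, as.numeric))
  colnames(mat) <- names(reports[[1]])
  list(mean = colMeans(mat),
       sd = if (nrow(mat) > 1) apply(mat, 2, sd)
            else setNames(rep(0, ncol(mat)), colnames(mat)),
       repeats = nrow(mat))
}
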