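#' Create a model configuration
#'
#' Defaults follow the study protocol where it is explicit (64- and
#' 32-unit LSTM layers, 16-unit ReLU dense layer, 2-unit softmax output,
#' sparse categorical cross-entropy, Adam, batch size 64, early-stopping
#' patience 20) and documented package conventions where it is not
#' (dropout 0.2 on all three dropout layers, L2 coefficient 0.01 on the
#' LSTM input kernels, Adam learning rate 1e-3, epoch cap 200 so that
#' patience, not the cap, normally ends training).
#'
#' @param inputWidth 2 (cases 1-2) or 8 (case 3).
#' @param lstm1,lstm2,dense Layer unit counts.
#' @param dropout1,dropout2,dropout3 Dropout rates in [0, 1).
#' @param l2 L2 penalty coefficient.
#' @param learningRate Adam learning rate.
#' @param batchSize Mini-batch size.
#' @param maxEpochs Epoch cap.
#' @param patience Early-stopping patience.
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @param allowAnyWidth Permit experimental input widths outside \{2, 8\}.
#' @return A [ModelConfig-class].
#' @export
modelConfig <- function(inputWidth = 2L, lstm1 = 64L, lstm2 = 32L,
                        dense = 16L, dropout1 = 0.2, dropout2 = 0.2,
                        dropout3 = 0.2, l2 = 0.01, learningRate = 1e-3,
                        batchSize = 64L, maxEpochs = 200L, patience = 20L,
                        seed = 1L, allowAnyWidth = FALSE) {
  inputWidth <- as.integer(inputWidth)
  if (!inputWidth %in% c(2L, 8L) && !allowAnyWidth)
    stop("inputWidth must be 2 or 8 (set allowAnyWidth = TRUE to override)")
  obj <- new("ModelConfig", inputWidth = inputWidth,
             lstm1 = as.integer(lstm1), lstm2 = as.integer(lstm2),
             dense = as.integer(dense), dropout1 = dropout1,
             dropout2 = dropout2, dropout3 = dropout3, l2 = l2,
             learningRate = learningRate, batchSize = as.integer(batchSize),
             maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
             seed = as.integer(seed))
  validObject(obj)
  obj
}

# derive a config from a template, overriding selected slots
reconfig <- function(config, ...) {
  dots <- list(...)
  for (nm in names(dots)) slot(config, nm) <- dots[[nm]]
  validObject(config)
  config
}

#' Build an untrained model
#'
#' Initializes the parameter stack LSTM(lstm1) -> dropout -> LSTM(lstm2)
#' -> dropout -> dense(ReLU) -> dropout -> softmax(2) with seeded
#' Glorot-uniform kernels (forget-gate biases start at 1). Two builds with
#' the same config are bit-identical.
#'
#' @param config A [ModelConfig-class].
#' @return A list with elements `weights` (parameter list) and `config`.
#' @export
buildModel <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  weights <- lstm_init_cpp(config@inputWidth, config@lstm1, config@lstm2,
                           config@dense, config@seed)
  list(weights = weights, config = config)
}

#' Number of trainable parameters of a configuration
#'
#' A pure function of the layer sizes and input width; cases 1 and 2 share
#' an input width of 2, so their models have identical parameter counts.
#'
#' @param config A [ModelConfig-class].
#' @return Integer parameter count.
#' @export
countParams <- function(config) {
  k <- config@inputWidth; h1 <- config@lstm1; h2 <- config@lstm2
  d <- config@dense
  as.integer(4 * h1 * (k + h1 + 1) + 4 * h2 * (h1 + h2 + 1) +
             h2 * d + d + d * 2 + 2)
}

encWidth <- function(encoded) dim(encoded@data)[2]

#' Train the glycation classifier
#'
#' Mini-batch Adam training with sparse categorical cross-entropy,
#' monitoring accuracy on the validation encoding; training stops once
#' validation accuracy has not improved for `patience` epochs and the
#' parameters of the best epoch (earliest on ties) are restored.
#'
#' Training is deterministic for a fixed config seed (single-threaded
#' float32 arithmetic; initialization, shuffling and dropout share one
#' seeded stream).
#'
#' @param trainEncoded,valEncoded [EncodedSet-class] objects with known
#'   labels; widths must match `config@inputWidth`.
#' @param config A [ModelConfig-class].
#' @param stats The [ScaleStats-class] used to produce the encodings
#'   (stored so the model is self-describing at prediction time).
#' @return A [TrainedModel-class].
#' @export
trainModel <- function(trainEncoded, valEncoded, config, stats = NULL) {
  stopifnot(is(trainEncoded, "EncodedSet"), is(valEncoded, "EncodedSet"),
            is(config, "ModelConfig"))
  if (dim(trainEncoded@data)[3] == 0L || dim(valEncoded@data)[3] == 0L)
    stop("training and validation sets must be non-empty")
  for (enc in list(trainEncoded, valEncoded))
    if (encWidth(enc) != config@inputWidth)
      stop(sprintf("encoded width %d does not match config inputWidth %d",
                   encWidth(enc), config@inputWidth))
  ytr <- trainEncoded@label; yval <- valEncoded@label
  if (any(is.na(ytr)) || any(is.na(yval)))
    stop("training and validation labels must be known")
  init <- buildModel(config)$weights
  fit <- lstm_train_cpp(trainEncoded@data, ytr, valEncoded@data, yval, init,
                        config@learningRate, config@l2, config@dropout1,
                        config@dropout2, config@dropout3, config@batchSize,
                        config@maxEpochs, config@patience, config@seed)
  hist <- as.data.frame(fit$history)
  colnames(hist) <- c("loss", "accuracy", "val_loss", "val_accuracy")
  hist$epoch <- seq_len(nrow(hist))
  if (is.null(stats))
    stats <- new("ScaleStats", mean = setNames(rep(0, 8), propertyIds()),
                 sd = setNames(rep(1, 8), propertyIds()), n = 0L)
  new("TrainedModel", weights = fit$params, config = config, history = hist,
      bestEpoch = as.integer(fit$best_epoch), stats = stats,
      caseSpec = trainEncoded@caseSpec)
}

setMethod("show", "TrainedModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "TrainedModel: LSTM(%d)->LSTM(%d)->dense(%d)->softmax(2), input 31 x %d\n",
    cfg@lstm1, cfg@lstm2, cfg@dense, cfg@inputWidth))
  cat(sprintf("  subcase %s; trained %d epoch(s), best epoch %d (val acc %.3f)\n",
              subcaseName(object@caseSpec), nrow(object@history),
              object@bestEpoch,
              object@history$val_accuracy[object@bestEpoch]))
})

#' Predict glycation probabilities
#'
#' Inference is deterministic (dropout disabled); each output pair sums to
#' 1 by softmax construction.
#'
#' @param model A [TrainedModel-class].
#' @param encoded An [EncodedSet-class] of matching width.
#' @return Numeric matrix with columns `p_glycated`, `p_nonglycated`, one
#'   row per input example, in input order.
#' @export
predictProba <- function(model, encoded) {
  stopifnot(is(model, "TrainedModel"), is(encoded, "EncodedSet"))
  if (encWidth(encoded) != model@config@inputWidth)
    stop(sprintf("encoded width %d does not match model width %d",
                 encWidth(encoded), model@config@inputWidth))
  P <- lstm_predict_cpp(model@weights, encoded@data)
  out <- cbind(p_glycated = P[, 2], p_nonglycated = P[, 1])
  rownames(out) <- encoded@id
  out
}

#' Turn probability pairs into hard labels
#'
#' Label 1 (glycated) iff `p_glycated > p_nonglycated`; an exact tie is
#' called 0 (nonglycated) by convention.
#'
#' @param probabilities Matrix with columns `(p_glycated, p_nonglycated)`;
#'   rows must sum to 1 within 1e-6.
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(probabilities) {
  probabilities <- as.matrix(probabilities)
  if (ncol(probabilities) != 2L)
    stop("expected two probability columns")
  if (any(abs(rowSums(probabilities) - 1) > 1e-6))
    stop("probability pairs must sum to 1 within 1e-6")
  as.integer(probabilities[, 1] > probabilities[, 2])
}

#' Save / load a trained model
#'
#' The model is written as a single self-describing JSON file carrying the
#' parameter matrices, the full configuration, the training history, the
#' scale statistics used for encoding and the case specification, so a
#' reloaded model can encode and score new windows without any other
#' state.
#'
#' @param model A [TrainedModel-class].
#' @param path File path (`.json`).
#' @return `saveModel`: `path` invisibly; `loadModel`: a
#'   [TrainedModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel"))
  cfg <- model@config
  cfgList <- lapply(setNames(slotNames(cfg), slotNames(cfg)),
                    function(s) slot(cfg, s))
  wnames <- c("W1","U1","b1","W2","U2","b2","W3","b3","W4","b4")
  payload <- list(
    format = "glycLSTM-model-1",
    weights = lapply(setNames(wnames, wnames), function(nm) {
      w <- model@weights[[nm]]
      list(nrow = nrow(w), ncol = ncol(w), values = as.numeric(w))
    }),
    dims = model@weights$dims,
    config = cfgList,
    history = model@history,
    bestEpoch = model@bestEpoch,
    stats = list(mean = as.list(model@stats@mean), sd = as.list(model@stats@sd),
                 n = model@stats@n),
    caseSpec = list(case = model@caseSpec@case,
                    properties = model@caseSpec@properties))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "glycLSTM-model-1")
    stop("not a glycLSTM model file (missing format marker): ", path)
  cfg <- do.call(modelConfig, c(p$config[setdiff(names(p$config), "inputWidth")],
                                list(inputWidth = p$config$inputWidth,
                                     allowAnyWidth = TRUE)))
  weights <- lapply(p$weights, function(w)
    matrix(as.numeric(w$values), nrow = w$nrow, ncol = w$ncol))
  weights$dims <- as.integer(p$dims)
  stats <- new("ScaleStats",
               mean = unlist(p$stats$mean)[propertyIds()],
               sd = unlist(p$stats$sd)[propertyIds()],
               n = as.integer(p$stats$n))
  spec <- caseSpec(p$caseSpec$case,
                   if (p$caseSpec$case == 3L) NULL else p$caseSpec$properties)
  hist <- as.data.frame(p$history)
  new("TrainedModel", weights = weights, config = cfg, history = hist,
      bestEpoch = as.integer(p$bestEpoch), stats = stats, caseSpec = spec)
}
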