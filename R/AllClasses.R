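#' @title Core S4 classes
#' @name glycLSTM-classes
#' @description S4 containers for property scales, peptide windows, encoded
#'   datasets, model configuration, trained models and experiment results.
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' PropertySet: eight residue-to-value physicochemical scales
#'
#' Holds one numeric lookup table per scale identifier (see
#' [propertyIds()]), each keyed by the 20 standard one-letter residue
#' codes, plus the value assigned to the padding symbol `X` after
#' standardization.
#'
#' @slot tables Named list of eight named numeric vectors (20 residues each).
#' @slot padValue Numeric scalar; standardized value of the pad symbol.
#' @slot source Named character vector; provenance label per scale.
#' @export
setClass("PropertySet",
  representation(tables = "list", padValue = "numeric", source = "character"))

setValidity("PropertySet", function(object) {
  ids <- propertyIds()
  if (!identical(sort(names(object@tables)), sort(ids)))
    return("tables must contain exactly the eight canonical scale ids")
  for (id in ids) {
    tab <- object@tables[[id]]
    if (!is.numeric(tab) || !identical(sort(names(tab)), STANDARD_RESIDUES))
      return(sprintf("scale '%s' must key exactly the 20 standard residues", id))
    if (any(!is.finite(tab)))
      return(sprintf("scale '%s' contains non-finite values", id))
  }
  if (length(object@padValue) != 1L || !is.finite(object@padValue))
    return("padValue must be a finite scalar")
  TRUE
})

#' ScaleStats: per-scale standardization statistics
#'
#' Mean and standard deviation of each scale over the residue positions of a
#' training split; used to z-score encoded values. Fit with
#' [fitScaleStats()] on training data only.
#'
#' @slot mean Named numeric vector (one entry per scale).
#' @slot sd Named numeric vector, strictly positive.
#' @slot n Integer; number of residue positions the statistics summarize.
#' @export
setClass("ScaleStats",
  representation(mean = "numeric", sd = "numeric", n = "integer"))

setValidity("ScaleStats", function(object) {
  ids <- propertyIds()
  if (!identical(sort(names(object@mean)), sort(ids)) ||
      !identical(sort(names(object@sd)), sort(ids)))
    return("mean and sd must be named by the eight scale ids")
  if (any(!is.finite(object@mean)) || any(!is.finite(object@sd)))
    return("non-finite statistics")
  if (any(object@sd <= 0))
    return(sprintf("zero or negative standard deviation for scale(s): %s",
                   paste(names(object@sd)[object@sd <= 0], collapse = ", ")))
  TRUE
})

#' PeptideSet: labeled 31-mer lysine-centered peptide windows
#'
#' Each record is a 31-character window over the 20-letter amino-acid
#' alphabet plus the pad symbol `X`, with lysine (`K`) fixed at position 16
#' (1-based) and a binary glycation label (`1` glycated, `0` nonglycated,
#' `NA` unknown, e.g. prediction-mode windows).
#'
#' @slot id Character vector of unique record identifiers.
#' @slot sequence Character vector of 31-mer windows.
#' @slot label Integer vector in \{0, 1, NA\}.
#' @slot provenance Character scalar, free-text origin note.
#' @export
setClass("PeptideSet",
  representation(id = "character", sequence = "character",
                 label = "integer", provenance = "character"))

setValidity("PeptideSet", function(object) {
  n <- length(object@id)
  if (length(object@sequence) != n || length(object@label) != n)
    return("id, sequence and label must have equal length")
  if (anyDuplicated(object@id))
    return("record ids must be unique")
  bad <- which(nchar(object@sequence) != WINDOW_LENGTH)
  if (length(bad))
    return(sprintf("sequence length must be %d (record %s has %d)",
                   WINDOW_LENGTH, object@id[bad[1]],
                   nchar(object@sequence[bad[1]])))
  centers <- substr(object@sequence, CENTER_POS, CENTER_POS)
  bad <- which(centers != "K")
  if (length(bad))
    return(sprintf("central residue (position %d) must be 'K' (record %s has '%s')",
                   CENTER_POS, object@id[bad[1]], centers[bad[1]]))
  alphabet <- c(STANDARD_RESIDUES, PAD_SYMBOL)
  letters_used <- unique(strsplit(paste(object@sequence, collapse = ""), "")[[1]])
  extra <- setdiff(letters_used, alphabet)
  if (length(extra))
    return(sprintf("disallowed residue code(s): %s (ambiguity codes are rejected)",
                   paste(extra, collapse = ", ")))
  if (!all(object@label %in% c(0L, 1L, NA_integer_)))
    return("labels must be 0, 1 or NA")
  TRUE
})

#' CaseSpec: which scales feed the model input
#'
#' The three comparative designs: case 1 uses a single scale (duplicated
#' into two input columns), case 2 a pair of distinct scales, case 3 all
#' eight in canonical order.
#'
#' @slot case Integer in \{1, 2, 3\}.
#' @slot properties Character vector of scale ids (length 1, 2 or 8).
#' @export
setClass("CaseSpec",
  representation(case = "integer", properties = "character"))

setValidity("CaseSpec", function(object) {
  ids <- propertyIds()
  if (!object@case %in% 1:3) return("case must be 1, 2 or 3")
  if (!all(object@properties %in% ids))
    return("unknown scale id in properties")
  np <- length(object@properties)
  if (object@case == 1L && np != 1L) return("case 1 takes exactly one scale")
  if (object@case == 2L) {
    if (np != 2L) return("case 2 takes exactly two scales")
    if (object@properties[1] == object@properties[2])
      return("case 2 scales must be distinct (a duplicated scale is case 1)")
  }
  if (object@case == 3L && !identical(object@properties, ids))
    return("case 3 uses all eight scales in canonical order")
  TRUE
})

#' EncodedSet: numeric model inputs for a set of peptide windows
#'
#' A 31 x k x n array of standardized scale values (k = 2 for cases 1-2,
#' k = 8 for case 3), one slice per record, rows ordered N- to C-terminal.
#'
#' @slot data Numeric array, dim c(31, k, n).
#' @slot label Integer vector of length n (0/1/NA).
#' @slot id Character vector of length n.
#' @slot caseSpec The [CaseSpec-class] that produced the encoding.
#' @export
setClass("EncodedSet",
  representation(data = "array", label = "integer", id = "character",
                 caseSpec = "CaseSpec"))

setValidity("EncodedSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || d[1] != WINDOW_LENGTH)
    return("data must be a 31 x k x n array")
  if (!d[2] %in% c(2L, 8L)) return("input width must be 2 or 8")
  if (d[3] != length(object@label) || d[3] != length(object@id))
    return("label/id length must match the number of slices")
  if (any(!is.finite(object@data))) return("non-finite encoded values")
  TRUE
})

#' ModelConfig: architecture and training hyperparameters
#'
#' The classifier stack is fixed: LSTM(lstm1, tanh, L2 on input kernels) ->
#' dropout -> LSTM(lstm2, same configuration) -> dropout -> dense(dense,
#' ReLU) -> dropout -> 2-unit softmax output; sparse categorical
#' cross-entropy loss, Adam optimizer, mini-batches, early stopping on
#' validation accuracy with best-epoch restoration.
#'
#' @slot inputWidth Integer, 2 or 8 (number of encoded columns).
#' @slot lstm1,lstm2,dense Integer unit counts.
#' @slot dropout1,dropout2,dropout3 Dropout rates in [0, 1).
#' @slot l2 L2 penalty coefficient on the LSTM input kernels.
#' @slot learningRate Adam learning rate.
#' @slot batchSize Mini-batch size.
#' @slot maxEpochs Epoch cap.
#' @slot patience Early-stopping patience (epochs without validation
#'   accuracy improvement).
#' @slot seed Integer seed for initialization, shuffling and dropout.
#' @export
setClass("ModelConfig",
  representation(inputWidth = "integer", lstm1 = "integer", lstm2 = "integer",
                 dense = "integer", dropout1 = "numeric", dropout2 = "numeric",
                 dropout3 = "numeric", l2 = "numeric", learningRate = "numeric",
                 batchSize = "integer", maxEpochs = "integer",
                 patience = "integer", seed = "integer"))

setValidity("ModelConfig", function(object) {
  if (any(c(object@lstm1, object@lstm2, object@dense) < 1L))
    return("unit counts must be positive")
  rates <- c(object@dropout1, object@dropout2, object@dropout3)
  if (any(rates < 0) || any(rates >= 1))
    return("dropout rates must lie in [0, 1)")
  if (object@patience < 1L) return("patience must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@maxEpochs < 1L) return("maxEpochs must be >= 1")
  if (object@l2 < 0 || object@learningRate <= 0)
    return("l2 must be >= 0 and learningRate > 0")
  TRUE
})

#' TrainedModel: a fitted glycation classifier
#'
#' @slot weights List of parameter matrices (opaque handle).
#' @slot config The [ModelConfig-class] used for training.
#' @slot history Data frame of per-epoch loss/accuracy on the training and
#'   validation splits.
#' @slot bestEpoch Integer; epoch whose parameters are retained (highest
#'   validation accuracy, earliest on ties).
#' @slot stats The [ScaleStats-class] used to encode the training data
#'   (kept so saved models are self-describing).
#' @slot caseSpec The [CaseSpec-class] of the inputs.
#' @export
setClass("TrainedModel",
  representation(weights = "list", config = "ModelConfig",
                 history = "data.frame", bestEpoch = "integer",
                 stats = "ScaleStats", caseSpec = "CaseSpec"))

#' ExperimentResult: repeat-averaged metrics across subcases
#'
#' @slot summary Data frame: one row per subcase with mean and sd of each
#'   metric over repeats.
#' @slot repeats Data frame: one row per subcase x repeat with raw metrics.
#' @slot ranking Character vector of subcase names, best first, ranked by
#'   the plan's ranking metric.
#' @slot roc Named list of per-subcase ROC curves (first repeat).
#' @slot provenance List: seeds, plan settings, dataset fingerprint.
#' @export
setClass("ExperimentResult",
  representation(summary = "data.frame", repeats = "data.frame",
                 ranking = "character", roc = "list", provenance = "list"))
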