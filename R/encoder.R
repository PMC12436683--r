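#' Construct a CaseSpec
#'
#' @param case 1 (single scale, duplicated column), 2 (scale pair) or
#'   3 (all eight scales).
#' @param properties Scale ids: one for case 1, two distinct for case 2;
#'   ignored for case 3 (always the full canonical order).
#' @return A [CaseSpec-class].
#' @export
#' @examples
#' caseSpec(1, "IEP")
#' caseSpec(2, c("Mass", "ToA"))
#' caseSpec(3)
caseSpec <- function(case, properties = NULL) {
  case <- as.integer(case)
  if (case == 3L) properties <- propertyIds()
  obj <- new("CaseSpec", case = case, properties = as.character(properties))
  validObject(obj)
  obj
}

# name used in result tables: "IEP", "Mass+ToA" or "All8"
subcaseName <- function(spec) {
  if (spec@case == 3L) "All8" else paste(spec@properties, collapse = "+")
}

# number of encoded input columns for a case
caseWidth <- function(spec) if (spec@case == 3L) 8L else 2L

# map one 31-mer to a numeric column for one scale (standardized, pad -> 0)
encodeColumn <- function(sequence, lookup) {
  unname(lookup[strsplit(sequence, "")[[1]]])
}

# core single-record encoder shared by the three cases
encodeRecord <- function(sequence, props, propertySet, stats) {
  lut <- lapply(props, function(p) standardizedLookup(propertySet, p, stats))
  vapply(lut, function(l) encodeColumn(sequence, l), numeric(WINDOW_LENGTH))
}

#' Encode one window for case 1 (single scale, duplicated column)
#'
#' Column 1 holds the standardized scale value of each residue position
#' (N- to C-terminal); column 2 duplicates column 1, keeping the input
#' width (and hence the model parameter count) identical to case 2.
#'
#' @param peptide A single-record [PeptideSet-class] (or the first record
#'   of a larger one).
#' @param property Scale id.
#' @param propertySet A [PropertySet-class].
#' @param stats [ScaleStats-class] fitted on the training split.
#' @return Numeric 31 x 2 matrix.
#' @export
encodeCase1 <- function(peptide, property, propertySet, stats) {
  stopifnot(is(peptide, "PeptideSet"))
  col <- encodeRecord(peptide@sequence[1], property, propertySet, stats)[, 1]
  cbind(col, col, deparse.level = 0)
}

#' Encode one window for case 2 (two distinct scales)
#'
#' @param propA,propB Distinct scale ids; column 1 comes from `propA`,
#'   column 2 from `propB`.
#' @inheritParams encodeCase1
#' @return Numeric 31 x 2 matrix.
#' @export
encodeCase2 <- function(peptide, propA, propB, propertySet, stats) {
  stopifnot(is(peptide, "PeptideSet"))
  if (identical(propA, propB))
    stop("case 2 requires two distinct scales (a duplicated scale is case 1)")
  encodeRecord(peptide@sequence[1], c(propA, propB), propertySet, stats)
}

#' Encode one window for case 3 (all eight scales)
#'
#' Columns follow the canonical scale order (see [propertyIds()]).
#'
#' @inheritParams encodeCase1
#' @return Numeric 31 x 8 matrix.
#' @export
encodeCase3 <- function(peptide, propertySet, stats) {
  stopifnot(is(peptide, "PeptideSet"))
  encodeRecord(peptide@sequence[1], propertyIds(), propertySet, stats)
}

#' Enumerate unordered scale pairs
#'
#' All unordered pairs of the given scale ids, in lexicographic order by
#' canonical scale position (so the full set yields the 28 case-2
#' subcases in a fixed, reproducible order).
#'
#' @param propertyIdsUsed Character vector of at least two distinct scale ids.
#' @return List of character 2-vectors.
#' @export
#' @examples
#' length(enumeratePairs(propertyIds()))  # 28
enumeratePairs <- function(propertyIdsUsed = propertyIds()) {
  ids <- unique(propertyIdsUsed)
  if (!all(ids %in% propertyIds())) stop("unknown scale id")
  if (length(ids) < 2L) stop("need at least two distinct scale ids")
  ids <- ids[order(match(ids, propertyIds()))]
  out <- list()
  for (i in seq_len(length(ids) - 1L))
    for (j in seq(i + 1L, length(ids)))
      out[[length(out) + 1L]] <- c(ids[i], ids[j])
  out
}

#' Encode a whole PeptideSet for a case
#'
#' Order-preserving batch encoder; the result never depends on the labels
#' (they are carried through untouched).
#'
#' @param peptides A [PeptideSet-class].
#' @param spec A [CaseSpec-class].
#' @param propertySet A [PropertySet-class].
#' @param stats [ScaleStats-class] fitted on the training split only.
#' @return An [EncodedSet-class] with a 31 x k x n data array.
#' @export
encodeDataset <- function(peptides, spec, propertySet, stats) {
  stopifnot(is(peptides, "PeptideSet"), is(spec, "CaseSpec"))
  n <- length(peptides)
  k <- caseWidth(spec)
  props <- if (spec@case == 1L) rep(spec@properties, 2L) else spec@properties
  lut <- lapply(props, function(p) standardizedLookup(propertySet, p, stats))
  arr <- array(0, dim = c(WINDOW_LENGTH, k, n))
  if (n > 0) {
    chars <- strsplit(peptides@sequence, "")
    for (i in seq_len(n)) {
      ch <- chars[[i]]
      for (j in seq_len(k)) arr[, j, i] <- unname(lut[[j]][ch])
    }
  }
  new("EncodedSet", data = arr, label = peptides@label, id = peptides@id,
      caseSpec = spec)
}

setMethod("show", "EncodedSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EncodedSet: %d window(s) as %d x %d matrices (%s, case %d)\n",
              d[3], d[1], d[2],
              paste(object@caseSpec@properties, collapse = ","),
              object@caseSpec@case))
})
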