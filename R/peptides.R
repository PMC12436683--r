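#' Construct a PeptideSet
#'
#' @param id Character vector of unique identifiers (default `seq_1`, ...).
#' @param sequence Character vector of 31-mer windows (center lysine,
#'   20-letter alphabet plus pad `X`).
#' @param label Vector coercible to integer 0/1, or `NA` for unknown.
#' @param provenance Free-text origin note.
#' @return A [PeptideSet-class].
#' @export
#' @examples
#' PeptideSet(sequence = paste0(strrep("A", 15), "K", strrep("A", 15)),
#'            label = 1)
PeptideSet <- function(sequence, label = NA, id = NULL, provenance = "") {
  n <- length(sequence)
  if (is.null(id)) id <- sprintf("seq_%d", seq_len(n))
  label <- rep_len(as.integer(label), n)
  obj <- new("PeptideSet", id = as.character(id),
             sequence = toupper(as.character(sequence)),
             label = label, provenance = as.character(provenance)[1])
  validObject(obj)
  obj
}

#' @describeIn PeptideSet Number of records.
#' @param x A `PeptideSet`.
#' @export
setMethod("length", "PeptideSet", function(x) length(x@id))

#' @describeIn PeptideSet Subset records.
#' @param i Index vector.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = FALSE) {
  new("PeptideSet", id = x@id[i], sequence = x@sequence[i],
      label = x@label[i], provenance = x@provenance)
})

setMethod("show", "PeptideSet", function(object) {
  n <- length(object)
  npos <- sum(object@label == 1L, na.rm = TRUE)
  nneg <- sum(object@label == 0L, na.rm = TRUE)
  cat(sprintf("PeptideSet with %d 31-mer window(s): %d glycated, %d nonglycated, %d unlabeled\n",
              n, npos, nneg, n - npos - nneg))
  if (n > 0)
    cat(sprintf("  first: %s  %s\n", object@id[1], object@sequence[1]))
})

#' Accessors for PeptideSet slots
#'
#' @param x A [PeptideSet-class].
#' @return `peptideIds`: character vector; `peptideSequences`: character
#'   vector; `peptideLabels`: integer vector (NA = unknown).
#' @export
peptideIds <- function(x) { stopifnot(is(x, "PeptideSet")); x@id }

#' @rdname peptideIds
#' @export
peptideSequences <- function(x) { stopifnot(is(x, "PeptideSet")); x@sequence }

#' @rdname peptideIds
#' @export
peptideLabels <- function(x) { stopifnot(is(x, "PeptideSet")); x@label }

#' Read labeled peptide windows from a delimited table or FASTA file
#'
#' Two dialects are accepted. `"table"`: delimited text with a header and
#' columns `id`, `sequence`, `label` (tab or comma separated, chosen by
#' extension). `"fasta"`: FASTA records whose headers carry `id|label`.
#' By default the dialect is inferred from the file extension
#' (`.fa`/`.fasta` vs anything else).
#'
#' Every record is validated against the window invariants (length 31,
#' central lysine, no ambiguity codes, label in \{0, 1\}); violations
#' raise an error citing the offending line or record.
#'
#' @param path Input file.
#' @param dialect `"auto"`, `"table"` or `"fasta"`.
#' @return A [PeptideSet-class].
#' @export
readPeptideTable <- function(path, dialect = c("auto", "table", "fasta")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "table"
  if (dialect == "fasta") {
    aa <- Biostrings::readBStringSet(path)
    headers <- names(aa)
    parts <- strsplit(headers, "|", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad))
      stop(sprintf("FASTA record %d ('%s'): header must be 'id|label'",
                   bad[1], headers[bad[1]]))
    ids <- vapply(parts, `[`, "", 1L)
    labs <- vapply(parts, `[`, "", 2L)
    seqs <- as.character(aa)
    lines <- seq_along(ids)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                     colClasses = "character")
    need <- c("id", "sequence", "label")
    if (!all(need %in% colnames(df)))
      stop("peptide table must have columns id, sequence, label")
    ids <- df$id; seqs <- toupper(df$sequence); labs <- df$label
    lines <- seq_along(ids) + 1L   # header is line 1
  }
  checkPeptideRows(ids, seqs, labs, lines)
  PeptideSet(sequence = seqs, label = as.integer(labs), id = ids,
             provenance = path)
}

# row-level validation with line numbers (strict: no silent repair)
checkPeptideRows <- function(ids, seqs, labs, lines) {
  bad <- which(nchar(seqs) != WINDOW_LENGTH)
  if (length(bad))
    stop(sprintf("line %d (id %s): sequence length %d, expected %d",
                 lines[bad[1]], ids[bad[1]], nchar(seqs[bad[1]]), WINDOW_LENGTH))
  centers <- substr(seqs, CENTER_POS, CENTER_POS)
  bad <- which(centers != "K")
  if (length(bad))
    stop(sprintf("line %d (id %s): central residue is '%s', expected 'K'",
                 lines[bad[1]], ids[bad[1]], centers[bad[1]]))
  ok_chars <- grepl(sprintf("^[%sX]+$", paste(STANDARD_RESIDUES, collapse = "")), seqs)
  if (any(!ok_chars))
    stop(sprintf("line %d (id %s): sequence contains a disallowed residue code",
                 lines[which(!ok_chars)[1]], ids[which(!ok_chars)[1]]))
  bad <- which(!labs %in% c("0", "1", 0, 1))
  if (length(bad))
    stop(sprintf("line %d (id %s): label '%s' outside {0,1}",
                 lines[bad[1]], ids[bad[1]], labs[bad[1]]))
  invisible(TRUE)
}

#' Write a PeptideSet as a tab-separated peptide table
#'
#' @param peptides A [PeptideSet-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writePeptideTable <- function(peptides, path) {
  stopifnot(is(peptides, "PeptideSet"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("id\tsequence\tlabel", con)
  if (length(peptides) > 0)
    writeLines(paste(peptides@id, peptides@sequence,
                     ifelse(is.na(peptides@label), "NA", peptides@label),
                     sep = "\t"), con)
  invisible(path)
}

#' Extract lysine-centered candidate windows from a protein FASTA file
#'
#' Emits one unlabeled 31-mer window per lysine per protein; windows that
#' would overhang a terminus are padded with `X` so the lysine stays at
#' position 16. Record ids are `protein_id:K<position>` with 1-based
#' protein coordinates. Proteins containing ambiguity codes are skipped
#' with a warning.
#'
#' @param fastaPath Protein FASTA file.
#' @param flank Residues on each side of the lysine (default 15, giving
#'   31-mer windows).
#' @return A [PeptideSet-class] with `NA` labels (possibly empty).
#' @export
extractWindows <- function(fastaPath, flank = 15L) {
  aa <- Biostrings::readAAStringSet(fastaPath)
  ids <- character(0); seqs <- character(0)
  alphabet_re <- sprintf("^[%s]*$", paste(STANDARD_RESIDUES, collapse = ""))
  for (i in seq_along(aa)) {
    prot <- as.character(aa[[i]])
    pid <- sub("\\s.*$", "", names(aa)[i])
    if (!grepl(alphabet_re, prot)) {
      warning(sprintf("skipping protein '%s': contains non-standard residue codes", pid))
      next
    }
    kpos <- which(strsplit(prot, "")[[1]] == "K")
    for (p in kpos) {
      lo <- p - flank; hi <- p + flank
      core <- substr(prot, max(1L, lo), min(nchar(prot), hi))
      win <- paste0(strrep(PAD_SYMBOL, max(0L, 1L - lo)), core,
                    strrep(PAD_SYMBOL, max(0L, hi - nchar(prot))))
      ids <- c(ids, sprintf("%s:K%d", pid, p))
      seqs <- c(seqs, win)
    }
  }
  if (!length(ids))
    return(new("PeptideSet", id = character(0), sequence = character(0),
               label = integer(0), provenance = fastaPath))
  PeptideSet(sequence = seqs, label = NA, id = ids, provenance = fastaPath)
}

# deterministic RNG scope helper: evaluates expr under a local seed without
# touching the caller's RNG state
withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# allocate per-list positive-class quotas by largest remainder so each list
# is label-balanced to within one record
posQuota <- function(sizes, npos, ntot) {
  exact <- sizes * npos / ntot
  q <- floor(exact)
  need <- round(sum(exact)) - sum(q)
  if (need > 0) {
    ord <- order(exact - q, decreasing = TRUE)
    q[ord[seq_len(need)]] <- q[ord[seq_len(need)]] + 1L
  }
  as.integer(q)
}

#' Stratified train/validation/test split
#'
#' Draws a label-stratified random partition of the requested sizes,
#' deterministic for a given seed. The default sizes mirror the study
#' protocol: 4830 training, 1000 validation, 1000 independent test
#' windows. Records beyond `sum(sizes)` are left unused.
#'
#' @param peptides A labeled [PeptideSet-class].
#' @param sizes Integer vector of three sizes (train, validation, test).
#' @param seed Integer seed.
#' @return Named list of three [PeptideSet-class] objects (`train`,
#'   `validation`, `test`) plus the `seed`.
#' @export
makeSplit <- function(peptides, sizes = c(4830L, 1000L, 1000L), seed) {
  stopifnot(is(peptides, "PeptideSet"), length(sizes) == 3L)
  sizes <- as.integer(sizes)
  if (any(is.na(peptideLabels(peptides))))
    stop("all labels must be known to build a stratified split")
  n <- length(peptides)
  if (n < sum(sizes))
    stop(sprintf("insufficient records: %d required, %d available", sum(sizes), n))
  labs <- peptideLabels(peptides)
  withLocalSeed(seed, {
    pos <- sample(which(labs == 1L))
    neg <- sample(which(labs == 0L))
  })
  qpos <- posQuota(sizes, length(pos), n)
  qneg <- sizes - qpos
  if (any(qpos > length(pos)) || any(qneg > length(neg)))
    stop("class composition too skewed for the requested stratified sizes")
  take <- function(pool, k, off) pool[off + seq_len(k)]
  idx <- list(
    train = c(take(pos, qpos[1], 0L), take(neg, qneg[1], 0L)),
    validation = c(take(pos, qpos[2], qpos[1]), take(neg, qneg[2], qneg[1])),
    test = c(take(pos, qpos[3], qpos[1] + qpos[2]),
             take(neg, qneg[3], qneg[1] + qneg[2])))
  out <- lapply(idx, function(i) peptides[sort(i)])
  out$seed <- as.integer(seed)
  out
}

#' Stratified k-fold plan
#'
#' Partitions record ids into `k` label-stratified folds whose sizes (and
#' per-class counts) differ by at most one; deterministic for a given seed.
#'
#' @param peptides A labeled [PeptideSet-class].
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List with `folds` (list of k character vectors of record ids),
#'   `k` and `seed`.
#' @export
makeFolds <- function(peptides, k = 10L, seed) {
  stopifnot(is(peptides, "PeptideSet"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  n <- length(peptides)
  if (n < k) stop(sprintf("need at least %d records for %d folds", k, k))
  labs <- peptideLabels(peptides)
  if (any(is.na(labs))) stop("all labels must be known to build folds")
  ord <- withLocalSeed(seed, c(sample(which(labs == 1L)), sample(which(labs == 0L))))
  assignment <- rep_len(seq_len(k), n)    # cyclic over strata-ordered records
  folds <- lapply(seq_len(k), function(f) peptideIds(peptides)[ord[assignment == f]])
  list(folds = folds, k = k, seed = as.integer(seed))
}

#' Write per-window glycation probabilities
#'
#' Tab-separated output with columns `id`, `sequence`, `p_glycated`,
#' `p_nonglycated`, `predicted_label` (argmax; an exact tie is called
#' nonglycated).
#'
#' @param peptides A [PeptideSet-class].
#' @param probabilities Numeric matrix, one row per record, columns
#'   `(p_glycated, p_nonglycated)`; each row must sum to 1 within 1e-6.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(peptides, probabilities, path) {
  stopifnot(is(peptides, "PeptideSet"))
  probabilities <- as.matrix(probabilities)
  if (nrow(probabilities) != length(peptides))
    stop(sprintf("%d probability pairs for %d records",
                 nrow(probabilities), length(peptides)))
  if (ncol(probabilities) != 2L)
    stop("probabilities must have two columns (p_glycated, p_nonglycated)")
  if (any(abs(rowSums(probabilities) - 1) > 1e-6))
    stop("each probability pair must sum to 1 within 1e-6")
  pred <- classify(probabilities)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("id\tsequence\tp_glycated\tp_nonglycated\tpredicted_label", con)
  if (length(peptides) > 0)
    writeLines(sprintf("%s\t%s\t%.6f\t%.6f\t%d", peptides@id, peptides@sequence,
                       probabilities[, 1], probabilities[, 2], pred), con)
  invisible(path)
}
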