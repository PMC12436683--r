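#' Load the built-in physicochemical scale set
#'
#' Returns the eight residue scales used throughout the package: SoA
#' (ordinal code of the one-letter alphabet, a placeholder for "sequence
#' structure"), Hyd (Kyte-Doolittle hydropathy), Mass (average residue
#' mass, Da), Hyp (Fauchere-Pliska hydrophobicity), Pol (polarizability),
#' vdW (normalized van der Waals volume), ToA (Chou-Fasman helical
#' propensity, a backbone-conformation preference placeholder) and IEP
#' (isoelectric point, pH units). Any or all scales can be replaced from a
#' TSV file with [loadPropertyTableFile()].
#'
#' @return A [PropertySet-class] with all eight scales.
#' @export
#' @examples
#' ps <- loadBuiltinPropertySet()
#' propertyValues(ps, "Mass")[c("G", "W")]
loadBuiltinPropertySet <- function() {
  path <- system.file("extdata", "property_scales.tsv", package = "glycLSTM",
                      mustWork = TRUE)
  src <- c(SoA = "ordinal alphabetical code (placeholder)",
           Hyd = "Kyte-Doolittle hydropathy",
           Mass = "average residue mass (Da)",
           Hyp = "Fauchere-Pliska hydrophobicity",
           Pol = "polarizability (AAindex CHAM820101)",
           vdW = "normalized van der Waals volume (AAindex FAUJ880103)",
           ToA = "Chou-Fasman helix propensity (backbone-conformation placeholder)",
           IEP = "amino-acid isoelectric point (pH)")
  loadPropertyTableFile(path, source = src)
}

#' Load physicochemical scales from a TSV file
#'
#' Reads a tab-separated table with a header line
#' `residue SoA Hyd Mass Hyp Pol vdW ToA IEP`, one row per standard
#' residue (20 rows, any order). This is the override hook for supplying
#' custom or transcribed scale values.
#'
#' @param path File path.
#' @param source Optional named character vector of provenance labels.
#' @return A [PropertySet-class].
#' @export
loadPropertyTableFile <- function(path, source = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!identical(colnames(df)[1], "residue"))
    stop("first column must be named 'residue'")
  extra <- setdiff(colnames(df)[-1], propertyIds())
  if (length(extra))
    stop("unknown scale column(s): ", paste(extra, collapse = ", "))
  missing_col <- setdiff(propertyIds(), colnames(df))
  if (length(missing_col))
    stop("missing scale column(s): ", paste(missing_col, collapse = ", "))
  res <- as.character(df$residue)
  dup <- res[duplicated(res)]
  if (length(dup))
    stop("duplicated residue row(s): ", paste(unique(dup), collapse = ", "))
  missing_res <- setdiff(STANDARD_RESIDUES, res)
  if (length(missing_res))
    stop("missing residue row(s): ", paste(missing_res, collapse = ", "))
  unknown_res <- setdiff(res, STANDARD_RESIDUES)
  if (length(unknown_res))
    stop("unknown residue row(s): ", paste(unknown_res, collapse = ", "))
  tables <- list()
  for (id in propertyIds()) {
    v <- df[[id]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s', residue row '%s'",
                   id, res[bad]))
    }
    if (any(!is.finite(v)))
      stop(sprintf("non-finite value in column '%s'", id))
    tables[[id]] <- setNames(as.numeric(v), res)[STANDARD_RESIDUES]
  }
  if (is.null(source))
    source <- setNames(rep(basename(path), length(propertyIds())), propertyIds())
  new("PropertySet", tables = tables, padValue = 0, source = source)
}

#' Write a property set to the TSV interchange format
#'
#' Inverse of [loadPropertyTableFile()]: values round-trip exactly through
#' their decimal representation (up to 15 significant digits).
#'
#' @param propertySet A [PropertySet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePropertyTable <- function(propertySet, path) {
  stopifnot(is(propertySet, "PropertySet"))
  df <- data.frame(residue = STANDARD_RESIDUES, stringsAsFactors = FALSE)
  for (id in propertyIds())
    df[[id]] <- format(propertySet@tables[[id]][STANDARD_RESIDUES],
                       digits = 15, trim = TRUE, scientific = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

#' Look up the raw values of one scale
#'
#' @param propertySet A [PropertySet-class].
#' @param id Scale identifier (see [propertyIds()]).
#' @return Named numeric vector over the 20 standard residues.
#' @export
propertyValues <- function(propertySet, id) {
  stopifnot(is(propertySet, "PropertySet"))
  if (!id %in% propertyIds()) stop("unknown scale id: ", id)
  propertySet@tables[[id]]
}

#' Fit standardization statistics on a training split
#'
#' Computes the mean and standard deviation of every scale over all
#' non-pad residue positions of the given records. Fit these on the
#' training split only, then reuse them to encode validation and test data
#' so no information leaks across the split boundary.
#'
#' @param peptides A [PeptideSet-class] (the training split).
#' @param propertySet A [PropertySet-class].
#' @return A [ScaleStats-class].
#' @export
fitScaleStats <- function(peptides, propertySet) {
  stopifnot(is(peptides, "PeptideSet"), is(propertySet, "PropertySet"))
  if (length(peptides) == 0L)
    stop("cannot fit scale statistics on an empty record set")
  chars <- strsplit(peptides@sequence, "")
  residues <- unlist(chars, use.names = FALSE)
  residues <- residues[residues != PAD_SYMBOL]
  counts <- table(factor(residues, levels = STANDARD_RESIDUES))
  n <- sum(counts)
  mu <- sdv <- setNames(numeric(length(propertyIds())), propertyIds())
  for (id in propertyIds()) {
    vals <- propertySet@tables[[id]][STANDARD_RESIDUES]
    m <- sum(vals * counts) / n
    # sample variance over the multiset of observed residue values
    v <- sum(counts * (vals - m)^2) / (n - 1)
    if (v <= 0)
      stop(sprintf("scale '%s' has zero variance on this split; cannot standardize", id))
    mu[id] <- m
    sdv[id] <- sqrt(v)
  }
  new("ScaleStats", mean = mu, sd = sdv, n = as.integer(n))
}

#' Standardize a raw scale value
#'
#' Affine z-score `(value - mean) / sd` with the fitted statistics; the pad
#' symbol always maps to 0 (the population center), whatever the statistics.
#'
#' @param value Numeric vector of raw values, or the pad symbol `"X"`.
#' @param property Scale identifier.
#' @param stats A [ScaleStats-class].
#' @return Numeric vector of standardized values.
#' @export
standardize <- function(value, property, stats) {
  stopifnot(is(stats, "ScaleStats"))
  if (!property %in% propertyIds()) stop("unknown scale id: ", property)
  if (is.character(value)) {
    if (!all(value == PAD_SYMBOL))
      stop("character input must be the pad symbol 'X'")
    return(rep(0, length(value)))
  }
  (value - stats@mean[[property]]) / stats@sd[[property]]
}

# Standardized per-residue lookup vector for one scale: the 20 residues
# z-scored, pad symbol at 0.
standardizedLookup <- function(propertySet, property, stats) {
  z <- standardize(propertySet@tables[[property]][STANDARD_RESIDUES],
                   property, stats)
  c(setNames(z, STANDARD_RESIDUES), setNames(0, PAD_SYMBOL))
}
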