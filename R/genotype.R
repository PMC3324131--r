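AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse a resistance-mutation pattern label
#'
#' Patterns follow the standard HIV resistance nomenclature: reference
#' residue, 1-based amino-acid position on the reference, then one or
#' more accepted alternate residues, with or without "/" separators
#' ("M184VI" is equivalent to "M184V/I").
#'
#' @param label character scalar, e.g. `"T215Y/F"`
#' @return an object of class `mutation_pattern`: a list with `position`
#'   (integer), `ref` (single letter), `alts` (character vector), and the
#'   canonical `label` (alternates "/"-separated).
#' @examples
#' parse_mutation_pattern("M184VI")
#' @seealso [format_mutation_pattern()], [call_mutations()]
#' @export
parse_mutation_pattern <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  raw <- toupper(trimws(label))
  m <- regmatches(raw, regexec("^([A-Z])([0-9]+)((?:/?[A-Z])+)$", raw))[[1]]
  if (length(m) != 4L) {
    stop_slgeno(sprintf("malformed mutation pattern label: '%s'", label),
                "slgeno_parse_error")
  }
  ref <- m[2]
  position <- as.integer(m[3])
  alts <- unique(strsplit(gsub("/", "", m[4]), "")[[1]])
  if (position < 1L) {
    stop_slgeno(sprintf("position must be >= 1 in '%s'", label),
                "slgeno_parse_error")
  }
  if (ref %in% alts) {
    stop_slgeno(
      sprintf("reference residue listed among alternates in '%s'", label),
      "slgeno_parse_error")
  }
  bad <- setdiff(c(ref, alts), AA_LETTERS)
  if (length(bad)) {
    stop_slgeno(sprintf("non-amino-acid letter(s) %s in '%s'",
                        paste(bad, collapse = ","), label),
                "slgeno_parse_error")
  }
  structure(
    list(position = position, ref = ref, alts = alts,
         label = paste0(ref, position, paste(alts, collapse = "/"))),
    class = "mutation_pattern")
}

#' Canonical label of a mutation pattern
#' @param pattern a `mutation_pattern`
#' @return character scalar, alternates "/"-separated (e.g. `"M184V/I"`)
#' @export
format_mutation_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "mutation_pattern"))
  pattern$label
}

#' @export
print.mutation_pattern <- function(x, ...) {
  cat("<mutation_pattern>", x$label, "\n")
  invisible(x)
}

#' Read a mutation-pattern list file
#'
#' Plain text, one pattern label per line; blank lines and `#` comments
#' are ignored.
#'
#' @param path file path
#' @return list of `mutation_pattern`
#' @export
read_mutation_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_mutation_pattern)
}

#' Read aligned amino-acid sequences from FASTA
#'
#' Headers (up to the first whitespace) are used as patient ids. Uses
#' Biostrings when available.
#'
#' @param path FASTA file path
#' @return named character vector of aligned amino-acid sequences
#' @export
read_fasta_aa <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_slgeno("reading FASTA requires the Biostrings package",
                "slgeno_dependency_error")
  }
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

# Split one sequence into per-position residue cells. Character-string
# input gives one residue per position; list input may carry mixtures
# ("VI") in a cell.
as_residue_cells <- function(seq) {
  if (is.character(seq) && length(seq) == 1L) {
    strsplit(toupper(seq), "")[[1]]
  } else {
    toupper(as.character(seq))
  }
}

#' Call mutations against a reference sequence
#'
#' An entry is 1 iff the patient's residue at the pattern position is one
#' of the pattern's alternates. A cell may carry a population mixture
#' (several residues, e.g. `"VI"`): the mutation is called if any residue
#' in the cell is an alternate. Gaps (`-`, `.`) and indeterminate `X`
#' give 0 with a warning (absence of evidence, not presence).
#'
#' @param sequences named character vector of aligned sequences (one
#'   character per position), or a named list of per-position character
#'   vectors whose cells may hold mixtures
#' @param patterns list of `mutation_pattern` (or labels, parsed on the
#'   fly)
#' @param reference the aligned reference amino-acid sequence (character
#'   scalar); each pattern's reference residue must match it
#' @return binary matrix, patients x mutations, dimnames = (patient ids,
#'   canonical labels)
#' @export
call_mutations <- function(sequences, patterns, reference) {
  patterns <- lapply(patterns, function(p) {
    if (inherits(p, "mutation_pattern")) p else parse_mutation_pattern(p)
  })
  ref_cells <- as_residue_cells(reference)
  ref_len <- length(ref_cells)
  for (p in patterns) {
    if (p$position > ref_len) {
      stop_slgeno(sprintf("pattern %s position beyond reference length %d",
                          p$label, ref_len), "slgeno_alignment_error")
    }
    if (!identical(ref_cells[p$position], p$ref)) {
      stop_slgeno(sprintf(
        "reference mismatch at position %d: pattern %s expects %s, reference has %s",
        p$position, p$label, p$ref, ref_cells[p$position]),
        "slgeno_reference_mismatch")
    }
  }
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop_slgeno("sequences must be uniquely named by patient id",
                "slgeno_format_error")
  }
  labels <- vapply(patterns, `[[`, character(1), "label")
  out <- matrix(0L, length(sequences), length(patterns),
                dimnames = list(ids, labels))
  n_indet <- 0L
  for (i in seq_along(sequences)) {
    cells <- as_residue_cells(sequences[[i]])
    if (length(cells) != ref_len) {
      stop_slgeno(sprintf(
        "sequence '%s' length %d does not match reference length %d",
        ids[i], length(cells), ref_len), "slgeno_alignment_error")
    }
    for (j in seq_along(patterns)) {
      residues <- strsplit(cells[patterns[[j]]$position], "")[[1]]
      if (any(residues %in% c("X", "-", "."))) {
        n_indet <- n_indet + 1L
        residues <- setdiff(residues, c("X", "-", "."))
      }
      out[i, j] <- as.integer(any(residues %in% patterns[[j]]$alts))
    }
  }
  if (n_indet > 0L) {
    warning(sprintf(
      "%d indeterminate cell(s) (gap or X) at pattern positions called as 0",
      n_indet), call. = FALSE)
  }
  out
}

validate_genotype_matrix <- function(x) {
  if (!is.matrix(x) || !all(x %in% c(0, 1))) {
    stop_slgeno("genotype matrix entries must all be 0 or 1",
                "slgeno_format_error")
  }
  if (is.null(colnames(x)) || is.null(rownames(x))) {
    stop_slgeno("genotype matrix needs patient ids (rownames) and mutation labels (colnames)",
                "slgeno_format_error")
  }
  if (anyDuplicated(rownames(x))) {
    stop_slgeno("duplicate patient ids", "slgeno_format_error")
  }
  invisible(x)
}

#' Bundle a genotype matrix with a continuous virologic outcome
#'
#' The outcome is the change in plasma HIV-1 RNA (delta VL) in log10
#' copies/mL; negative values are reductions.
#'
#' @param genotype binary patients x mutations matrix with dimnames
#' @param outcome numeric vector, one value per patient, finite
#' @return object of class `geno_dataset` with elements `genotype`,
#'   `outcome`
#' @export
geno_dataset <- function(genotype, outcome) {
  storage.mode(genotype) <- "double"
  validate_genotype_matrix(genotype)
  outcome <- as.numeric(outcome)
  if (length(outcome) != nrow(genotype)) {
    stop_slgeno("outcome length must equal patient count", "slgeno_format_error")
  }
  if (any(!is.finite(outcome))) {
    stop_slgeno("outcome values must be finite", "slgeno_format_error")
  }
  names(outcome) <- rownames(genotype)
  structure(list(genotype = genotype, outcome = outcome),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat(sprintf("<geno_dataset> %d patients x %d mutations\n",
              nrow(x$genotype), ncol(x$genotype)))
  cat("  mutations:", paste(colnames(x$genotype), collapse = ", "), "\n")
  cat(sprintf("  delta VL (log10 copies/mL): median %.3f, IQR (%.3f, %.3f)\n",
              stats::median(x$outcome),
              stats::quantile(x$outcome, 0.25),
              stats::quantile(x$outcome, 0.75)))
  invisible(x)
}

#' Per-mutation sample prevalence
#' @param genotype a binary genotype matrix or a `geno_dataset`
#' @return named numeric vector of column means in \[0, 1\]
#' @export
prevalence <- function(genotype) {
  if (inherits(genotype, "geno_dataset")) genotype <- genotype$genotype
  if (!is.matrix(genotype) || nrow(genotype) < 1L) {
    stop_slgeno("prevalence needs a genotype matrix with at least one patient",
                "slgeno_format_error")
  }
  colMeans(genotype)
}

OUTCOME_COL <- "delta_vl_log10"

#' Read / write the dataset CSV dialect
#'
#' Header `patient_id`, one 0/1 column per canonical mutation label, then
#' `delta_vl_log10`. The round trip `write_dataset()` then
#' [read_dataset()] is lossless.
#'
#' @param path CSV file path
#' @return `read_dataset`: a [geno_dataset()]
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"patient_id" %in% names(df) || !OUTCOME_COL %in% names(df)) {
    stop_slgeno(sprintf("dataset CSV needs 'patient_id' and '%s' columns",
                        OUTCOME_COL), "slgeno_format_error")
  }
  mut_cols <- setdiff(names(df), c("patient_id", OUTCOME_COL))
  if (!length(mut_cols)) {
    stop_slgeno("dataset CSV has no mutation columns", "slgeno_format_error")
  }
  if (anyDuplicated(df$patient_id)) {
    stop_slgeno(sprintf("duplicate patient id '%s'",
                        df$patient_id[duplicated(df$patient_id)][1]),
                "slgeno_format_error")
  }
  geno <- matrix(NA_real_, nrow(df), length(mut_cols),
                 dimnames = list(df$patient_id, mut_cols))
  for (j in seq_along(mut_cols)) {
    cell <- trimws(df[[mut_cols[j]]])
    bad <- which(!cell %in% c("0", "1"))
    if (length(bad)) {
      stop_slgeno(sprintf(
        "non-binary genotype value '%s' at row %d, column '%s'",
        cell[bad[1]], bad[1], mut_cols[j]), "slgeno_format_error")
    }
    geno[, j] <- as.numeric(cell)
  }
  yraw <- trimws(df[[OUTCOME_COL]])
  y <- suppressWarnings(as.numeric(yraw))
  bad <- which(!nzchar(yraw) | is.na(y))
  if (length(bad)) {
    stop_slgeno(sprintf("missing or non-numeric outcome at row %d", bad[1]),
                "slgeno_format_error")
  }
  geno_dataset(geno, y)
}

#' @rdname read_dataset
#' @param dataset a `geno_dataset`
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "geno_dataset"))
  df <- data.frame(patient_id = rownames(dataset$genotype),
                   dataset$genotype,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[[OUTCOME_COL]] <- format(dataset$outcome, digits = 17, trim = TRUE,
                              scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
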