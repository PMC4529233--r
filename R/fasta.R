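#' Read a peptide FASTA file
#'
#' Reads plain FASTA into a tibble, one row per record. The description line
#' is interpreted as a record name followed by optional whitespace-separated
#' `key=value` metadata pairs, which become extra columns.
#'
#' @param path FASTA file path.
#' @param alphabet Residue alphabet used to validate the sequences.
#' @return A tibble with columns `name`, `sequence`, plus one column per
#'   metadata key found.
#' @export
read_peptide_fasta <- function(path, alphabet = aa_alphabet()) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) {
    abort(sprintf("no FASTA records in '%s'", path), class = "pepremc_empty_fasta")
  }
  seqs <- vapply(as.character(aa), make_peptide, character(1),
                 alphabet = alphabet, USE.NAMES = FALSE)
  descs <- names(aa)
  tokens <- strsplit(trimws(descs), "\\s+")
  nm <- vapply(tokens, function(x) x[1], character(1))
  meta <- purrr::map(tokens, function(x) {
    kv <- grep("=", x[-1], fixed = TRUE, value = TRUE)
    parts <- strsplit(kv, "=", fixed = TRUE)
    vals <- setNames(
      vapply(parts, function(p) paste(p[-1], collapse = "="), character(1)),
      vapply(parts, `[[`, character(1), 1)
    )
    vals
  })
  out <- tibble(name = nm, sequence = seqs)
  for (key in unique(unlist(lapply(meta, names)))) {
    out[[key]] <- vapply(meta, function(m) m[key] %|na|% NA_character_,
                         character(1), USE.NAMES = FALSE)
  }
  out
}

#' Write peptides to FASTA
#'
#' Inverse of [read_peptide_fasta()]: writes one record per row, carrying any
#' columns beyond `name`/`sequence` as `key=value` pairs on the description
#' line. FASTA has no comment syntax, so file-level provenance (tool version,
#' seed, config hash) is attached to every record's description instead.
#'
#' @param x Data frame with columns `name` and `sequence`.
#' @param path Output file path.
#' @param metadata Named character vector appended to every description line.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(x, path, metadata = NULL) {
  stopifnot(is.data.frame(x), all(c("name", "sequence") %in% names(x)))
  extra_cols <- setdiff(names(x), c("name", "sequence"))
  descs <- vapply(seq_len(nrow(x)), function(i) {
    kv <- character(0)
    for (col in extra_cols) {
      val <- x[[col]][i]
      if (is.numeric(val)) val <- format(val, digits = 10)
      kv <- c(kv, paste0(col, "=", val))
    }
    if (!is.null(metadata)) {
      kv <- c(kv, paste0(names(metadata), "=", unname(metadata)))
    }
    paste(c(x$name[i], kv), collapse = " ")
  }, character(1))
  aa <- Biostrings::AAStringSet(x$sequence)
  names(aa) <- descs
  Biostrings::writeXStringSet(aa, path, width = 80L)
  invisible(path)
}
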