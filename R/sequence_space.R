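#' The twenty canonical amino acids
#'
#' One-letter codes, alphabetical. This is the default residue alphabet for
#' every sequence-space operation; smaller alphabets (e.g. a four-letter set
#' for exhaustively enumerable test spaces) go through the same code paths.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

check_alphabet <- function(alphabet) {
  if (!is.character(alphabet) || length(alphabet) < 1 ||
      any(nchar(alphabet) != 1) || anyDuplicated(toupper(alphabet))) {
    abort("`alphabet` must be distinct single characters.",
          class = "pepremc_bad_alphabet")
  }
  toupper(alphabet)
}

#' Validate a peptide sequence
#'
#' Canonicalises a residue string to upper case and checks every residue
#' against the declared alphabet. Campaigns fix the chain length elsewhere;
#' this only guarantees alphabet membership.
#'
#' @param sequence Residue string, e.g. `"AAAAAAAA"`. Case-insensitive.
#' @param alphabet Allowed one-letter residue codes.
#' @return The validated sequence as an upper-case character scalar.
#' @export
#' @examples
#' make_peptide("yhfpyfrf")
make_peptide <- function(sequence, alphabet = aa_alphabet()) {
  alphabet <- check_alphabet(alphabet)
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      !nzchar(trimws(sequence))) {
    abort("`sequence` must be a single non-empty residue string.",
          class = "pepremc_invalid_residue")
  }
  up <- toupper(trimws(sequence))
  chars <- strsplit(up, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0) {
    abort(
      sprintf("invalid residue '%s' at position %d (allowed: %s)",
              chars[bad[1]], bad[1], paste(alphabet, collapse = "")),
      class = "pepremc_invalid_residue"
    )
  }
  up
}

#' Single-point mutation move
#'
#' Proposes a new sequence differing from the input at exactly one position:
#' the position is drawn uniformly over the chain, the replacement uniformly
#' over the alphabet excluding the incumbent residue. This kernel is symmetric
#' (P(p to q) = P(q to p) for all Hamming-1 pairs), which the Metropolis rule
#' needs in order to target the Boltzmann measure, and connects sequence space
#' in at most `nchar(sequence)` moves.
#'
#' Consumes exactly two draws from the R random stream (position, residue).
#'
#' @inheritParams make_peptide
#' @return The mutated sequence (the input is unchanged).
#' @export
#' @examples
#' set.seed(1)
#' mutate_peptide("AAAAAAAA")
mutate_peptide <- function(sequence, alphabet = aa_alphabet()) {
  alphabet <- check_alphabet(alphabet)
  if (length(alphabet) < 2) {
    abort("mutation needs an alphabet of at least 2 residues.",
          class = "pepremc_bad_alphabet")
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), 1L)
  others <- alphabet[alphabet != chars[pos]]
  chars[pos] <- others[sample.int(length(others), 1L)]
  paste(chars, collapse = "")
}

#' Enumerate a small sequence space
#'
#' Deterministic enumeration of all sequences of a given length, lexicographic
#' in the supplied alphabet order. Intended for exact reference computations
#' (partition functions, brute-force optima) on spaces small enough to hold in
#' memory.
#'
#' @param length Chain length.
#' @param alphabet Allowed residues; their order fixes the enumeration order.
#' @param cap Refuse spaces larger than this many sequences.
#' @return Character vector of `length(alphabet)^length` sequences.
#' @export
#' @examples
#' enumerate_peptides(2, c("A", "G"))
enumerate_peptides <- function(length, alphabet = aa_alphabet(), cap = 1e6) {
  alphabet <- check_alphabet(alphabet)
  stopifnot(is.numeric(length), length >= 1, length == floor(length))
  n <- length(alphabet)^length
  if (n > cap) {
    abort(sprintf("sequence space has %.3g sequences, above the cap of %.3g",
                  n, cap),
          class = "pepremc_space_too_large")
  }
  seqs <- alphabet
  if (length > 1) {
    for (i in seq_len(length - 1)) {
      seqs <- as.vector(t(outer(seqs, alphabet, paste0)))
    }
  }
  seqs
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b Residue strings of equal length.
#' @return Integer count of differing positions.
#' @export
hamming_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) {
    abort("sequences must have equal length.", class = "pepremc_length_mismatch")
  }
  sum(ca != cb)
}

# integer encoding used by the engine hot loops
encode_seq <- function(sequence, alphabet) {
  idx <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], alphabet)
  if (anyNA(idx)) {
    abort("sequence contains residues outside the backend alphabet.",
          class = "pepremc_invalid_residue")
  }
  idx
}

decode_seq <- function(idx, alphabet) {
  paste(alphabet[idx], collapse = "")
}
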