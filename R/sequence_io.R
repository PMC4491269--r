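# Peptide sequence input/output and redundancy filtering.
#
# Sequences are carried as named character vectors: names are record ids,
# elements are uppercase residue strings over the 20 standard amino acids
# plus the ambiguity codes X, B, Z and the rare translated residues U, O.
# All reported coordinates are 1-based.

.STP_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                   "X", "B", "Z", "U", "O")

#' Validate a set of peptide sequences
#'
#' Uppercases the residue strings and checks them against the accepted
#' amino-acid alphabet (20 standard residues plus X/B/Z/U/O). Ambiguity
#' codes are retained; downstream motif scanning treats them as ordinary
#' non-cysteine residues.
#'
#' @param seqs Character vector of residue strings, optionally named with
#'   record identifiers. Unnamed inputs are given ids `seq1`, `seq2`, ...
#' @return The validated, uppercased named character vector.
#' @export
validate_peptides <- function(seqs) {
  if (length(seqs) == 0L) return(stats::setNames(character(0), character(0)))
  nm <- names(seqs) %||% rep("", length(seqs))
  blank <- !nzchar(nm)
  nm[blank] <- paste0("seq", which(blank))
  seqs <- stats::setNames(vapply(seqs, as.character, character(1), USE.NAMES = FALSE), nm)
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (!nzchar(s))
      stop("record '", names(seqs)[i], "': empty sequence", call. = FALSE)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% .STP_ALPHABET))
    if (length(bad))
      stop("record '", names(seqs)[i], "': illegal residue '", chars[bad[1]],
           "' at position ", bad[1], call. = FALSE)
  }
  seqs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read peptide sequences from a FASTA file
#'
#' Accepts single-line and wrapped FASTA. Residues are uppercased and
#' validated; characters outside the accepted alphabet raise an error
#' naming the record and position.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of validated sequences (ids as names),
#'   in file order. An empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  # keep only the first whitespace-delimited token of each header, as ids
  names(seqs) <- vapply(strsplit(names(aa), "[ \t]+"), `[[`, character(1), 1L)
  validate_peptides(seqs)
}

#' Write peptide sequences to a FASTA file
#'
#' Writes 60-column wrapped FASTA; `read_fasta(write_fasta(x, f))` is the
#' identity on validated inputs.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- validate_peptides(seqs)
  if (length(seqs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

# identity of one global (Needleman-Wunsch) alignment: match 1, mismatch 0,
# linear gap -1; identity = matches / alignment length (gaps included).
.pair_identity <- function(a, b) {
  alpha <- .STP_ALPHABET
  m <- diag(1, length(alpha))
  dimnames(m) <- list(alpha, alpha)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = m,
                                       gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::pattern(aln)))
}

#' Greedy redundancy filter on global pairwise identity
#'
#' Scans sequences in input order and drops any sequence whose global
#' alignment identity (matches over alignment length, Needleman-Wunsch with
#' match 1 / mismatch 0 / linear gap -1) to an already retained sequence is
#' at or above `threshold`. This is a simple deterministic stand-in for
#' word-based clustering tools such as CD-HIT and makes no attempt to
#' reproduce their cluster definitions.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity fraction in (0, 1]; default 0.9.
#' @return The retained subset, original order preserved.
#' @export
dedup_by_identity <- function(seqs, threshold = 0.9) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  seqs <- validate_peptides(seqs)
  if (length(seqs) <= 1L) return(seqs)
  keep <- integer(0)
  for (i in seq_along(seqs)) {
    dup <- FALSE
    for (j in keep) {
      if (.pair_identity(seqs[[i]], seqs[[j]]) >= threshold) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  seqs[keep]
}
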