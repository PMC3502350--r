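#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Lowercases the input and converts thymine to uracil, so that sequences
#' taken from mixed DNA/RNA sources are comparable.  Any character outside
#' \code{a, c, g, u, t} (after lowercasing) is a validation error.
#'
#' @param raw Character scalar, the sequence to normalize.
#' @return Character scalar over the alphabet \code{{a, c, g, u}}.
#' @examples
#' normalize_rna("ACGT")              # "acgu"
#' normalize_rna("aggcgagtcatctgtgacagg")
#' @export
normalize_rna <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("sequence must be a single non-empty string")
  s <- chartr("T", "U", tolower(raw))
  s <- chartr("t", "u", s)
  bad <- regexpr("[^acgu]", s)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at position %d",
                 substr(s, bad, bad), bad))
  s
}

#' Vectorised normalization of sequences
#' @param x Character vector of sequences (names preserved).
#' @return Character vector of normalized RNA sequences.
#' @export
normalize_rna_all <- function(x) {
  out <- vapply(x, normalize_rna, character(1))
  names(out) <- names(x)
  out
}

#' Reverse complement of a normalized RNA sequence
#' @param seq Character scalar, normalized RNA.
#' @return Character scalar, the reverse complement (5'->3').
#' @export
revcomp_rna <- function(seq) {
  rc <- chartr("acgu", "ugca", seq)
  vapply(rc, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# round half away from zero, the convention used for the printed GC column
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Length and GC content of a sequence
#'
#' @param seq Normalized RNA sequence (see [normalize_rna()]).
#' @return List with \code{length} (nt) and \code{gc_percent}
#'   (percent, rounded half-away-from-zero to one decimal).
#' @examples
#' sequence_stats("ugacagaagagagugagcaca")  # 21 nt, 47.6 %
#' @export
sequence_stats <- function(seq) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  gc <- nchar(gsub("[^gc]", "", seq))
  list(length = n, gc_percent = round_half_away(100 * gc / n, 1))
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a named
#' character vector of normalized RNA sequences.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector (names = FASTA ids up to first space).
#' @export
read_fasta_rna <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  normalize_rna_all(seqs)
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param desc Optional character vector of description suffixes appended to
#'   the ids (e.g. coordinates of a planted mature).
#' @return Invisibly, \code{path}.
#' @export
write_fasta_rna <- function(seqs, path, desc = NULL) {
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
  if (!is.null(desc)) nm <- paste(nm, desc)
  x <- Biostrings::BStringSet(unname(seqs))
  names(x) <- nm
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
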