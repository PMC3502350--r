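#' Mismatch-tolerant homology scan of mature miRNAs against a transcriptome
#'
#' Exhaustive ungapped scan of every query along both strands of every
#' transcript, reporting all windows within a Hamming-distance budget.
#' For 20-24 nt queries a full scan is exact and cheap, and avoids the
#' seed/gap heuristics of alignment tools.  Coordinates are 0-based
#' half-open and always refer to the forward strand of the transcript;
#' minus-strand hits carry \code{strand == "-"} and a \code{matched_seq}
#' equal to the reverse complement of the transcript slice (i.e. the
#' query-oriented sequence).
#'
#' @param queries Named character vector of mature sequences, or a
#'   \code{mirna_catalog}.
#' @param db Named character vector of transcript sequences (normalized
#'   internally), e.g. from [read_fasta_rna()].
#' @param max_mismatch Maximum Hamming distance (default 4).
#' @param query_length_range Allowed query lengths; queries outside it are
#'   skipped with a warning, or rejected when \code{on_bad_query = "error"}.
#' @param on_bad_query \code{"warn"} (default) or \code{"error"}.
#' @return data.frame of class \code{homology_hits}: \code{query},
#'   \code{transcript}, \code{start}, \code{end}, \code{strand},
#'   \code{mismatches}, \code{matched_seq}, sorted by
#'   (transcript, start, strand).
#' @export
scan_homologs <- function(queries, db, max_mismatch = 4,
                          query_length_range = c(20, 24),
                          on_bad_query = c("warn", "error")) {
  on_bad_query <- match.arg(on_bad_query)
  if (inherits(queries, "mirna_catalog")) {
    q <- queries$sequence
    names(q) <- queries$name
    queries <- q
  }
  queries <- normalize_rna_all(queries)
  db <- normalize_rna_all(db)
  if (is.null(names(queries)) || is.null(names(db)))
    stop("queries and db must be named")
  ql <- nchar(queries)
  bad <- ql < query_length_range[1] | ql > query_length_range[2]
  if (any(bad)) {
    msg <- sprintf("%d query(ies) outside %d-%d nt skipped: %s",
                   sum(bad), query_length_range[1], query_length_range[2],
                   paste(names(queries)[bad], collapse = ", "))
    if (on_bad_query == "error") stop(msg)
    warning(msg)
    queries <- queries[!bad]
  }
  res <- vector("list", 2L * length(queries) * length(db))
  k <- 0L
  for (qi in seq_along(queries)) {
    qname <- names(queries)[qi]
    qf <- queries[[qi]]
    qr <- revcomp_rna(qf)
    m <- nchar(qf)
    for (ti in seq_along(db)) {
      subj <- db[[ti]]
      for (strand in c("+", "-")) {
        hits <- .cpp_hamming_scan(subj, if (strand == "+") qf else qr,
                                  as.integer(max_mismatch))
        if (nrow(hits)) {
          k <- k + 1L
          slice <- substring(subj, hits[, 1] + 1L, hits[, 1] + m)
          res[[k]] <- data.frame(
            query = qname, transcript = names(db)[ti],
            start = hits[, 1], end = hits[, 1] + m, strand = strand,
            mismatches = hits[, 2],
            matched_seq = if (strand == "+") slice else revcomp_rna(slice),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (k) do.call(rbind, res[seq_len(k)]) else
    data.frame(query = character(), transcript = character(),
               start = integer(), end = integer(), strand = character(),
               mismatches = integer(), matched_seq = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$transcript, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("homology_hits", "data.frame")
  out
}

#' Classify a transcript as coding or non-coding by its longest ORF
#'
#' Scans all six reading frames for AUG-initiated, stop-terminated open
#' reading frames and calls the transcript non-coding when the longest ORF
#' is below \code{min_orf_aa} amino acids (start codon included, stop
#' excluded).  This is a database-free stand-in for a protein-homology
#' check; the threshold is exposed so users can match their annotation
#' conventions.
#'
#' @param seq Transcript sequence (normalized internally).
#' @param min_orf_aa Minimum ORF length, in amino acids, for a coding call
#'   (default 100).
#' @return List: \code{non_coding} (logical), \code{longest_orf_aa}.
#' @export
coding_filter <- function(seq, min_orf_aa = 100) {
  seq <- normalize_rna(seq)
  longest <- 0L
  for (s in c(seq, revcomp_rna(seq))) {
    n <- nchar(s)
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    for (frame in 0:2) {
      idx <- seq.int(frame + 1L, n, by = 3L)
      idx <- idx[idx + 2L <= n]
      if (!length(idx)) next
      codons <- paste0(v[idx], v[idx + 1L], v[idx + 2L])
      augs <- which(codons == "aug")
      stops <- which(codons %in% c("uaa", "uag", "uga"))
      if (!length(augs) || !length(stops)) next
      nxt <- stops[findInterval(augs, stops) + 1L]
      len <- nxt - augs  # codons from AUG to the one before the stop
      len <- len[!is.na(len)]
      if (length(len) && max(len) > longest) longest <- max(len)
    }
  }
  list(non_coding = longest < min_orf_aa, longest_orf_aa = as.integer(longest))
}

#' Extract a candidate precursor window around a homology hit
#'
#' Returns the transcript subsequence extending \code{flank} nt on each
#' side of the hit, truncated at the transcript ends (and flagged when
#' truncation occurs).  For minus-strand hits the window is
#' reverse-complemented so the mature reads 5' to 3', and the reported
#' offset refers to the reverse-complemented window.
#'
#' @param seq Transcript sequence.
#' @param hit One row of a \code{homology_hits} data.frame (or any list
#'   with \code{start}, \code{end}, \code{strand}).
#' @param flank Flank size in nt on each side (default 100).
#' @return List: \code{sequence}, \code{mature_offset} (0-based within the
#'   returned window), \code{mature_length}, \code{window_start},
#'   \code{window_end} (forward-strand transcript coordinates),
#'   \code{strand}, \code{truncated}.
#' @export
extract_precursor <- function(seq, hit, flank = 100) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  s <- as.integer(hit$start); e <- as.integer(hit$end)
  if (s < 0 || e > n || s >= e) stop("hit does not lie within the transcript")
  ws <- max(0L, s - as.integer(flank))
  we <- min(n, e + as.integer(flank))
  truncated <- ws > s - flank || we < e + flank
  win <- substr(seq, ws + 1L, we)
  strand <- if (is.null(hit$strand)) "+" else hit$strand
  if (strand == "-") {
    win <- revcomp_rna(win)
    offset <- we - e
  } else {
    offset <- s - ws
  }
  list(sequence = win, mature_offset = offset, mature_length = e - s,
       window_start = ws, window_end = we, strand = strand,
       truncated = truncated)
}
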