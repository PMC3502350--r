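#' Predict miRNA target sites by complementarity
#'
#' Scans every window of every transcript (sense strand) against the
#' miRNA's reverse complement, counting Watson-Crick mismatches and G:U
#' wobbles separately.  The duplex convention is the standard
#' miRNA-antiparallel one: miRNA position p (from its 5' end) pairs the
#' transcript base at \code{end - p}.  A site is reported when
#' \code{mismatches + wobble_weight * wobbles <= max_score}.  By default a
#' wobble counts as a full mismatch (\code{wobble_weight = 1}); set 0.5 for
#' plant-rule-style scoring.
#'
#' @param mirna Mature miRNA sequence (a single named element or scalar).
#' @param db Named character vector of transcripts.
#' @param max_score Score budget (default 4).
#' @param wobble_weight Weight of a G:U wobble in the score (default 1).
#' @return data.frame of class \code{target_sites}: \code{mirna},
#'   \code{transcript}, \code{start}, \code{end} (0-based half-open),
#'   \code{mismatches}, \code{wobbles}, \code{score}, \code{duplex}
#'   (transcript site 5'->3'), sorted by (score, transcript, start).
#' @export
predict_targets <- function(mirna, db, max_score = 4, wobble_weight = 1) {
  name <- if (!is.null(names(mirna))) names(mirna)[1] else "miRNA"
  m <- normalize_rna(mirna[[1]])
  L <- nchar(m)
  if (L < 20 || L > 24) stop("miRNA must be 20-24 nt")
  db <- normalize_rna_all(db)
  res <- list(); k <- 0L
  for (ti in seq_along(db)) {
    hits <- .cpp_target_scan(db[[ti]], m, max_score, wobble_weight)
    if (nrow(hits)) {
      k <- k + 1L
      res[[k]] <- data.frame(
        mirna = name, transcript = names(db)[ti],
        start = hits[, 1], end = hits[, 1] + L,
        mismatches = hits[, 2], wobbles = hits[, 3],
        score = hits[, 2] + wobble_weight * hits[, 3],
        duplex = substring(db[[ti]], hits[, 1] + 1L, hits[, 1] + L),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (k) do.call(rbind, res) else
    data.frame(mirna = character(), transcript = character(),
               start = integer(), end = integer(), mismatches = integer(),
               wobbles = integer(), score = numeric(), duplex = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$score, out$transcript, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_sites", "data.frame")
  out
}

#' Detect TAS loci and lay out phased tasiRNA windows
#'
#' For each transcript carrying a binding site of a trigger miRNA
#' (canonically miR390 for TAS3, miR828 for TAS4) within the score budget,
#' places the cleavage position between the target nucleotides paired to
#' miRNA positions 10 and 11 (counting from the miRNA 5' end) and tiles
#' 21-nt phased windows 3' from the cleavage site.  When several sites pass
#' the budget on one transcript, the best-scoring (then leftmost) site is
#' used.
#'
#' @param db Named character vector of transcripts.
#' @param triggers Named character vector of trigger miRNA sequences, or a
#'   \code{mirna_catalog} subset.
#' @param max_score Complementarity budget passed to [predict_targets()].
#' @param wobble_weight Wobble weight passed to [predict_targets()].
#' @param phase Phase length in nt (default 21).
#' @param n_windows Number of phased windows requested (default 8); fewer
#'   full windows plus one truncated-flagged window are returned when the
#'   transcript is too short.
#' @return List of \code{tas_locus} objects: \code{transcript},
#'   \code{trigger}, \code{site} (one-row \code{target_sites}),
#'   \code{cleavage_pos}, \code{windows} (data.frame \code{start},
#'   \code{end}, \code{truncated}).
#' @export
find_tas_loci <- function(db, triggers, max_score = 4, wobble_weight = 1,
                          phase = 21, n_windows = 8) {
  if (inherits(triggers, "mirna_catalog")) {
    t <- triggers$sequence
    names(t) <- triggers$name
    triggers <- t
  }
  db <- normalize_rna_all(db)
  loci <- list()
  for (qi in seq_along(triggers)) {
    sites <- predict_targets(triggers[qi], db, max_score, wobble_weight)
    for (tr in unique(sites$transcript)) {
      st <- sites[sites$transcript == tr, , drop = FALSE]
      st <- st[order(st$score, st$start), , drop = FALSE][1, , drop = FALSE]
      cleave <- st$end - 10L  # cut between bases paired to miRNA nt 10 and 11
      tlen <- nchar(db[[tr]])
      wins <- phased_windows(cleave, tlen, phase, n_windows)
      loci[[length(loci) + 1L]] <- structure(
        list(transcript = tr, trigger = names(triggers)[qi], site = st,
             cleavage_pos = cleave, windows = wins),
        class = "tas_locus")
    }
  }
  loci
}

# tile `n_windows` windows of `phase` nt from `from`, truncating at `len`
phased_windows <- function(from, len, phase = 21, n_windows = 8) {
  starts <- from + phase * seq_len(n_windows) - phase
  starts <- starts[starts < len]
  ends <- pmin(starts + phase, len)
  data.frame(start = starts, end = ends, truncated = ends - starts < phase)
}

#' @export
print.tas_locus <- function(x, ...) {
  cat(sprintf("TAS locus on %s triggered by %s (score %g), cleavage at %d, %d window(s)\n",
              x$transcript, x$trigger, x$site$score, x$cleavage_pos,
              nrow(x$windows)))
  invisible(x)
}

#' Match candidate tasiRNAs against reference tasiRNAs
#'
#' All-versus-all ungapped Hamming comparison of equal-length sequences;
#' pairs of unequal length are skipped with a warning.
#'
#' @param windows Named character vector of candidate tasiRNA sequences.
#' @param reference Named character vector of reference tasiRNAs.
#' @param max_mismatch Maximum Hamming distance (default 4).
#' @return data.frame: \code{window}, \code{reference}, \code{distance}.
#' @export
match_conserved_tasirna <- function(windows, reference, max_mismatch = 4) {
  windows <- normalize_rna_all(windows)
  reference <- normalize_rna_all(reference)
  out <- list(); k <- 0L; skipped <- 0L
  for (wi in seq_along(windows)) for (ri in seq_along(reference)) {
    if (nchar(windows[[wi]]) != nchar(reference[[ri]])) {
      skipped <- skipped + 1L
      next
    }
    d <- hamming_distance(windows[[wi]], reference[[ri]])
    if (d <= max_mismatch) {
      k <- k + 1L
      out[[k]] <- data.frame(window = names(windows)[wi],
                             reference = names(reference)[ri],
                             distance = d, stringsAsFactors = FALSE)
    }
  }
  if (skipped)
    warning(sprintf("%d pair(s) of unequal length skipped", skipped))
  if (k) do.call(rbind, out) else
    data.frame(window = character(), reference = character(),
               distance = integer(), stringsAsFactors = FALSE)
}

#' Hamming distance between two equal-length sequences
#' @param a,b Sequences of equal length.
#' @return Integer distance.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}
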