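#' Read a mature miRNA catalog
#'
#' Loads a tab-separated catalog of mature miRNA sequences.  The packaged
#' default is the 59-entry Nicotiana attenuata set with, per entry, the
#' precursor minimum free energy (MFE, kcal/mol; \code{"-"} when the
#' precursor did not fold into a reportable stem-loop), the mature sequence,
#' the printed length and GC content, the closest miRBase homolog and its
#' E-value.  Printed length/GC are carried verbatim as metadata; the loader
#' recomputes both from the sequence and flags rows where they disagree,
#' rather than silently correcting either side.
#'
#' @param path Path to the catalog TSV; defaults to the packaged fixture.
#' @return A data.frame of class \code{mirna_catalog} with columns
#'   \code{name}, \code{family}, \code{sequence} (normalized RNA),
#'   \code{mfe} (numeric, NA when absent), \code{length_printed},
#'   \code{gc_printed}, \code{length_nt}, \code{gc_percent} (recomputed),
#'   \code{consistent} (printed == recomputed), \code{hit}, \code{evalue}.
#' @examples
#' cat59 <- read_mirna_catalog()
#' summarize_catalog(cat59)
#' @export
read_mirna_catalog <- function(path = system.file("extdata", "mature_mirnas.tsv",
                                                  package = "mirtas")) {
  x <- utils::read.delim(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("name", "mfe", "sequence", "length", "gc", "hit", "evalue")
  if (!all(need %in% names(x)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  seqs <- normalize_rna_all(x$sequence)
  stats <- lapply(seqs, sequence_stats)
  out <- data.frame(
    name           = x$name,
    family         = mirna_family(x$name),
    sequence       = unname(seqs),
    mfe            = suppressWarnings(as.numeric(ifelse(x$mfe == "-", NA, x$mfe))),
    length_printed = as.integer(x$length),
    gc_printed     = as.numeric(x$gc),
    length_nt      = vapply(stats, `[[`, integer(1), "length"),
    gc_percent     = vapply(stats, `[[`, numeric(1), "gc_percent"),
    hit            = x$hit,
    evalue         = as.numeric(x$evalue),
    stringsAsFactors = FALSE
  )
  out$consistent <- out$length_printed == out$length_nt &
    abs(out$gc_printed - out$gc_percent) < 0.05
  if (anyDuplicated(out$name)) stop("duplicate entry names in catalog")
  if (any(!is.na(out$mfe) & out$mfe >= 0))
    stop("recorded MFE values must be negative")
  class(out) <- c("mirna_catalog", "data.frame")
  out
}

#' Derive the miRNA family from an entry name
#'
#' Strips the species prefix up to \code{"miR"} and a trailing single
#' lowercase letter suffix, so \code{Nat-miR156a} and \code{Nat-miR156b}
#' both map to \code{miR156}.
#'
#' @param name Character vector of entry names.
#' @return Character vector of family names.
#' @export
mirna_family <- function(name) {
  fam <- sub("^.*?(miR[0-9]+).*$", "\\1", name)
  # keep numeric core only: trailing letter suffixes are member labels
  fam
}

#' Summarize a miRNA catalog
#'
#' Counts entries and distinct families, splits entries by presence of a
#' recorded precursor MFE, and reports MFE statistics (mean/min/max,
#' kcal/mol) over the recorded values.
#'
#' @param catalog A \code{mirna_catalog} (or compatible data.frame).
#' @return List of class \code{catalog_summary}: \code{n_entries},
#'   \code{n_families}, \code{n_folded}, \code{n_unfolded},
#'   \code{mfe_mean}, \code{mfe_min}, \code{mfe_max} (the latter three NA
#'   for an empty or MFE-free catalog).
#' @export
summarize_catalog <- function(catalog) {
  mfe <- catalog$mfe[!is.na(catalog$mfe)]
  out <- list(
    n_entries  = nrow(catalog),
    n_families = length(unique(catalog$family)),
    n_folded   = length(mfe),
    n_unfolded = sum(is.na(catalog$mfe)),
    mfe_mean   = if (length(mfe)) mean(mfe) else NA_real_,
    mfe_min    = if (length(mfe)) min(mfe) else NA_real_,
    mfe_max    = if (length(mfe)) max(mfe) else NA_real_
  )
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("miRNA catalog summary\n")
  cat(sprintf("  entries:  %d in %d families\n", x$n_entries, x$n_families))
  cat(sprintf("  with MFE: %d   without: %d\n", x$n_folded, x$n_unfolded))
  if (!is.na(x$mfe_mean))
    cat(sprintf("  MFE kcal/mol: mean %.1f, range [%.1f, %.1f]\n",
                x$mfe_mean, x$mfe_min, x$mfe_max))
  invisible(x)
}

#' Export catalog mature sequences as FASTA
#' @param catalog A \code{mirna_catalog}.
#' @param path Output FASTA path.
#' @return Invisibly, \code{path}.
#' @export
catalog_to_fasta <- function(catalog, path) {
  seqs <- catalog$sequence
  names(seqs) <- catalog$name
  write_fasta_rna(seqs, path)
}
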