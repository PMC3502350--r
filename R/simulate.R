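#' @name simulate-data
#' @title Deterministic synthetic data for pipeline testing
#' @description
#' The generators in this group emulate the inputs the discovery and
#' expression stages expect -- a transcriptome with planted miRNA
#' precursors and coding decoys, TAS-like transcripts carrying trigger
#' binding sites, qPCR Ct tables with planted response archetypes, and
#' microarray intensity matrices -- and return machine-readable ground
#' truth next to every output.  All generators are deterministic given
#' their seed.
NULL

random_rna <- function(n) {
  paste(sample(c("a", "c", "g", "u"), n, replace = TRUE), collapse = "")
}

# random sequence guaranteed free of ORFs >= min_orf_aa
random_noncoding <- function(n, min_orf_aa = 100, max_tries = 50) {
  for (i in seq_len(max_tries)) {
    s <- random_rna(n)
    if (coding_filter(s, min_orf_aa)$non_coding) return(s)
  }
  stop("could not generate an ORF-free sequence of length ", n)
}

# substitute exactly k positions, each to a different base
mutate_seq <- function(seq, k) {
  if (k == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("a", "c", "g", "u"), v[p]), 1)
  paste(v, collapse = "")
}

# hairpin precursor: [pad5 mature pad3] loop [~revcomp of the arm];
# arm mismatches are placed opposite the pads, never opposite the mature
make_precursor <- function(mature, pad5 = 12, pad3 = 10, loop_len = 8,
                           arm_mismatch = 2) {
  arm5 <- paste0(random_rna(pad5), mature, random_rna(pad3))
  al <- nchar(arm5)
  arm3 <- revcomp_rna(arm5)
  if (arm_mismatch > 0) {
    opp_mature <- al - (pad5 + seq_len(nchar(mature)) - 1L)  # 3'-arm idx, 1-based
    free <- setdiff(seq_len(al), opp_mature)
    v <- strsplit(arm3, "", fixed = TRUE)[[1]]
    for (p in sample(free, min(arm_mismatch, length(free))))
      v[p] <- sample(setdiff(c("a", "c", "g", "u"), v[p]), 1)
    arm3 <- paste(v, collapse = "")
  }
  list(sequence = paste0(arm5, random_rna(loop_len), arm3),
       mature_offset = pad5, mature_length = nchar(mature))
}

#' Generate a synthetic transcriptome with planted miRNA precursors
#'
#' Builds \code{n_transcripts} random non-coding transcripts, embeds one
#' hairpin precursor per planted mature (the mature possibly carrying a
#' fixed number of substitutions, on a random strand), and adds decoy
#' transcripts containing long AUG-initiated ORFs.  Ground truth records
#' every planted coordinate (forward-strand, 0-based half-open), strand
#' and substitution count.
#'
#' @param catalog A \code{mirna_catalog} supplying mature sequences.
#' @param planted data.frame with columns \code{name} (catalog entry) and
#'   \code{n_sub} (substitutions applied to the planted copy), one row per
#'   planted precursor.  Default: 50 entries cycled from the catalog with
#'   0-4 substitutions.
#' @param n_transcripts Total number of transcripts (default 2000).
#' @param n_coding_decoys How many transcripts carry a long ORF
#'   (default 20).
#' @param length_range Transcript length range in nt.
#' @param min_orf_aa ORF-freedom guarantee for non-decoy transcripts.
#' @param seed Integer seed.
#' @return List: \code{transcripts} (named character vector),
#'   \code{truth} (data.frame \code{transcript}, \code{query},
#'   \code{start}, \code{end}, \code{strand}, \code{n_sub}),
#'   \code{decoys} (ids of coding decoys).
#' @export
generate_transcriptome <- function(catalog, planted = NULL,
                                   n_transcripts = 2000,
                                   n_coding_decoys = 20,
                                   length_range = c(300, 1500),
                                   min_orf_aa = 100, seed = 1) {
  set.seed(seed)
  if (is.null(planted)) {
    idx <- rep_len(seq_len(nrow(catalog)), 50)
    planted <- data.frame(name = catalog$name[idx],
                          n_sub = rep_len(0:4, 50))
  }
  if (!all(planted$name %in% catalog$name))
    stop("planted mature(s) absent from catalog: ",
         paste(setdiff(planted$name, catalog$name), collapse = ", "))
  n_plain <- n_transcripts - nrow(planted) - n_coding_decoys
  if (n_plain < 0) stop("n_transcripts too small for planted + decoys")
  lens <- sample(length_range[1]:length_range[2], n_transcripts,
                 replace = TRUE)
  ids <- sprintf("NA454_%05d", seq_len(n_transcripts))
  slot <- sample(n_transcripts)  # which transcript gets which content
  planted_slot <- slot[seq_len(nrow(planted))]
  decoy_slot <- slot[nrow(planted) + seq_len(n_coding_decoys)]
  seqs <- character(n_transcripts)
  truth <- vector("list", nrow(planted))
  for (i in seq_len(n_transcripts)) {
    if (i %in% planted_slot) next   # filled below
    if (i %in% decoy_slot) {
      seqs[i] <- make_coding_decoy(lens[i], min_orf_aa)
    } else {
      seqs[i] <- random_noncoding(lens[i], min_orf_aa)
    }
  }
  for (k in seq_len(nrow(planted))) {
    i <- planted_slot[k]
    mature <- catalog$sequence[catalog$name == planted$name[k]]
    mut <- mutate_seq(mature, planted$n_sub[k])
    pre <- make_precursor(mut)
    plen <- nchar(pre$sequence)
    flank_total <- max(lens[i] - plen, 60L)
    left <- sample.int(flank_total - 20L, 1) + 10L
    right <- flank_total - left
    strand <- sample(c("+", "-"), 1)
    insert <- if (strand == "+") pre$sequence else revcomp_rna(pre$sequence)
    seqs[i] <- paste0(random_noncoding(left, min_orf_aa), insert,
                      random_noncoding(right, min_orf_aa))
    ml <- pre$mature_length
    ms <- if (strand == "+") left + pre$mature_offset
          else left + plen - pre$mature_offset - ml
    truth[[k]] <- data.frame(transcript = ids[i], query = planted$name[k],
                             start = ms, end = ms + ml, strand = strand,
                             n_sub = planted$n_sub[k],
                             stringsAsFactors = FALSE)
  }
  names(seqs) <- ids
  list(transcripts = seqs, truth = do.call(rbind, truth),
       decoys = ids[decoy_slot])
}

# transcript carrying an AUG-initiated ORF of >= min_orf_aa codons
make_coding_decoy <- function(len, min_orf_aa = 100) {
  n_codons <- min_orf_aa + 20L
  stops <- c("uaa", "uag", "uga")
  sense <- c("gcu", "gcc", "gca", "ucu", "acg", "gga", "cua", "aaa", "gau",
             "cgu", "uuc", "cac", "aua", "gug", "ccg", "caa", "aac", "ugg")
  orf <- paste0("aug", paste(sample(sense, n_codons - 1L, replace = TRUE),
                             collapse = ""), sample(stops, 1))
  pad <- max(len - nchar(orf), 20L)
  left <- sample.int(pad - 1L, 1)
  paste0(random_rna(left), orf, random_rna(pad - left))
}

#' Generate validated and corrupted precursor candidates
#'
#' Constructs \code{n_valid} precursors that the folding module itself
#' confirms as single stem-loops with the mature on one arm, and
#' \code{n_corrupt} deliberately broken candidates (scrambled 3' arm,
#' mature placed across the terminal loop, or a heavily mismatched weak
#' stem), each confirmed to fail validation.  Construction resamples
#' flanks/pads on failure (bounded retries), so the labels are guaranteed
#' under the package's own energy model.
#'
#' @param catalog A \code{mirna_catalog}.
#' @param n_valid,n_corrupt Counts of valid and corrupted candidates.
#' @param seed Integer seed.
#' @param min_paired,mfe_max Validation thresholds, as in
#'   [validate_hairpin()].
#' @return List: \code{sequences} (named character), \code{truth}
#'   (data.frame \code{id}, \code{name}, \code{valid}, \code{mode},
#'   \code{mature_offset}, \code{mature_length}).
#' @export
generate_precursor_set <- function(catalog, n_valid = 52, n_corrupt = 7,
                                   seed = 1, min_paired = 0.6,
                                   mfe_max = -15) {
  set.seed(seed)
  entries <- catalog$name[rep_len(seq_len(nrow(catalog)), n_valid + n_corrupt)]
  modes <- c(rep("valid", n_valid),
             rep_len(c("scrambled_arm", "mature_in_loop", "weak_stem"),
                     n_corrupt))
  seqs <- character(0); truth <- list()
  for (k in seq_along(entries)) {
    mature <- catalog$sequence[catalog$name == entries[k]]
    made <- NULL
    for (try in 1:40) {
      cand <- switch(modes[k],
        valid = make_precursor(mature),
        scrambled_arm = {
          p <- make_precursor(mature, arm_mismatch = 0)
          armlen <- 12 + nchar(mature) + 10
          list(sequence = paste0(substr(p$sequence, 1, armlen + 8),
                                 random_rna(armlen)),
               mature_offset = p$mature_offset,
               mature_length = p$mature_length)
        },
        mature_in_loop = {
          # strong random hairpin whose terminal loop sits inside the
          # declared mature interval
          arm <- random_rna(20)
          list(sequence = paste0(random_rna(6), arm, random_rna(8),
                                 revcomp_rna(arm), random_rna(6)),
               mature_offset = 6 + 20 - 8,
               mature_length = nchar(mature))
        },
        weak_stem = {
          # heavy substitution across the whole 3' arm, mature pairing included
          arm5 <- paste0(random_rna(12), mature, random_rna(10))
          arm3 <- mutate_seq(revcomp_rna(arm5), 30)
          list(sequence = paste0(arm5, random_rna(8), arm3),
               mature_offset = 12, mature_length = nchar(mature))
        })
      fold <- fold_mfe(cand$sequence)
      v <- validate_hairpin(fold, cand$mature_offset, cand$mature_length,
                            min_paired, mfe_max)
      want_valid <- modes[k] == "valid"
      if (v$is_stem_loop == want_valid) { made <- cand; break }
    }
    if (is.null(made))
      stop("failed to construct ", modes[k], " candidate for ", entries[k])
    id <- sprintf("pre_%02d_%s", k, entries[k])
    seqs[id] <- made$sequence
    truth[[k]] <- data.frame(id = id, name = entries[k],
                             valid = modes[k] == "valid", mode = modes[k],
                             mature_offset = made$mature_offset,
                             mature_length = made$mature_length,
                             stringsAsFactors = FALSE)
  }
  list(sequences = seqs, truth = do.call(rbind, truth))
}

#' Generate a TAS-like transcript with a planted trigger binding site
#'
#' The transcript carries the reverse complement of the trigger miRNA
#' (optionally with substitutions) at \code{site_pos}, with enough
#' downstream sequence for \code{n_phases} phased 21-nt windows after the
#' 10/11 cleavage position.
#'
#' @param trigger Named character scalar (e.g. the catalog's miR390
#'   sequence) or a catalog entry name plus \code{catalog}.
#' @param catalog Optional \code{mirna_catalog} to resolve \code{trigger}
#'   by name.
#' @param site_pos 0-based start of the binding site (default 150).
#' @param n_phases Number of phased windows to leave room for (default 8).
#' @param mismatches Substitutions applied to the planted site (default 0).
#' @param phase Phase length (default 21).
#' @param extra_3p Extra 3' tail beyond the phased region (default 30).
#' @param total_len Optional total length; an error is raised if it cannot
#'   accommodate the requested phases.
#' @param seed Integer seed.
#' @return List: \code{sequence} (named), \code{truth} (list with
#'   \code{site_start}, \code{site_end}, \code{cleavage_pos},
#'   \code{windows}).
#' @export
generate_tas <- function(trigger, catalog = NULL, site_pos = 150,
                         n_phases = 8, mismatches = 0, phase = 21,
                         extra_3p = 30, total_len = NULL, seed = 1) {
  set.seed(seed)
  if (!is.null(catalog) && is.character(trigger) &&
      trigger[1] %in% catalog$name) {
    nm <- trigger[1]
    trigger <- catalog$sequence[catalog$name == nm]
    names(trigger) <- nm
  }
  nm <- names(trigger) %||% "trigger"
  tseq <- normalize_rna(trigger[[1]])
  L <- nchar(tseq)
  site <- mutate_seq(revcomp_rna(tseq), mismatches)
  cleave <- site_pos + L - 10L
  need <- cleave + phase * n_phases + extra_3p
  if (!is.null(total_len)) {
    if (total_len < cleave + phase * n_phases)
      stop(sprintf("total_len %d too short for %d phased windows",
                   total_len, n_phases))
    need <- total_len
  }
  seq <- paste0(random_rna(site_pos), site,
                random_rna(need - site_pos - L))
  names(seq) <- paste0("TASsyn_", nm)
  wins <- phased_windows(cleave, nchar(seq), phase, n_phases)
  list(sequence = seq,
       truth = list(site_start = site_pos, site_end = site_pos + L,
                    cleavage_pos = cleave, windows = wins))
}

#' Generate a qPCR Ct table with planted response archetypes
#'
#' Reference-gene Ct values are drawn around \code{baseline_ref}; target
#' Ct values around \code{baseline_target} minus an archetype- and
#' cell-specific effect (in cycles, i.e. log2 units), plus Gaussian noise.
#' Archetypes encode the canonical herbivory-response patterns:
#' \describe{
#'   \item{wound-inducible}{up after W+W and W+OS in both genotypes
#'     (JA-independent).}
#'   \item{OS-inducible}{up after W+OS only, both genotypes
#'     (JA-independent).}
#'   \item{OS-inducible-JA-dependent}{up after W+OS in WT only.}
#'   \item{JA-suppressed}{constitutively elevated in ir-aoc under all
#'     treatments.}
#'   \item{null}{no effect.}
#' }
#'
#' @param archetypes Named character vector: gene name -> archetype.
#' @param effect Effect size in log2 units / Ct cycles (default 2, i.e.
#'   4-fold).
#' @param sd Replicate standard deviation in Ct cycles (default 0.3).
#' @param n_rep Replicates per cell (default 3).
#' @param genotypes,treatments,times Factor levels of the design.
#' @param baseline_ref,baseline_target Baseline Ct of the reference and
#'   target genes (defaults 20 and 24, keeping values in the plausible
#'   10-40 band).
#' @param reference Reference gene name (default \code{"NaEF"}).
#' @param seed Integer seed.
#' @return A \code{qpcr_table} including the reference gene rows; the
#'   archetype map is kept in \code{attr(x, "truth")}.
#' @export
generate_qpcr <- function(archetypes, effect = 2, sd = 0.3, n_rep = 3,
                          genotypes = c("WT", "ir-aoc"),
                          treatments = c("CTRL", "W+W", "W+OS"),
                          times = c("1h", "5h"),
                          baseline_ref = 20, baseline_target = 24,
                          reference = "NaEF", seed = 1) {
  known <- c("wound-inducible", "OS-inducible", "OS-inducible-JA-dependent",
             "JA-suppressed", "null")
  if (!all(archetypes %in% known))
    stop("unknown archetype(s): ",
         paste(setdiff(archetypes, known), collapse = ", "))
  set.seed(seed)
  cells <- expand.grid(genotype = genotypes, treatment = treatments,
                       time = times, replicate = seq_len(n_rep),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff <- function(arch, genotype, treatment) {
    switch(arch,
      "wound-inducible" = ifelse(treatment %in% c("W+W", "W+OS"), effect, 0),
      "OS-inducible" = ifelse(treatment == "W+OS", effect, 0),
      "OS-inducible-JA-dependent" =
        ifelse(treatment == "W+OS" & genotype == "WT", effect, 0),
      "JA-suppressed" = ifelse(genotype == "ir-aoc", effect, 0),
      "null" = 0)
  }
  ref <- data.frame(gene = reference, cells,
                    ct = baseline_ref + stats::rnorm(nrow(cells), 0, sd),
                    stringsAsFactors = FALSE)
  tgt <- do.call(rbind, lapply(names(archetypes), function(gn) {
    e <- eff(archetypes[[gn]], cells$genotype, cells$treatment)
    data.frame(gene = gn, cells,
               ct = baseline_target - e + stats::rnorm(nrow(cells), 0, sd),
               stringsAsFactors = FALSE)
  }))
  out <- as_qpcr_table(rbind(ref, tgt))
  attr(out, "truth") <- archetypes
  out
}

# expected classification labels for a generator archetype
archetype_labels <- function(arch) {
  switch(arch,
    "wound-inducible" = c(induction = "wound-inducible", ja = "JA-independent"),
    "OS-inducible" = c(induction = "OS-inducible", ja = "JA-independent"),
    "OS-inducible-JA-dependent" = c(induction = "OS-inducible",
                                    ja = "JA-dependent"),
    "JA-suppressed" = c(induction = "not-induced", ja = "JA-suppressed"),
    "null" = c(induction = "not-induced", ja = "undetermined"),
    stop("unknown archetype: ", arch))
}

#' Generate a microarray intensity matrix with planted fold changes
#'
#' Log-normal intensities with per-sample scale factors (so percentile
#' normalization is actually exercised); the first \code{n_de} genes are
#' shifted by \code{log2(fold)} in the treatment group.
#'
#' @param n_genes Number of genes (default 100).
#' @param n_de Number of differentially expressed genes (default 10).
#' @param fold True fold change of the DE genes (default 4).
#' @param n_rep Arrays per group (default 3).
#' @param groups Group labels (default CTRL and W+OS).
#' @param base_log2 Mean baseline log2 intensity.
#' @param noise_sd Per-measurement log2 noise sd.
#' @param scale_range Range of per-sample linear scale factors.
#' @param seed Integer seed.
#' @return List: \code{intensities} (genes x samples, positive),
#'   \code{factors} (data.frame \code{sample}, \code{group}),
#'   \code{truth} (character vector of DE gene names).
#' @export
generate_microarray <- function(n_genes = 100, n_de = 10, fold = 4,
                                n_rep = 3, groups = c("CTRL", "W+OS"),
                                base_log2 = 8, noise_sd = 0.25,
                                scale_range = c(0.5, 2), seed = 1) {
  if (n_de > 0 && fold <= 1) stop("fold must exceed 1 for planted DE genes")
  set.seed(seed)
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  samples <- paste(rep(groups, each = n_rep), seq_len(n_rep), sep = "_")
  grp <- rep(groups, each = n_rep)
  mu <- stats::rnorm(n_genes, base_log2, 1)
  de <- genes[seq_len(n_de)]
  lmat <- sapply(seq_along(samples), function(s) {
    shift <- ifelse(genes %in% de & grp[s] == groups[2], log2(fold), 0)
    mu + shift + stats::rnorm(n_genes, 0, noise_sd)
  })
  scl <- stats::runif(length(samples), scale_range[1], scale_range[2])
  m <- sweep(2^lmat, 2, scl, "*")
  dimnames(m) <- list(genes, samples)
  list(intensities = m,
       factors = data.frame(sample = samples, group = grp,
                            stringsAsFactors = FALSE),
       truth = de)
}
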