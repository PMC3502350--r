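#' Classify the treatment response of a small RNA at one timepoint
#'
#' Decides between OS-inducible, wound-inducible and not-induced from
#' per-replicate log2 relative quantities across the three treatments
#' (CTRL, W+W, W+OS), using [anova_plsd()].  Following common microarray
#' practice (and to keep single noisy replicates from flipping calls), a
#' difference between two treatments counts only when it is both
#' significant in the protected LSD test and larger than
#' \code{log2(min_fold)} in magnitude:
#' \itemize{
#'   \item OS-inducible: W+OS above both CTRL and W+W;
#'   \item wound-inducible: W+W and W+OS both above CTRL, W+W and W+OS
#'     not different from each other;
#'   \item otherwise not-induced.
#' }
#'
#' @param log2_rq Numeric vector of per-replicate log2 relative quantities.
#' @param treatment Vector of treatments, must contain CTRL, W+W and W+OS.
#' @param alpha Significance level (default 0.05).
#' @param min_fold Minimum fold change for a difference to count
#'   (default 2).
#' @return List of class \code{induction_call}: \code{class} (one of
#'   \code{"OS-inducible"}, \code{"wound-inducible"},
#'   \code{"not-induced"}), \code{plsd} (the fitted [anova_plsd()] object),
#'   \code{letters}.
#' @export
classify_induction <- function(log2_rq, treatment, alpha = 0.05,
                               min_fold = 2) {
  treatment <- as.character(treatment)
  need <- c("CTRL", "W+W", "W+OS")
  if (!all(need %in% treatment))
    stop("missing treatment(s): ",
         paste(setdiff(need, unique(treatment)), collapse = ", "))
  fit <- anova_plsd(log2_rq, treatment, alpha)
  up <- function(a, b) pair_diff(fit, a, b, alpha, min_fold) > 0
  differs <- function(a, b) pair_diff(fit, a, b, alpha, min_fold) != 0
  cls <- if (up("W+OS", "CTRL") && up("W+OS", "W+W")) {
    "OS-inducible"
  } else if (up("W+W", "CTRL") && up("W+OS", "CTRL") &&
             !differs("W+W", "W+OS")) {
    "wound-inducible"
  } else "not-induced"
  structure(list(class = cls, plsd = fit, letters = fit$letters),
            class = "induction_call")
}

# signed call for group a vs b: +1 (a above b), -1, or 0 (no difference);
# a difference requires protected-LSD significance AND |diff| > log2(min_fold)
pair_diff <- function(fit, a, b, alpha, min_fold) {
  pw <- fit$pairwise
  row <- which((pw$g1 == a & pw$g2 == b) | (pw$g1 == b & pw$g2 == a))
  if (!length(row)) stop("no such pair: ", a, " vs ", b)
  d <- if (pw$g1[row] == a) pw$diff[row] else -pw$diff[row]
  p <- pw$p[row]
  if (is.na(p) || p >= alpha || abs(d) <= log2(min_fold)) return(0)
  sign(d)
}

#' Classify the jasmonate dependence of a small RNA at one timepoint
#'
#' Compares WT and the JA-deficient genotype (ir-aoc):
#' \itemize{
#'   \item JA-dependent: induced in WT but not in ir-aoc;
#'   \item JA-independent: induced in both genotypes with no WT vs ir-aoc
#'     difference within any treatment;
#'   \item JA-suppressed: constitutively elevated in ir-aoc (ir-aoc above
#'     WT in CTRL), i.e. negatively regulated by jasmonates;
#'   \item undetermined otherwise.
#' }
#' Rules are evaluated in the order dependent, independent, suppressed.
#' Genotype differences use two-group [anova_plsd()] per treatment with
#' the same significance-plus-magnitude criterion as
#' [classify_induction()].  Quantities must share a single calibrator
#' (e.g. WT CTRL) so cross-genotype comparisons are meaningful.
#'
#' @param log2_rq Per-replicate log2 relative quantities for both genotypes.
#' @param genotype Vector over \code{{"WT", "ir-aoc"}}.
#' @param treatment Vector of treatments (CTRL, W+W, W+OS).
#' @param alpha,min_fold As in [classify_induction()].
#' @return List of class \code{ja_call}: \code{class} (one of
#'   \code{"JA-dependent"}, \code{"JA-independent"},
#'   \code{"JA-suppressed"}, \code{"undetermined"}), \code{induction}
#'   (per-genotype [classify_induction()] calls), \code{genotype_diff}
#'   (named vector of signed per-treatment calls, +1 = ir-aoc above WT).
#' @export
classify_ja <- function(log2_rq, genotype, treatment, alpha = 0.05,
                        min_fold = 2) {
  genotype <- as.character(genotype)
  if (!all(c("WT", "ir-aoc") %in% genotype))
    stop("missing genotype(s): ",
         paste(setdiff(c("WT", "ir-aoc"), unique(genotype)), collapse = ", "))
  ind <- lapply(c(WT = "WT", `ir-aoc` = "ir-aoc"), function(gt) {
    sel <- genotype == gt
    classify_induction(log2_rq[sel], treatment[sel], alpha, min_fold)
  })
  gdiff <- vapply(sort(unique(treatment)), function(tr) {
    sel <- treatment == tr
    fit <- anova_plsd(log2_rq[sel], genotype[sel], alpha)
    pair_diff(fit, "ir-aoc", "WT", alpha, min_fold)
  }, numeric(1))
  induced <- vapply(ind, function(x) x$class != "not-induced", logical(1))
  cls <- if (induced[["WT"]] && !induced[["ir-aoc"]]) {
    "JA-dependent"
  } else if (induced[["WT"]] && induced[["ir-aoc"]] && all(gdiff == 0)) {
    "JA-independent"
  } else if (gdiff[["CTRL"]] > 0) {
    "JA-suppressed"
  } else "undetermined"
  structure(list(class = cls, induction = ind, genotype_diff = gdiff),
            class = "ja_call")
}

#' Classify all genes of a qPCR experiment
#'
#' Runs [relative_quantity()], [classify_induction()] (per genotype) and,
#' when both genotypes are present, [classify_ja()] for every gene at
#' every timepoint.  Timepoints are then combined the way the response
#' patterns are read in practice: a small RNA counts as inducible when it
#' is inducible at either timepoint (OS-specificity taking precedence over
#' plain wounding), per genotype.  The combined jasmonate label is derived
#' from the combined per-genotype induction calls together with WT vs
#' ir-aoc tests per treatment that pool replicates across timepoints
#' (the archetype contrasts are constant over time, so pooling doubles the
#' error degrees of freedom and stabilizes the equivalence side of the
#' call).
#'
#' @param qpcr A \code{qpcr_table}.
#' @param genes Genes to classify (default: all except the reference).
#' @param reference Reference gene (default \code{"NaEF"}).
#' @param alpha,min_fold As in [classify_induction()].
#' @return data.frame of class \code{smrna_classification}: one row per
#'   gene with per-timepoint and combined \code{induction_class} and
#'   \code{ja_class}.  Per-gene call objects (with test statistics and
#'   letters) are kept in \code{attr(x, "calls")}.
#' @export
classify_responses <- function(qpcr, genes = NULL, reference = "NaEF",
                               alpha = 0.05, min_fold = 2) {
  if (is.null(genes)) genes <- setdiff(unique(qpcr$gene), reference)
  times <- sort(unique(as.character(qpcr$time)))
  both_geno <- all(c("WT", "ir-aoc") %in% qpcr$genotype)
  calls <- list()
  rows <- lapply(genes, function(gn) {
    rq <- relative_quantity(qpcr, gn, reference)
    rep_tab <- rq$replicate
    per_time <- lapply(times, function(tm) {
      tt <- rep_tab[rep_tab$time == tm, , drop = FALSE]
      wt <- tt[tt$genotype == "WT", , drop = FALSE]
      ic <- classify_induction(wt$log2_rq, wt$treatment, alpha, min_fold)
      jc <- if (both_geno)
        classify_ja(tt$log2_rq, tt$genotype, tt$treatment, alpha, min_fold)
      else NULL
      list(induction = ic, ja = jc)
    })
    names(per_time) <- times
    calls[[gn]] <<- per_time
    icls <- vapply(per_time, function(x) x$induction$class, character(1))
    jcls <- if (both_geno)
      vapply(per_time, function(x) x$ja$class, character(1)) else NULL
    out <- data.frame(gene = gn, stringsAsFactors = FALSE)
    for (i in seq_along(times)) {
      out[[paste0("induction_", times[i])]] <- icls[i]
      if (both_geno) out[[paste0("ja_", times[i])]] <- jcls[i]
    }
    out$induction_class <- combine_induction(icls)
    if (both_geno) {
      aoc_cls <- vapply(per_time, function(x)
        x$ja$induction[["ir-aoc"]]$class, character(1))
      out$ja_class <- combine_ja_pooled(
        wt_induced = out$induction_class != "not-induced",
        aoc_induced = combine_induction(aoc_cls) != "not-induced",
        rep_tab = rep_tab, alpha = alpha, min_fold = min_fold)
    }
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "calls") <- calls
  class(res) <- c("smrna_classification", "data.frame")
  res
}

# inducible at either timepoint; OS-specificity wins over plain wounding
combine_induction <- function(x) {
  if ("OS-inducible" %in% x) "OS-inducible"
  else if ("wound-inducible" %in% x) "wound-inducible"
  else "not-induced"
}

combine_ja <- function(x) {
  inf <- setdiff(unique(x), "undetermined")
  if (length(inf) == 1) inf else "undetermined"
}

# gene-level JA label from combined induction flags plus WT vs ir-aoc
# contrasts per treatment with replicates pooled over timepoints
combine_ja_pooled <- function(wt_induced, aoc_induced, rep_tab, alpha,
                              min_fold) {
  gdiff <- vapply(sort(unique(rep_tab$treatment)), function(tr) {
    sel <- rep_tab$treatment == tr
    fit <- anova_plsd(rep_tab$log2_rq[sel], rep_tab$genotype[sel], alpha)
    pair_diff(fit, "ir-aoc", "WT", alpha, min_fold)
  }, numeric(1))
  if (wt_induced && !aoc_induced) {
    "JA-dependent"
  } else if (wt_induced && aoc_induced && all(gdiff == 0)) {
    "JA-independent"
  } else if (gdiff[["CTRL"]] > 0) {
    "JA-suppressed"
  } else "undetermined"
}
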