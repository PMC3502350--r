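#' Predict the minimum-free-energy secondary structure of an RNA
#'
#' Folds a single sequence under the packaged reduced nearest-neighbor
#' model (see [rna_energy_params()]) with a Zuker-style dynamic program:
#' nested structures only, Watson-Crick and G:U pairs, minimum hairpin loop
#' of 3 nt, interior loops bounded at 30 unpaired nt, affine multiloops.
#' Ties among co-optimal structures are broken deterministically (paired
#' over unpaired at the leftmost undecided position, then smallest partner).
#'
#' Because the model omits dangles, coaxial stacking and sequence-specific
#' loop bonuses, absolute energies are not comparable to full Turner-model
#' folders; catalog MFE values are metadata, not folding targets.
#'
#' @param seq RNA sequence (normalized internally).
#' @param params Energy parameter list, default [rna_energy_params()].
#' @param min_len,max_len Allowed sequence length range.
#' @return Object of class \code{fold_result}: \code{sequence},
#'   \code{structure} (dot-bracket), \code{mfe} (kcal/mol, <= 0, 0 iff no
#'   pairs), \code{pairs} (two-column 0-based matrix of paired positions).
#' @examples
#' fold_mfe("ggggcaaaagcccc")
#' @export
fold_mfe <- function(seq, params = rna_energy_params(),
                     min_len = 10, max_len = 1000) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (n < min_len || n > max_len)
    stop(sprintf("sequence length %d outside [%d, %d]", n, min_len, max_len))
  res <- .cpp_fold_mfe(seq, params$stack, params$hairpin, params$bulge,
                       params$internal, params$asym_coef, params$asym_max,
                       params$ml_a, params$ml_b, params$ml_c,
                       params$max_interior, params$min_hairpin)
  out <- list(sequence = seq, structure = res$structure,
              mfe = res$mfe, pairs = res$pairs)
  class(out) <- "fold_result"
  out
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", sep = "")
  cat(sprintf("%s (%.2f)\n", x$structure, x$mfe))
  invisible(x)
}

# partner vector (0-based positions -> 0-based partner or NA) from a pairs matrix
pair_partner <- function(pairs, n) {
  p <- rep(NA_integer_, n)
  if (nrow(pairs)) {
    p[pairs[, 1] + 1L] <- pairs[, 2]
    p[pairs[, 2] + 1L] <- pairs[, 1]
  }
  p
}

# closing pairs of hairpin loops: pairs with no other pair strictly inside
hairpin_loops <- function(pairs) {
  if (!nrow(pairs)) return(pairs[0, , drop = FALSE])
  inner <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    !any(pairs[, 1] > i & pairs[, 2] < j)
  }, logical(1))
  pairs[inner, , drop = FALSE]
}

#' Validate a folded precursor as a miRNA-style stem-loop
#'
#' A candidate passes when (i) the branch of the structure enclosing the
#' mature contains exactly one hairpin loop, (ii) the mature lies entirely
#' on one arm of that hairpin without overlapping the terminal loop,
#' (iii) at least \code{min_paired} of the mature's nucleotides are paired,
#' and (iv) the fold is stable, \code{mfe <= mfe_max}.  The first failing
#' criterion is reported.  Extra hairpins formed by flanking sequence
#' outside the mature's own stem-loop unit do not disqualify a candidate.
#'
#' @param fold A \code{fold_result} from [fold_mfe()].
#' @param mature_start 0-based offset of the mature within the sequence.
#' @param mature_len Mature length (nt).
#' @param min_paired Minimum fraction of mature nucleotides paired
#'   (default 0.6).
#' @param mfe_max Stability threshold in kcal/mol (default -15).
#' @return List of class \code{hairpin_validation}: \code{is_stem_loop},
#'   \code{reason} (\code{"ok"} or the first failure), \code{arm}
#'   (\code{"5p"}, \code{"3p"} or \code{"none"}),
#'   \code{mature_paired_fraction}, \code{loop_span} (0-based closing pair
#'   of the terminal loop, NA if undefined), \code{n_hairpin_loops} (in the
#'   mature's unit), \code{mfe}, and the thresholds used.
#' @export
validate_hairpin <- function(fold, mature_start, mature_len,
                             min_paired = 0.6, mfe_max = -15) {
  n <- nchar(fold$sequence)
  ms <- as.integer(mature_start); me <- ms + as.integer(mature_len)  # [ms, me)
  if (ms < 0 || me > n || mature_len <= 0)
    stop("mature interval out of range")
  pairs <- fold$pairs
  partner <- pair_partner(pairs, n)
  paired_frac <- mean(!is.na(partner[(ms + 1L):me]))

  fail <- function(reason, arm = "none", loop = c(NA_integer_, NA_integer_),
                   nh = NA_integer_) {
    structure(list(is_stem_loop = FALSE, reason = reason, arm = arm,
                   mature_paired_fraction = paired_frac, loop_span = loop,
                   n_hairpin_loops = nh, mfe = fold$mfe,
                   min_paired = min_paired, mfe_max = mfe_max),
              class = "hairpin_validation")
  }

  # outermost pair enclosing the mature defines its stem-loop unit
  if (nrow(pairs) == 0L) return(fail("not a single stem-loop", nh = 0L))
  enc <- pairs[pairs[, 1] <= ms & pairs[, 2] >= me - 1L, , drop = FALSE]
  unit <- if (nrow(enc)) {
    enc[which.min(enc[, 1]), ]
  } else {
    # mature not enclosed: take the unit as the whole structure only if the
    # mature touches a stem at all
    if (all(is.na(partner[(ms + 1L):me]))) return(fail("mature unpaired"))
    c(min(pairs[, 1]), max(pairs[, 2]))
  }
  in_unit <- pairs[, 1] >= unit[1] & pairs[, 2] <= unit[2]
  hp <- hairpin_loops(pairs[in_unit, , drop = FALSE])
  nh <- nrow(hp)
  if (nh != 1L) return(fail("not a single stem-loop", nh = nh))
  hi <- hp[1, 1]; hj <- hp[1, 2]
  loop <- c(hi, hj)
  # terminal loop is the unpaired run (hi, hj) exclusive
  overlaps_loop <- ms <= hj - 1L && me - 1L >= hi + 1L
  if (overlaps_loop) return(fail("mature overlaps loop", loop = loop, nh = nh))
  arm <- if (me - 1L <= hi) "5p" else "3p"
  if (paired_frac < min_paired)
    return(fail("mature insufficiently paired", arm = arm, loop = loop, nh = nh))
  if (fold$mfe > mfe_max)
    return(fail("not stable", arm = arm, loop = loop, nh = nh))
  structure(list(is_stem_loop = TRUE, reason = "ok", arm = arm,
                 mature_paired_fraction = paired_frac, loop_span = loop,
                 n_hairpin_loops = nh, mfe = fold$mfe,
                 min_paired = min_paired, mfe_max = mfe_max),
            class = "hairpin_validation")
}

#' @export
print.hairpin_validation <- function(x, ...) {
  cat(sprintf("stem-loop: %s (%s); arm %s, %.0f%% of mature paired, mfe %.2f\n",
              if (x$is_stem_loop) "yes" else "no", x$reason, x$arm,
              100 * x$mature_paired_fraction, x$mfe))
  invisible(x)
}

#' Write fold results in Vienna format
#'
#' One record per fold: a \code{>id} header, the sequence, and the
#' dot-bracket line with the energy in parentheses.
#'
#' @param folds A \code{fold_result} or list of them.
#' @param path Output path.
#' @param ids Record ids (default \code{seq1, seq2, ...}).
#' @return Invisibly, \code{path}.
#' @export
write_vienna <- function(folds, path, ids = NULL) {
  if (inherits(folds, "fold_result")) folds <- list(folds)
  if (is.null(ids)) ids <- paste0("seq", seq_along(folds))
  lines <- unlist(lapply(seq_along(folds), function(k) {
    f <- folds[[k]]
    c(paste0(">", ids[k]), f$sequence,
      sprintf("%s (%.2f)", f$structure, f$mfe))
  }))
  writeLines(lines, path)
  invisible(path)
}
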