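#' One-way ANOVA with Fisher's protected LSD and compact letters
#'
#' Fits a one-way ANOVA by the pooled sums-of-squares decomposition, then
#' performs Fisher's protected least-significant-difference test: pairwise
#' two-sided t tests using the pooled within-group variance (error df),
#' carried out only when the omnibus F test is significant at \code{alpha}.
#' Groups are annotated with a compact letter display (insert-and-absorb on
#' groups sorted by descending mean; letter symbols assigned in ascending
#' order of group mean, so the lowest group reads "a").
#'
#' @param values Numeric vector of measurements.
#' @param groups Factor (or coercible) of group membership, >= 2 levels
#'   with >= 2 replicates each.
#' @param alpha Significance level (default 0.05).
#' @return Object of class \code{plsd}: \code{F}, \code{df1}, \code{df2},
#'   \code{p}, \code{protected} (was the omnibus significant),
#'   \code{means} (named group means), \code{n} (group sizes),
#'   \code{mse}, \code{pairwise} (data.frame \code{g1}, \code{g2},
#'   \code{diff}, \code{t}, \code{p}; p is NA when the omnibus was not
#'   significant), \code{letters} (named character), \code{alpha}.
#' @examples
#' anova_plsd(c(1, 1.1, 0.9, 5, 5.2, 4.9), rep(c("ctrl", "trt"), each = 3))
#' @export
anova_plsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  n <- tapply(values, groups, length)
  if (any(n < 2)) stop("every group needs at least 2 replicates: ",
                       paste(names(n)[n < 2], collapse = ", "))
  means <- tapply(values, groups, mean)
  N <- length(values)
  ssb <- sum(n * (means - mean(values))^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1; df2 <- N - k
  mse <- ssw / df2
  F <- if (mse > 0) (ssb / df1) / mse else if (ssb > 0) Inf else 0
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  protected <- is.finite(p) && p < alpha || (is.infinite(F))
  cmb <- utils::combn(levels(groups), 2)
  pw <- data.frame(g1 = cmb[1, ], g2 = cmb[2, ],
                   diff = means[cmb[1, ]] - means[cmb[2, ]],
                   t = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  rownames(pw) <- NULL
  if (protected) {
    se <- sqrt(mse * (1 / n[cmb[1, ]] + 1 / n[cmb[2, ]]))
    pw$t <- ifelse(se > 0, pw$diff / se, ifelse(pw$diff == 0, 0, Inf * sign(pw$diff)))
    pw$p <- 2 * stats::pt(abs(pw$t), df2, lower.tail = FALSE)
  }
  letters <- cld_letters(means, pw, alpha, protected)
  structure(list(F = F, df1 = df1, df2 = df2, p = p, protected = protected,
                 means = means, n = n, mse = mse, pairwise = pw,
                 letters = letters, alpha = alpha),
            class = "plsd")
}

# compact letter display: insert-and-absorb over groups in descending mean
# order; letter symbols follow ascending group means
cld_letters <- function(means, pw, alpha, protected) {
  gs <- names(means)
  sig <- function(a, b) {
    if (!protected) return(FALSE)
    row <- (pw$g1 == a & pw$g2 == b) | (pw$g1 == b & pw$g2 == a)
    any(!is.na(pw$p[row]) & pw$p[row] < alpha)
  }
  ord <- gs[order(-unlist(means))]
  sets <- list()
  for (g in ord) {
    placed <- FALSE
    for (si in seq_along(sets)) {
      if (all(!vapply(sets[[si]], sig, logical(1), b = g))) {
        sets[[si]] <- c(sets[[si]], g)
        placed <- TRUE
      }
    }
    if (!placed) {
      newset <- g
      for (h in setdiff(ord, g)) {
        if (!sig(h, g) && all(!vapply(newset, sig, logical(1), b = h)))
          newset <- c(newset, h)
      }
      sets[[length(sets) + 1L]] <- newset
    }
  }
  # drop sets fully contained in another (can arise from absorption)
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
        length(sets[[i]]) < length(sets[[j]])) keep[i] <- FALSE
  }
  sets <- sets[keep]
  setmin <- vapply(sets, function(s) min(unlist(means[s])), numeric(1))
  sets <- sets[order(setmin)]
  lett <- vapply(gs, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  names(lett) <- gs
  lett
}

#' @export
print.plsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g%s\n",
              x$df1, x$df2, x$F, x$p,
              if (x$protected) "" else " (pairwise PLSD not performed)"))
  tab <- data.frame(mean = round(unlist(x$means), 4), n = as.integer(x$n),
                    letters = x$letters)
  print(tab)
  invisible(x)
}

#' Read a long-format qPCR Ct table
#'
#' @param path TSV with columns \code{gene}, \code{genotype},
#'   \code{treatment}, \code{time}, \code{replicate}, \code{ct}.
#' @return data.frame of class \code{qpcr_table}.
#' @export
read_qpcr <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_qpcr_table(x)
}

#' Validate and class a data.frame as a qPCR table
#' @param x data.frame with columns \code{gene}, \code{genotype},
#'   \code{treatment}, \code{time}, \code{replicate}, \code{ct}.
#' @return The validated data.frame, classed \code{qpcr_table}.
#' @export
as_qpcr_table <- function(x) {
  need <- c("gene", "genotype", "treatment", "time", "replicate", "ct")
  if (!all(need %in% names(x)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(x$ct))) stop("all Ct values must be finite")
  class(x) <- c("qpcr_table", "data.frame")
  x
}

#' Relative quantification by the 2^-ddCt method
#'
#' For each condition (genotype x treatment x time), dCt is the mean Ct of
#' the gene minus the mean Ct of the reference gene; ddCt subtracts the
#' calibrator condition's dCt; the relative quantity is 2^-ddCt, so
#' induction yields values above 1.  Per-replicate quantities (replicates
#' paired with the reference by index) are also returned for downstream
#' ANOVA, on the log2 scale.
#'
#' @param qpcr A \code{qpcr_table}.
#' @param gene Gene to quantify.
#' @param reference Reference (housekeeping) gene, default \code{"NaEF"}.
#' @param calibrator Named list or vector giving the calibrator condition,
#'   default \code{c(genotype = "WT", treatment = "CTRL")} with the
#'   alphabetically first time.
#' @return List of class \code{rq_table}: \code{condition} (data.frame
#'   \code{genotype}, \code{treatment}, \code{time}, \code{dct},
#'   \code{ddct}, \code{rq}) and \code{replicate} (adds \code{replicate},
#'   \code{log2_rq}).
#' @export
relative_quantity <- function(qpcr, gene, reference = "NaEF",
                              calibrator = NULL) {
  g <- qpcr[qpcr$gene == gene, , drop = FALSE]
  r <- qpcr[qpcr$gene == reference, , drop = FALSE]
  if (!nrow(g)) stop("gene not present: ", gene)
  if (!nrow(r)) stop("reference gene not present: ", reference)
  cells <- unique(g[, c("genotype", "treatment", "time")])
  cells <- cells[order(cells$genotype, cells$treatment, cells$time), ]
  if (is.null(calibrator))
    calibrator <- c(genotype = "WT", treatment = "CTRL",
                    time = sort(unique(as.character(cells$time)))[1])
  calibrator <- as.list(calibrator)
  if (is.null(calibrator$time))
    calibrator$time <- sort(unique(as.character(cells$time)))[1]

  cell_dct <- function(gt, tr, tm) {
    gg <- g[g$genotype == gt & g$treatment == tr & g$time == tm, ]
    rr <- r[r$genotype == gt & r$treatment == tr & r$time == tm, ]
    if (!nrow(rr))
      stop(sprintf("reference '%s' missing in cell (%s, %s, %s)",
                   reference, gt, tr, tm))
    rr <- rr[match(gg$replicate, rr$replicate), ]
    if (any(is.na(rr$ct)))
      stop(sprintf("reference '%s' missing replicate(s) in cell (%s, %s, %s)",
                   reference, gt, tr, tm))
    list(dct = mean(gg$ct) - mean(rr$ct),
         rep = data.frame(replicate = gg$replicate, dct = gg$ct - rr$ct))
  }
  per <- Map(cell_dct, cells$genotype, cells$treatment, cells$time)
  dct <- vapply(per, `[[`, numeric(1), "dct")
  cal <- cell_dct(calibrator$genotype, calibrator$treatment, calibrator$time)
  ddct <- dct - cal$dct
  cond <- data.frame(cells, dct = dct, ddct = ddct, rq = 2^(-ddct),
                     row.names = NULL)
  rep_tab <- do.call(rbind, lapply(seq_along(per), function(i) {
    data.frame(cells[i, , drop = FALSE], per[[i]]$rep, row.names = NULL)
  }))
  rep_tab$ddct <- rep_tab$dct - cal$dct
  rep_tab$log2_rq <- -rep_tab$ddct
  structure(list(gene = gene, reference = reference,
                 calibrator = calibrator, condition = cond,
                 replicate = rep_tab),
            class = "rq_table")
}

#' 75th-percentile normalization of an intensity matrix
#'
#' Divides each sample (column) by its 75th percentile (linear
#' interpolation, R quantile type 7) and log2-transforms.  Rescaling a
#' sample by any positive constant therefore leaves its normalized column
#' unchanged.
#'
#' @param m Numeric matrix, genes x samples, strictly positive.
#' @return The normalized log2 matrix.
#' @export
normalize_array <- function(m) {
  m <- as.matrix(m)
  bad <- which(!(m > 0), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("nonpositive intensity at gene %s, sample %s",
                 rownames(m)[bad[1, 1]] %||% bad[1, 1],
                 colnames(m)[bad[1, 2]] %||% bad[1, 2]))
  p75 <- apply(m, 2, stats::quantile, probs = 0.75, type = 7)
  log2(sweep(m, 2, p75, "/"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fold-change screen with protected LSD confirmation
#'
#' Passes genes whose absolute mean log2 difference between the two sides
#' of the contrast is strictly greater than \code{log2(min_fold)}, then
#' tests the passing genes with [anova_plsd()] across the contrast groups.
#'
#' @param normalized Log2 intensity matrix (see [normalize_array()]).
#' @param contrast List of two character vectors of column names (the two
#'   sample groups to compare).
#' @param min_fold Fold-change threshold (default 2).
#' @param alpha Significance level for the confirmation test.
#' @return data.frame: \code{gene}, \code{log2fc}, \code{pass_screen},
#'   \code{F}, \code{p}, \code{significant}.
#' @export
fold_change_screen <- function(normalized, contrast, min_fold = 2,
                               alpha = 0.05) {
  a <- normalized[, contrast[[1]], drop = FALSE]
  b <- normalized[, contrast[[2]], drop = FALSE]
  lfc <- rowMeans(b) - rowMeans(a)
  pass <- abs(lfc) > log2(min_fold)
  Fv <- pv <- rep(NA_real_, nrow(normalized))
  for (i in which(pass)) {
    fit <- anova_plsd(c(a[i, ], b[i, ]),
                      rep(c("A", "B"), c(ncol(a), ncol(b))), alpha)
    Fv[i] <- fit$F; pv[i] <- fit$p
  }
  data.frame(gene = rownames(normalized) %||% seq_len(nrow(normalized)),
             log2fc = lfc, pass_screen = pass, F = Fv, p = pv,
             significant = pass & !is.na(pv) & pv < alpha,
             row.names = NULL)
}
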