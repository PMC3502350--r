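#' Pairwise distances from a multiple alignment
#'
#' Computes p-distances (mismatches per valid site) or Jukes-Cantor
#' distances between all pairs of aligned sequences.  Columns containing a
#' gap or ambiguity in either member of a pair are excluded pairwise.
#'
#' @param aln Named character vector of equal-length aligned sequences, or
#'   a character matrix (rows = taxa).
#' @param model \code{"p"} (default) or \code{"jc"} for the Jukes-Cantor
#'   correction \code{-(3/4) log(1 - (4/3) p)}.
#' @return Symmetric numeric matrix with taxa as dimnames,
#'   substitutions/site.
#' @export
p_distance <- function(aln, model = c("p", "jc")) {
  model <- match.arg(model)
  m <- alignment_matrix(aln)
  if (nrow(m) < 2) stop("need at least 2 taxa")
  ok <- matrix(m %in% c("a", "c", "g", "u"), nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    valid <- ok[i, ] & ok[j, ]
    if (!any(valid))
      stop(sprintf("no valid sites shared by '%s' and '%s'",
                   rownames(m)[i], rownames(m)[j]))
    p <- mean(m[i, valid] != m[j, valid])
    if (model == "jc") {
      if (p >= 0.75)
        stop(sprintf("saturated pair '%s'/'%s': p = %.3f",
                     rownames(m)[i], rownames(m)[j], p))
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

alignment_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is.null(names(aln))) names(aln) <- paste0("t", seq_along(aln))
  L <- unique(nchar(aln))
  if (length(L) != 1) stop("aligned sequences must have equal length")
  aln <- chartr("T", "U", tolower(aln))
  aln <- chartr("t", "u", aln)
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining (Saitou-Nei Q criterion with the standard
#' branch-length formulas).  Ties in Q are broken deterministically by the
#' lexicographic order of the joined pair's representative taxon names.
#' Negative branch lengths are clamped to zero; the pre-clamp values are
#' retained in \code{attr(tree, "edge.length.raw")} (aligned with
#' \code{tree$edge}).
#'
#' @param D Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted \code{ape::phylo} tree.
#' @export
neighbor_joining <- function(D) {
  taxa <- rownames(D)
  if (is.null(taxa)) taxa <- colnames(D)
  if (is.null(taxa)) stop("distance matrix must carry taxon names")
  n <- length(taxa)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(D < 0) || any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0))
    stop("distance matrix must be symmetric and nonnegative with zero diagonal")
  d <- unname(as.matrix(D))
  lab <- taxa           # newick fragment per active cluster (clamped)
  lab_raw <- taxa       # same with raw (possibly negative) lengths
  rep_name <- taxa      # representative taxon for tie-breaking
  br <- function(x) sprintf("%.12g", x)
  while (nrow(d) > 3) {
    k <- nrow(d)
    r <- rowSums(d)
    Q <- (k - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij)
      paste(sort(c(rep_name[ij[1]], rep_name[ij[2]])), collapse = "\r"))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    vj <- d[i, j] - vi
    newlab <- sprintf("(%s:%s,%s:%s)", lab[i], br(max(vi, 0)),
                      lab[j], br(max(vj, 0)))
    newraw <- sprintf("(%s:%s,%s:%s)", lab_raw[i], br(vi), lab_raw[j], br(vj))
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    lab <- c(lab[keep], newlab)
    lab_raw <- c(lab_raw[keep], newraw)
    rep_name <- c(rep_name[keep], min(rep_name[c(i, j)]))
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", lab[1], br(max(v1, 0)),
                 lab[2], br(max(v2, 0)), lab[3], br(max(v3, 0)))
  raw <- sprintf("(%s:%s,%s:%s,%s:%s);", lab_raw[1], br(v1),
                 lab_raw[2], br(v2), lab_raw[3], br(v3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "edge.length.raw") <- ape::read.tree(text = raw)$edge.length
  tree
}

# informative bipartitions of an unrooted tree as canonical string keys
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  out <- character(0)
  for (node in unique(tree$edge[, 2])) {
    if (node <= ntip) next
    tips <- tree$tip.label[tips_under(tree, node)]
    if (tree$tip.label[1] %in% tips)
      tips <- setdiff(tree$tip.label, tips)
    if (length(tips) < 2 || length(tips) > ntip - 2) next
    out <- c(out, paste(sort(tips), collapse = "|"))
  }
  names(out) <- NULL
  unique(out)
}

tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  acc <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    acc <- c(acc, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  acc
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement \code{n_reps} times, rebuilds the tree per
#' replicate (replicate r uses \code{seed + r}), and reports the percent of
#' replicates containing each internal edge's bipartition.  Supports are
#' written to \code{tree$node.label} so they survive Newick round-trips.
#'
#' @param aln Named character vector of aligned sequences (or matrix).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; results are reproducible given the same seed.
#' @param model Distance model, see [p_distance()].
#' @return The NJ tree (\code{ape::phylo}) with per-internal-node support
#'   percents in \code{node.label} and a \code{support} attribute
#'   (data.frame of bipartition key and percent).
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1, model = "p") {
  if (n_reps < 1) stop("n_reps must be >= 1")
  m <- alignment_matrix(aln)
  main <- neighbor_joining(p_distance(m, model))
  counts <- integer(0)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    bt <- neighbor_joining(p_distance(m[, cols, drop = FALSE], model))
    for (key in tree_bipartitions(bt))
      counts[key] <- if (is.na(counts[key])) 1L else counts[key] + 1L
  }
  main <- ape::unroot(main)
  ntip <- length(main$tip.label)
  nl <- rep("", main$Nnode)
  sup <- data.frame(bipartition = character(0), percent = numeric(0))
  for (node in unique(main$edge[, 2])) {
    if (node <= ntip) next
    tips <- main$tip.label[tips_under(main, node)]
    key_tips <- if (main$tip.label[1] %in% tips)
      setdiff(main$tip.label, tips) else tips
    if (length(key_tips) < 2 || length(key_tips) > ntip - 2) next
    key <- paste(sort(key_tips), collapse = "|")
    pct <- 100 * (if (is.na(counts[key])) 0L else counts[key]) / n_reps
    nl[node - ntip] <- sprintf("%g", pct)
    sup <- rbind(sup, data.frame(bipartition = key, percent = pct))
  }
  main$node.label <- nl
  attr(main, "support") <- sup
  main
}

#' Write a tree in Newick format
#' @param tree An \code{ape::phylo} tree.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An \code{ape::phylo} tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
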