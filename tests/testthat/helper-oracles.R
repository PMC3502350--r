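# Independent oracles used across the suite.  These deliberately avoid the
# package's dynamic-programming / scanning code paths: structures are
# enumerated exhaustively and scored by loop decomposition, scans are done
# window by window in plain R.

ALPH <- c("a", "c", "g", "u")

oracle_random_rna <- function(n) paste(sample(ALPH, n, TRUE), collapse = "")

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("au", "ua", "cg", "gc", "gu", "ug")
}

# all nested structures (lists of 1-based c(i, j) pairs), min loop 3
enumerate_structures <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)                      # i unpaired
    for (k in seq(i + 4, j, length.out = max(0, j - i - 3))) {
      if (!oracle_can_pair(v[i], v[k])) next
      left <- rec(i + 1, k - 1)
      right <- rec(k + 1, j)
      for (L in left) for (R in right)
        out[[length(out) + 1L]] <- c(list(c(i, k)), L, R)
    }
    memo[[key]] <- out
    out
  }
  rec(1, nchar(seq))
}

oracle_loop_lookup <- function(tab, size) {
  if (size <= length(tab)) return(tab[size])
  tab[length(tab)] + 1.75 * 0.6163 * log(size / length(tab))
}

# score a structure by decomposing it into loops; independent of the DP
oracle_energy <- function(seq, pairs, params = rna_energy_params()) {
  if (!length(pairs)) return(0)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  pm <- do.call(rbind, pairs)
  pm <- pm[order(pm[, 1]), , drop = FALSE]
  ptname <- function(i, j) toupper(paste0(v[i], v[j]))
  # children of pair r: pairs directly enclosed (not within another enclosed pair)
  children_of <- function(i, j) {
    inside <- which(pm[, 1] > i & pm[, 2] < j)
    direct <- inside[vapply(inside, function(r) {
      !any(pm[inside, 1] < pm[r, 1] & pm[inside, 2] > pm[r, 2])
    }, logical(1))]
    pm[direct, , drop = FALSE]
  }
  total <- 0
  for (r in seq_len(nrow(pm))) {
    i <- pm[r, 1]; j <- pm[r, 2]
    ch <- children_of(i, j)
    if (nrow(ch) == 0) {
      total <- total + oracle_loop_lookup(params$hairpin, j - i - 1)
    } else if (nrow(ch) == 1) {
      k <- ch[1, 1]; l <- ch[1, 2]
      l1 <- k - i - 1; l2 <- j - l - 1
      if (l1 == 0 && l2 == 0) {
        total <- total + params$stack[ptname(i, j), ptname(k, l)]
      } else if (l1 == 0 || l2 == 0) {
        total <- total + oracle_loop_lookup(params$bulge, l1 + l2)
      } else {
        total <- total + oracle_loop_lookup(params$internal, l1 + l2) +
          min(params$asym_max, params$asym_coef * abs(l1 - l2))
      }
    } else {
      unpaired <- (j - i - 1) - sum(ch[, 2] - ch[, 1] + 1)
      total <- total + params$ml_a + params$ml_b * (1 + nrow(ch)) +
        params$ml_c * unpaired
    }
  }
  total
}

# exhaustive-minimum MFE (empty structure allowed at 0)
oracle_mfe <- function(seq, params = rna_energy_params()) {
  structs <- enumerate_structures(seq)
  e <- vapply(structs, oracle_energy, numeric(1), seq = seq, params = params)
  min(0, e)
}

# window-by-window Hamming scan in plain R (both strands)
oracle_scan <- function(query, subject, max_mm) {
  qv <- strsplit(query, "", fixed = TRUE)[[1]]
  rv <- strsplit(revcomp_rna(query), "", fixed = TRUE)[[1]]
  sv <- strsplit(subject, "", fixed = TRUE)[[1]]
  m <- length(qv); out <- NULL
  for (s in 0:(length(sv) - m)) {
    w <- sv[(s + 1):(s + m)]
    dmf <- sum(w != qv); dmr <- sum(w != rv)
    if (dmf <= max_mm) out <- rbind(out, c(s, dmf, 1L))
    if (dmr <= max_mm) out <- rbind(out, c(s, dmr, 2L))
  }
  out
}

# window-by-window complementarity scoring (mismatches, wobbles)
oracle_target_scan <- function(mirna, subject) {
  mv <- strsplit(mirna, "", fixed = TRUE)[[1]]
  sv <- strsplit(subject, "", fixed = TRUE)[[1]]
  L <- length(mv)
  t(vapply(0:(length(sv) - L), function(s) {
    mm <- 0L; wb <- 0L
    for (p in seq_len(L)) {
      tb <- sv[s + L + 1 - p]; mb <- mv[p]
      pr <- paste0(mb, tb)
      if (pr %in% c("au", "ua", "cg", "gc")) next
      if (pr %in% c("gu", "ug")) wb <- wb + 1L else mm <- mm + 1L
    }
    c(s, mm, wb)
  }, integer(3)))
}

# Altschul-Erikson dinucleotide-preserving shuffle
dinuc_shuffle <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  if (n < 3) return(seq)
  first <- v[1]; last <- v[n]
  edges <- split(v[-1], v[-n])  # successors per vertex, in order
  verts <- names(edges)
  repeat {
    last_edge <- vapply(verts, function(vx) {
      if (vx == last && !length(edges[[vx]])) return(NA_character_)
      sample(edges[[vx]], 1)
    }, character(1))
    # all vertices (except `last`) must reach `last` via last-edges
    ok <- TRUE
    for (vx in setdiff(verts, last)) {
      seen <- character(0); cur <- vx
      while (!is.na(cur) && cur != last && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- if (cur %in% names(last_edge)) last_edge[[cur]] else NA
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  walk_edges <- lapply(verts, function(vx) {
    e <- edges[[vx]]
    if (vx == last || is.na(last_edge[[vx]])) return(sample(e, length(e)))
    pick <- which(e == last_edge[[vx]])[1]
    c(sample(e[-pick], length(e) - 1L), e[pick])
  })
  names(walk_edges) <- verts
  out <- character(n); out[1] <- first
  ptr <- setNames(rep(1L, length(verts)), verts)
  cur <- first
  for (i in 2:n) {
    nxt <- walk_edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

# random additive tree + its exact leaf-to-leaf distance matrix
oracle_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- sort(tr$tip.label)[order(sample(n_taxa))]
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
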