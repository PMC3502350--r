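test_that("the DP matches exhaustive enumeration on random short sequences", {
  set.seed(101)
  for (i in 1:60) {
    s <- oracle_random_rna(sample(10:20, 1))
    f <- fold_mfe(s)
    expect_equal(f$mfe, oracle_mfe(s), tolerance = 1e-8)
    # the reported structure scores to the reported energy
    if (nrow(f$pairs)) {
      pl <- lapply(seq_len(nrow(f$pairs)), function(k) f$pairs[k, ] + 1L)
      expect_equal(oracle_energy(s, pl), f$mfe, tolerance = 1e-8)
    }
  }
})

test_that("structures are well-formed: balanced, nested, paired, min loop 3", {
  set.seed(102)
  for (i in 1:30) {
    s <- oracle_random_rna(sample(15:60, 1))
    f <- fold_mfe(s)
    expect_equal(nchar(f$structure), nchar(s))
    expect_equal(sum(strsplit(f$structure, "")[[1]] == "("),
                 sum(strsplit(f$structure, "")[[1]] == ")"))
    expect_lte(f$mfe, 0)
    if (f$mfe == 0) expect_equal(nrow(f$pairs), 0)
    if (nrow(f$pairs)) {
      v <- strsplit(s, "")[[1]]
      for (k in seq_len(nrow(f$pairs))) {
        i0 <- f$pairs[k, 1]; j0 <- f$pairs[k, 2]
        expect_true(oracle_can_pair(v[i0 + 1], v[j0 + 1]))
        expect_gte(j0 - i0 - 1, 3)
      }
      # nested: no crossing pairs
      for (a in seq_len(nrow(f$pairs))) for (b in seq_len(nrow(f$pairs))) {
        ia <- f$pairs[a, 1]; ja <- f$pairs[a, 2]
        ib <- f$pairs[b, 1]; jb <- f$pairs[b, 2]
        expect_false(ia < ib && ib < ja && ja < jb)
      }
    }
  }
})

test_that("a base-free sequence yields no pairs and zero energy", {
  f <- fold_mfe(paste(rep("a", 30), collapse = ""))
  expect_equal(f$mfe, 0)
  expect_equal(f$structure, paste(rep(".", 30), collapse = ""))
  expect_equal(nrow(f$pairs), 0)
})

test_that("closing a hairpin with an extra GC pair strictly lowers the energy", {
  set.seed(103)
  for (i in 1:10) {
    stem <- oracle_random_rna(6)
    hp <- paste0(stem, "gaaac", revcomp_rna(stem))
    base <- fold_mfe(hp)
    if (base$mfe >= 0) next
    ext <- fold_mfe(paste0("g", hp, "c"))
    expect_lt(ext$mfe, base$mfe)
  }
})

test_that("energies are invariant under reverse complement of WC hairpins", {
  # mixed GC/AU stems whose reverse complement maps pairs onto pairs
  set.seed(104)
  for (i in 1:10) {
    stem <- paste(sample(c("g", "c", "a"), 8, TRUE), collapse = "")
    hp <- paste0(stem, "aacaa", revcomp_rna(stem))
    f1 <- fold_mfe(hp)
    f2 <- fold_mfe(revcomp_rna(hp))
    expect_equal(oracle_mfe(hp), f1$mfe, tolerance = 1e-8)
    expect_equal(f2$mfe, f1$mfe, tolerance = 1e-8)
  }
})

test_that("dinucleotide-shuffled precursors fold less stably than the original", {
  set.seed(105)
  cat59 <- read_mirna_catalog()
  p <- mirtas:::make_precursor(cat59$sequence[cat59$name == "Nat-miR390a"])
  orig <- fold_mfe(p$sequence)$mfe
  shuf <- replicate(100, {
    s <- dinuc_shuffle(p$sequence)
    fold_mfe(s)$mfe
  })
  # doublet counts preserved by construction
  doublets <- function(s) table(substring(s, 1:(nchar(s) - 1), 2:nchar(s)))
  s1 <- dinuc_shuffle(p$sequence)
  expect_equal(as.list(doublets(s1)), as.list(doublets(p$sequence)))
  z <- (mean(shuf) - orig) / (sd(shuf) / sqrt(length(shuf)))
  expect_gt(z, 3)
  expect_gt(mean(shuf), orig)
})

test_that("hairpin validation accepts canonical precursors and localizes the mature", {
  set.seed(106)
  cat59 <- read_mirna_catalog()
  for (nm in c("Nat-miR156a", "Nat-miR390a", "Nat-miR828")) {
    p <- mirtas:::make_precursor(cat59$sequence[cat59$name == nm])
    f <- fold_mfe(p$sequence)
    v <- validate_hairpin(f, p$mature_offset, p$mature_length)
    expect_true(v$is_stem_loop)
    expect_equal(v$arm, "5p")
    expect_gte(v$mature_paired_fraction, 0.6)
    # oracle: recompute the pairing fraction from the pair list
    partner <- rep(NA, nchar(p$sequence))
    for (k in seq_len(nrow(f$pairs))) {
      partner[f$pairs[k, 1] + 1] <- f$pairs[k, 2]
      partner[f$pairs[k, 2] + 1] <- f$pairs[k, 1]
    }
    idx <- (p$mature_offset + 1):(p$mature_offset + p$mature_length)
    expect_equal(v$mature_paired_fraction, mean(!is.na(partner[idx])))
  }
})

test_that("a mature across the terminal loop is rejected with the right reason", {
  arm <- "gcgcgugcagcaucgg"
  hp <- paste0(arm, "auaaauaa", revcomp_rna(arm))
  f <- fold_mfe(hp)
  v <- validate_hairpin(f, mature_start = 10, mature_len = 21)
  expect_false(v$is_stem_loop)
  expect_equal(v$reason, "mature overlaps loop")
})

test_that("branched two-hairpin folds are rejected as not a single stem-loop", {
  outer <- "ggcgcaugcgcc"
  h1 <- "gggcgaaaacgccc"
  h2 <- "ggcgcaaaagcgcc"
  s <- paste0(outer, "aa", h1, "aa", h2, "aa", revcomp_rna(outer))
  f <- fold_mfe(s)
  v <- validate_hairpin(f, mature_start = 0, mature_len = 12)
  expect_false(v$is_stem_loop)
  expect_equal(v$reason, "not a single stem-loop")
  expect_gte(v$n_hairpin_loops, 2)
})

test_that("weak folds fail on stability and out-of-range matures error", {
  f <- fold_mfe("ggcgaaaacgcuaaaaaaaaaa")  # one tiny stem
  expect_gt(f$mfe, -15)
  if (nrow(f$pairs)) {
    v <- validate_hairpin(f, 0, 4, mfe_max = -15)
    expect_false(v$is_stem_loop)
  }
  expect_error(validate_hairpin(f, 10, 30), "out of range")
})

test_that("Vienna output carries sequence, structure and energy", {
  f <- fold_mfe("ggggcaaaagcccc")
  path <- tempfile(fileext = ".vienna")
  write_vienna(f, path, ids = "hp1")
  lines <- readLines(path)
  expect_equal(lines[1], ">hp1")
  expect_equal(lines[2], f$sequence)
  expect_match(lines[3], "^[().]+ \\(-?[0-9.]+\\)$")
})
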