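cat59 <- read_mirna_catalog()
q390 <- setNames(cat59$sequence[cat59$name == "Nat-miR390a"], "Nat-miR390a")

test_that("exact planted copies are found with zero mismatches", {
  set.seed(21)
  db <- c(tx = paste0(oracle_random_rna(150), q390, oracle_random_rna(100)))
  hits <- scan_homologs(q390, db, max_mismatch = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 150)
  expect_equal(hits$end, 171)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0)
  expect_identical(hits$matched_seq, unname(q390))
})

test_that("reverse-complement copies with substitutions are found on minus strand", {
  set.seed(22)
  mut <- mirtas:::mutate_seq(unname(q390), 2)
  db <- c(tx = paste0(oracle_random_rna(80), revcomp_rna(mut),
                      oracle_random_rna(120)))
  hits <- scan_homologs(q390, db, max_mismatch = 4)
  planted <- hits[hits$start == 80, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$strand, "-")
  expect_equal(planted$mismatches, 2)
  # oracle: recompute distances window by window
  orc <- oracle_scan(unname(q390), db[[1]], 4)
  expect_true(all(hits$start %in% orc[, 1]))
  expect_equal(nrow(hits), nrow(orc))
})

test_that("sites beyond the mismatch budget are not reported", {
  set.seed(23)
  mut5 <- mirtas:::mutate_seq(unname(q390), 5)
  db <- c(tx = paste0(oracle_random_rna(60), mut5, oracle_random_rna(60)))
  hits <- scan_homologs(q390, db, max_mismatch = 4)
  expect_false(any(hits$start == 60 & hits$strand == "+"))
  expect_equal(hamming_distance(mut5, unname(q390)), 5)
})

test_that("scan agrees with the window oracle and exact search at budget 0", {
  set.seed(24)
  for (rep in 1:5) {
    q <- setNames(oracle_random_rna(21), "q")
    db <- c(t1 = oracle_random_rna(400), t2 = oracle_random_rna(300))
    mm <- sample(0:4, 1)
    hits <- scan_homologs(q, db, max_mismatch = mm)
    for (tx in names(db)) {
      got <- hits[hits$transcript == tx, ]
      orc <- oracle_scan(unname(q), db[[tx]], mm)
      expect_equal(nrow(got), if (is.null(orc)) 0 else nrow(orc))
    }
    # reported mismatch counts equal Hamming distance to the query
    if (nrow(hits))
      expect_equal(hits$mismatches,
                   vapply(hits$matched_seq, hamming_distance,
                          numeric(1), b = unname(q), USE.NAMES = FALSE))
  }
  # budget 0 equals exact substring search
  set.seed(25)
  db <- c(tx = oracle_random_rna(5000))
  q <- setNames(substr(db[[1]], 1001, 1021), "sub")
  h0 <- scan_homologs(q, db, max_mismatch = 0)
  starts <- gregexpr(unname(q), db[[1]], fixed = TRUE)[[1]]
  expect_setequal(h0$start[h0$strand == "+"], starts - 1L)
})

test_that("queries outside 20-24 nt are skipped with a warning", {
  db <- c(tx = oracle_random_rna(100))
  qs <- c(short = "acgu", ok = oracle_random_rna(21))
  expect_warning(h <- scan_homologs(qs, db, 4), "skipped")
  expect_true(all(h$query == "ok"))
  expect_error(scan_homologs(qs, db, 4, on_bad_query = "error"), "skipped")
})

test_that("coding filter finds ORFs on all six frames", {
  set.seed(26)
  # 120-codon ORF, plus strand, shifted frame
  orf <- paste0("aug", paste(rep("gca", 119), collapse = ""), "uaa")
  tx <- paste0("cc", orf, oracle_random_rna(50))
  res <- coding_filter(tx, min_orf_aa = 100)
  expect_false(res$non_coding)
  expect_equal(res$longest_orf_aa, 120)
  # same ORF on the minus strand
  res_m <- coding_filter(revcomp_rna(tx), min_orf_aa = 100)
  expect_false(res_m$non_coding)
  expect_equal(res_m$longest_orf_aa, 120)
  # no AUG anywhere
  no_aug <- gsub("aug", "aca", paste(rep("ccuu", 60), collapse = ""))
  res0 <- coding_filter(no_aug)
  expect_true(res0$non_coding)
  expect_equal(res0$longest_orf_aa, 0)
})

test_that("planted precursor windows pass the coding filter", {
  set.seed(27)
  p <- mirtas:::make_precursor(unname(q390))
  win <- paste0(oracle_random_rna(60), p$sequence, oracle_random_rna(60))
  expect_true(coding_filter(win, min_orf_aa = 100)$non_coding)
})

test_that("precursor windows are extracted with correct offsets and truncation", {
  set.seed(28)
  tx <- oracle_random_rna(1000)
  hit <- list(start = 100, end = 121, strand = "+")
  w <- extract_precursor(tx, hit, flank = 80)
  expect_equal(w$window_start, 20)
  expect_equal(w$window_end, 201)
  expect_equal(w$mature_offset, 80)
  expect_false(w$truncated)
  expect_identical(substr(w$sequence, 81, 101), substr(tx, 101, 121))
  # truncation at the 5' end
  w2 <- extract_precursor(tx, list(start = 5, end = 26, strand = "+"), 80)
  expect_equal(w2$window_start, 0)
  expect_equal(w2$window_end, 106)
  expect_true(w2$truncated)
  expect_equal(w2$mature_offset, 5)
})

test_that("minus-strand windows round-trip with scan coordinates", {
  set.seed(29)
  q <- setNames(oracle_random_rna(21), "q")
  tx <- paste0(oracle_random_rna(200), revcomp_rna(unname(q)),
               oracle_random_rna(150))
  hits <- scan_homologs(q, c(tx = tx), 0)
  hit <- hits[hits$strand == "-", ][1, ]
  w <- extract_precursor(tx, hit, flank = 50)
  mat <- substr(w$sequence, w$mature_offset + 1,
                w$mature_offset + w$mature_length)
  expect_identical(mat, unname(q))
})
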