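cat59 <- read_mirna_catalog()

test_that("generators are deterministic given the seed", {
  t1 <- generate_transcriptome(cat59, n_transcripts = 30,
                               planted = data.frame(name = cat59$name[1:5],
                                                    n_sub = 0:4),
                               n_coding_decoys = 2,
                               length_range = c(300, 600), seed = 99)
  t2 <- generate_transcriptome(cat59, n_transcripts = 30,
                               planted = data.frame(name = cat59$name[1:5],
                                                    n_sub = 0:4),
                               n_coding_decoys = 2,
                               length_range = c(300, 600), seed = 99)
  expect_identical(t1$transcripts, t2$transcripts)
  expect_identical(t1$truth, t2$truth)
  m1 <- generate_microarray(seed = 5)
  m2 <- generate_microarray(seed = 5)
  expect_identical(m1$intensities, m2$intensities)
  q1 <- generate_qpcr(c(g = "null"), seed = 6)
  q2 <- generate_qpcr(c(g = "null"), seed = 6)
  expect_identical(q1$ct, q2$ct)
})

test_that("planted matures are recovered at the recorded coordinates", {
  plant <- data.frame(name = cat59$name[c(1, 10, 30, 44, 50)], n_sub = 0:4)
  sim <- generate_transcriptome(cat59, planted = plant, n_transcripts = 40,
                                n_coding_decoys = 2,
                                length_range = c(300, 700), seed = 7)
  queries <- setNames(cat59$sequence[match(plant$name, cat59$name)],
                      plant$name)
  hits <- scan_homologs(queries, sim$transcripts, max_mismatch = 4)
  for (k in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[k, ]
    found <- hits[hits$query == tr$query & hits$transcript == tr$transcript &
                  hits$start == tr$start & hits$strand == tr$strand, ]
    expect_equal(nrow(found), 1)
    expect_equal(found$mismatches, tr$n_sub)
  }
  # every reported hit is a true <=4-mismatch window (precision oracle)
  for (k in seq_len(nrow(hits))) {
    h <- hits[k, ]
    expect_lte(hamming_distance(h$matched_seq, unname(queries[h$query])), 4)
  }
})

test_that("five substitutions escape a four-mismatch scan", {
  plant <- data.frame(name = cat59$name[1], n_sub = 5)
  sim <- generate_transcriptome(cat59, planted = plant, n_transcripts = 10,
                                n_coding_decoys = 0,
                                length_range = c(300, 500), seed = 8)
  q <- setNames(cat59$sequence[1], cat59$name[1])
  hits <- scan_homologs(q, sim$transcripts, max_mismatch = 4)
  tr <- sim$truth[1, ]
  expect_false(any(hits$transcript == tr$transcript & hits$start == tr$start &
                   hits$strand == tr$strand))
})

test_that("coding decoys are coding and the rest are not", {
  sim <- generate_transcriptome(cat59,
                                planted = data.frame(name = cat59$name[1],
                                                     n_sub = 0),
                                n_transcripts = 12, n_coding_decoys = 3,
                                length_range = c(400, 600), seed = 9)
  for (id in sim$decoys)
    expect_false(coding_filter(sim$transcripts[[id]])$non_coding)
  plain <- setdiff(names(sim$transcripts),
                   c(sim$decoys, sim$truth$transcript))
  for (id in plain[1:4])
    expect_true(coding_filter(sim$transcripts[[id]])$non_coding)
})

test_that("the precursor set honors its validity labels under validation", {
  ps <- generate_precursor_set(cat59, n_valid = 6, n_corrupt = 3, seed = 10)
  for (k in seq_len(nrow(ps$truth))) {
    tr <- ps$truth[k, ]
    f <- fold_mfe(ps$sequences[[tr$id]])
    v <- validate_hairpin(f, tr$mature_offset, tr$mature_length)
    expect_equal(v$is_stem_loop, tr$valid)
  }
})

test_that("synthetic TAS transcripts reproduce their planted truth", {
  tas <- generate_tas("Nat-miR390a", cat59, site_pos = 150, n_phases = 4,
                      seed = 11)
  trig <- setNames(cat59$sequence[cat59$name == "Nat-miR390a"], "Nat-miR390a")
  loci <- find_tas_loci(tas$sequence, trig, n_windows = 4)
  expect_length(loci, 1)
  loc <- loci[[1]]
  expect_equal(loc$site$start, tas$truth$site_start)
  expect_equal(loc$cleavage_pos, tas$truth$cleavage_pos)
  expect_equal(loc$windows$start, tas$truth$windows$start)
  expect_true(all(!loc$windows$truncated))
  # a trigger with 5 substitutions stays below the budget
  tas5 <- generate_tas("Nat-miR390a", cat59, mismatches = 5, seed = 12)
  loci5 <- find_tas_loci(tas5$sequence, trig, max_score = 4)
  expect_false(any(vapply(loci5, function(l)
    l$site$start == tas5$truth$site_start, logical(1))))
  # insufficient room for the requested phases is an error
  expect_error(generate_tas("Nat-miR390a", cat59, n_phases = 10,
                            total_len = 250, seed = 13),
               "too short")
  # zero phases: a locus with an empty window list
  tas0 <- generate_tas("Nat-miR390a", cat59, n_phases = 0, seed = 14)
  loci0 <- find_tas_loci(tas0$sequence, trig, n_windows = 0)
  expect_equal(nrow(loci0[[1]]$windows), 0)
})

test_that("null qPCR archetypes keep the false-induction rate low", {
  arch <- setNames(rep("null", 60), sprintf("n%02d", 1:60))
  q <- generate_qpcr(arch, seed = 15, genotypes = "WT")
  cls <- classify_responses(q)
  expect_gte(mean(cls$induction_class == "not-induced"), 0.94)
})

test_that("unknown archetypes and absent matures are rejected", {
  expect_error(generate_qpcr(c(g = "mystery")), "unknown archetype")
  expect_error(generate_transcriptome(cat59,
                                      planted = data.frame(name = "nope",
                                                           n_sub = 0),
                                      n_transcripts = 5),
               "absent from catalog")
})
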