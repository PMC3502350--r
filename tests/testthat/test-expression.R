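test_that("the omnibus F and p agree with base aov on random data", {
  set.seed(401)
  for (i in 1:10) {
    g <- factor(rep(c("a", "b", "c", "d")[1:sample(2:4, 1)], each = 4))
    y <- rnorm(length(g), mean = as.integer(g) * runif(1, 0, 2))
    fit <- anova_plsd(y, g)
    ref <- anova(stats::aov(y ~ g))
    expect_equal(fit$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(fit$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(fit$mse, ref$`Mean Sq`[2], tolerance = 1e-10)
  }
})

test_that("two-group PLSD equals the pooled-variance t-test", {
  set.seed(402)
  y <- c(rnorm(4), rnorm(4, 3))
  g <- rep(c("a", "b"), each = 4)
  fit <- anova_plsd(y, g)
  tt <- stats::t.test(y[g == "a"], y[g == "b"], var.equal = TRUE)
  expect_true(fit$protected)
  expect_equal(fit$pairwise$p, tt$p.value, tolerance = 1e-10)
  expect_equal(abs(fit$pairwise$t), abs(unname(tt$statistic)),
               tolerance = 1e-10)
})

test_that("identical groups share one letter and skip pairwise tests", {
  y <- c(1, 1.05, 0.95, 1.02, 0.98, 1.01)
  g <- rep(c("a", "b"), each = 3)
  fit <- anova_plsd(y, g)
  expect_false(fit$protected)
  expect_true(all(is.na(fit$pairwise$p)))
  expect_equal(unname(fit$letters), c("a", "a"))
})

test_that("clearly separated groups get distinct letters in mean order", {
  set.seed(403)
  y <- c(rnorm(3, 0, 0.1), rnorm(3, 0, 0.1), rnorm(3, 10, 0.1))
  g <- rep(c("g1", "g2", "g3"), each = 3)
  fit <- anova_plsd(y, g)
  expect_equal(unname(fit$letters[c("g1", "g2")]), c("a", "a"))
  expect_equal(unname(fit$letters["g3"]), "b")
  # oracle: the g1/g3 PLSD p equals the pooled-variance t computed by hand
  mse <- fit$mse; df2 <- fit$df2
  tstat <- (mean(y[1:3]) - mean(y[7:9])) / sqrt(mse * (2 / 3))
  row <- fit$pairwise$g1 == "g1" & fit$pairwise$g2 == "g3"
  expect_equal(abs(fit$pairwise$t[row]), abs(tstat), tolerance = 1e-10)
  # three well-separated groups get three letters
  y2 <- c(rnorm(3, 0, 0.1), rnorm(3, 5, 0.1), rnorm(3, 10, 0.1))
  fit2 <- anova_plsd(y2, g)
  expect_equal(sort(unname(fit2$letters)), c("a", "b", "c"))
})

test_that("groups with a single replicate are rejected", {
  expect_error(anova_plsd(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("relative quantities follow the ddCt arithmetic", {
  # 3 replicates, hand-computed oracle
  ct <- data.frame(
    gene = rep(c("NaEF", "mir"), each = 6),
    genotype = "WT",
    treatment = rep(rep(c("CTRL", "W+OS"), each = 3), 2),
    time = "1h",
    replicate = rep(1:3, 4),
    ct = c(20.0, 20.1, 19.9, 20.0, 20.1, 19.9,   # reference, both conditions
           24.0, 24.1, 23.9, 22.0, 22.1, 21.9))  # gene: 2 cycles lower in W+OS
  q <- as_qpcr_table(ct)
  rq <- relative_quantity(q, "mir", "NaEF",
                          calibrator = list(genotype = "WT", treatment = "CTRL",
                                            time = "1h"))
  cond <- rq$condition
  expect_equal(cond$rq[cond$treatment == "CTRL"], 1.0)
  expect_equal(cond$rq[cond$treatment == "W+OS"], 4.0)
  expect_equal(cond$ddct[cond$treatment == "W+OS"], -2)
  # per-replicate values match the paired-by-index computation
  rep_tab <- rq$replicate
  expect_equal(rep_tab$dct[rep_tab$treatment == "CTRL"], c(4, 4, 4))
  expect_equal(rep_tab$log2_rq[rep_tab$treatment == "W+OS"], c(2, 2, 2))
})

test_that("rq is invariant to a constant shift of all Ct values", {
  set.seed(404)
  arch <- c(g1 = "OS-inducible")
  q <- generate_qpcr(arch, seed = 5, genotypes = "WT", times = "1h")
  rq1 <- relative_quantity(q, "g1")
  q2 <- q; q2$ct <- q2$ct + 3.7
  rq2 <- relative_quantity(q2, "g1")
  expect_equal(rq1$condition$rq, rq2$condition$rq, tolerance = 1e-12)
})

test_that("a missing reference cell is a hard, named error", {
  set.seed(405)
  q <- generate_qpcr(c(g1 = "null"), seed = 5, genotypes = "WT", times = "1h")
  q2 <- q[!(q$gene == "NaEF" & q$treatment == "W+OS"), ]
  expect_error(relative_quantity(q2, "g1"), "W\\+OS")
})

test_that("percentile normalization centers samples and ignores scale", {
  m <- matrix(5, 10, 4, dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  expect_equal(unname(normalize_array(m)), matrix(0, 10, 4))
  set.seed(406)
  m2 <- matrix(rlnorm(40, 3), 10, 4, dimnames = dimnames(m))
  n1 <- normalize_array(m2)
  m3 <- m2; m3[, 2] <- m3[, 2] * 7.3
  n2 <- normalize_array(m3)
  expect_equal(n1, n2, tolerance = 1e-12)
  # interpolated 75th percentile oracle on {1,2,3,4}: 3.25
  m4 <- matrix(1:4, 4, 1, dimnames = list(NULL, "s"))
  expect_equal(unname(normalize_array(m4)[, 1]), log2((1:4) / 3.25))
  m2[2, 2] <- -1
  expect_error(normalize_array(m2), "nonpositive")
})

test_that("the fold-change screen uses a strict 2-fold boundary", {
  m <- rbind(pass = c(0, 0, 0, 1.5, 1.5, 1.5),
             edge = c(0, 0, 0, 1.0, 1.0, 1.0))
  colnames(m) <- c(paste0("c", 1:3), paste0("t", 1:3))
  res <- fold_change_screen(m, list(paste0("c", 1:3), paste0("t", 1:3)))
  expect_true(res$pass_screen[res$gene == "pass"])
  expect_false(res$pass_screen[res$gene == "edge"])
})

test_that("planted differential genes survive the screen and the test", {
  sim <- generate_microarray(n_genes = 100, n_de = 10, fold = 4, seed = 7)
  norm <- normalize_array(sim$intensities)
  grp <- split(sim$factors$sample, sim$factors$group)
  res <- fold_change_screen(norm, list(grp[["CTRL"]], grp[["W+OS"]]))
  called <- res$gene[res$significant]
  expect_gte(mean(sim$truth %in% called), 0.95)
  expect_lte(sum(!(called %in% sim$truth)), 2)
})
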