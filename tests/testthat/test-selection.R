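test_that("one-way ANOVA matches the hand ANOVA table and aov", {
  # identical groups: F = 0, p = 1
  r <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # separated groups with tiny jitter: p -> 0
  r2 <- one_way_anova(list(c(0, 1e-6, -1e-6), c(10, 10 + 1e-6, 10 - 1e-6)))
  expect_lt(r2$p_value, 1e-10)
  # hand-computed table for (1,2) vs (2,4): SSB = 2.25, SSW = 2.5, F = 1.8
  r3 <- one_way_anova(list(c(1, 2), c(2, 4)))
  expect_equal(r3$statistic, 1.8, tolerance = 1e-12)
  expect_equal(r3$p_value, pf(1.8, 1, 2, lower.tail = FALSE), tolerance = 1e-12)
  # cross-check against stats::aov on a random case
  set.seed(21)
  g <- list(rnorm(7), rnorm(5, 0.5), rnorm(6, 1))
  ref <- summary(aov(y ~ grp, data.frame(
    y = unlist(g), grp = factor(rep(1:3, lengths(g))))))[[1]]
  r4 <- one_way_anova(g)
  expect_equal(r4$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(r4$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("lfdr estimates are bounded, near 1 under the null, near 0 under strong signal", {
  set.seed(22)
  p_null <- runif(2000)
  r <- estimate_lfdr(p_null)
  expect_true(all(r$lfdr >= 0 & r$lfdr <= 1))
  expect_gt(r$pi0, 0.85)
  expect_gt(mean(r$lfdr), 0.85)
  # two-groups mixture: half strong signal
  p_mix <- c(rbeta(1000, 0.1, 1), runif(1000))
  r2 <- estimate_lfdr(p_mix)
  small <- r2$lfdr[order(p_mix)][1:200]  # smallest decile
  expect_lt(mean(small), 0.2)
  expect_error(estimate_lfdr(rep(0.5, 50)), "distinct")
  expect_error(estimate_lfdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("transcript batch filter removes planted batch shifts and matches brute force", {
  set.seed(23)
  n <- 60
  batch <- setNames(sample(c("1", "2", "3"), n, replace = TRUE,
                           prob = c(0.5, 0.2, 0.3)),
                    sprintf("F%03d", 1:n))
  vals <- matrix(rnorm(n * 200, 5), n, 200,
                 dimnames = list(names(batch), sprintf("t%03d", 1:200)))
  shifted <- 1:30
  vals[batch == "2", shifted] <- vals[batch == "2", shifted] + 2
  fm <- family_features(vals, "transcript_log2", batch = batch)
  cfg <- run_config(adjust_method = "BH")
  out <- batch_filter_transcripts(fm, cfg)
  rpt <- attr(out, "filter_report")
  # brute-force recomputation with aov + BH on every column
  p_brute <- apply(vals, 2, function(v)
    summary(aov(v ~ factor(batch)))[[1]]$`Pr(>F)`[1])
  removed_brute <- colnames(vals)[p.adjust(p_brute, "BH") < 0.05]
  expect_setequal(rpt$removed, removed_brute)
  # all planted shifts are caught
  expect_true(all(sprintf("t%03d", shifted) %in% rpt$removed))
  # chaining bookkeeping
  expect_equal(rpt$n_in, 200)
  expect_equal(rpt$n_in - rpt$n_out, length(rpt$removed))
})

test_that("multi-batch families are excluded from the batch ANOVA but kept in the matrix", {
  set.seed(37)
  batch <- c(F1 = "1", F2 = "1", F3 = "1,2", F4 = "2", F5 = "2", F6 = "1",
             F7 = "2", F8 = "1", F9 = "2", F10 = "1")
  vals <- matrix(rnorm(10 * 50, 5), 10, 50,
                 dimnames = list(names(batch), sprintf("t%02d", 1:50)))
  fm <- family_features(vals, "transcript_log2", batch = batch)
  out <- batch_filter_transcripts(fm, run_config(adjust_method = "BH"))
  expect_true("F3" %in% rownames(out$values))
  p_single <- apply(vals[names(batch) != "F3", ], 2, function(v)
    summary(aov(v ~ factor(batch[names(batch) != "F3"])))[[1]]$`Pr(>F)`[1])
  expect_equal(unname(attr(out, "filter_report")$params$p_raw),
               unname(p_single), tolerance = 1e-10)
})

test_that("SNP batch filter removes batch-biased dosages and matches brute force", {
  set.seed(24)
  n <- 60
  batch <- setNames(rep(c("1", "2", "3"), c(30, 12, 18)), sprintf("F%03d", 1:n))
  vals <- vapply(runif(150, 0.1, 0.5), function(p) rbinom(n, 2, p),
                 numeric(n))
  dimnames(vals) <- list(names(batch), sprintf("s%03d", 1:150))
  vals[batch == "3", 1:20] <- rbinom(sum(batch == "3") * 20, 2, 0.9)
  fm <- family_features(vals, "snp_dosage", batch = batch)
  out <- batch_filter_snps(fm, alpha = 0.05)
  rpt <- attr(out, "filter_report")
  p_brute <- apply(vals, 2, function(v)
    summary(aov(v ~ factor(batch)))[[1]]$`Pr(>F)`[1])
  expect_setequal(rpt$removed, colnames(vals)[p_brute < 0.05])
  expect_true(all(sprintf("s%03d", 1:20) %in% rpt$removed))
  # idempotent
  out2 <- batch_filter_snps(out, alpha = 0.05)
  expect_identical(colnames(out2$values), colnames(out$values))
})

test_that("relative-variance filter matches the hand-worked dosage examples", {
  vals <- cbind(s1 = c(0, 0, 2, 2),   # mean 1, var 4/3 -> kept
                s2 = c(1, 1, 1, 1),   # var 0 -> removed
                s3 = c(0, 1, 1, 2))   # mean 1, var 2/3 -> removed
  rownames(vals) <- paste0("F", 1:4)
  out <- relative_variance_filter(family_features(vals, "snp_dosage"), 1)
  expect_identical(colnames(out$values), "s1")
  expect_equal(unname(attr(out, "filter_report")$params$ratio),
               c(4 / 3, 0, 2 / 3))
})

test_that("correlation pruning matches an independent greedy oracle", {
  # duplicated features: exactly one of the pair removed
  set.seed(25)
  base <- rnorm(12)
  dup <- cbind(a = base, b = base, c = rnorm(12))
  rownames(dup) <- sprintf("F%02d", 1:12)
  out <- correlation_prune(family_features(dup, "transcript_log2"), 0.5)
  expect_equal(ncol(out$values), 2)
  expect_true("a" %in% colnames(out$values))  # tie removes later column
  # orthogonal features: nothing removed
  zc <- scale(matrix(rnorm(36), 12, 3), center = TRUE, scale = FALSE)
  ortho <- qr.Q(qr(zc))  # centered, mutually uncorrelated columns
  dimnames(ortho) <- list(sprintf("F%02d", 1:12), c("x", "y", "z"))
  out2 <- correlation_prune(family_features(ortho, "transcript_log2"), 0.05)
  expect_equal(ncol(out2$values), 3)
  # planted correlation blocks vs the independently coded greedy rule
  for (s in 1:5) {
    set.seed(100 + s)
    z <- matrix(rnorm(20 * 2), 20, 2)
    x <- cbind(z[, 1] + rnorm(20, 0, 0.3), z[, 1] + rnorm(20, 0, 0.3),
               z[, 1] + rnorm(20, 0, 0.6), z[, 2] + rnorm(20, 0, 0.3),
               z[, 2] + rnorm(20, 0, 0.3), rnorm(20), rnorm(20), rnorm(20))
    dimnames(x) <- list(sprintf("F%02d", 1:20), sprintf("f%d", 1:8))
    out3 <- correlation_prune(family_features(x, "transcript_log2"), 0.5)
    expect_identical(colnames(out3$values),
                     colnames(x)[greedy_prune_oracle(x, 0.5)])
  }
})

test_that("transcript phenotype screen keeps signal, drops constants, matches brute force", {
  set.seed(26)
  n <- 30
  phen <- phenotypes(sprintf("F%02d", 1:n), rnorm(n), rep("1", n))
  vals <- matrix(rnorm(n * 40, 5), n, 40,
                 dimnames = list(phen$family, sprintf("t%02d", 1:40)))
  vals[, 1] <- phen$bv           # r = 1
  vals[, 2] <- 7                 # constant -> degenerate r = 0
  fm <- family_features(vals, "transcript_log2")
  out <- phenotype_screen_transcripts(fm, phen, 0.05)
  expect_true("t01" %in% colnames(out$values))
  expect_false("t02" %in% colnames(out$values))
  brute <- colnames(vals)[vapply(seq_len(ncol(vals)), function(j) {
    r <- suppressWarnings(cor(rank(vals[, j]), rank(phen$bv)))
    !is.na(r) && abs(r) > 0.05
  }, NA)]
  expect_setequal(colnames(out$values), brute)
  # idempotent
  out2 <- phenotype_screen_transcripts(out, phen, 0.05)
  expect_identical(colnames(out2$values), colnames(out$values))
})

test_that("SNP phenotype screen keeps separating SNPs and drops untestable ones", {
  set.seed(27)
  n <- 30
  bv <- c(rnorm(15, -2, 0.3), rnorm(15, 2, 0.3))
  phen <- phenotypes(sprintf("F%02d", 1:n), bv, rep("1", n))
  vals <- cbind(
    sep = rep(c(0, 2), each = 15),           # perfectly partitions BV
    mono = rep(2, n),                        # single dosage class
    noise = rbinom(n, 2, 0.4))
  rownames(vals) <- phen$family
  out <- phenotype_screen_snps(family_features(vals, "snp_dosage"), phen, 0.05)
  expect_true("sep" %in% colnames(out$values))
  expect_false("mono" %in% colnames(out$values))
  rpt <- attr(out, "filter_report")
  expect_true(is.na(rpt$params$p["mono"]))
  # brute force over testable SNPs
  p_noise <- summary(aov(bv ~ factor(vals[, "noise"])))[[1]]$`Pr(>F)`[1]
  expect_equal(unname(rpt$params$p["noise"]), p_noise, tolerance = 1e-10)
})

test_that("every filter is idempotent on generated data", {
  dat <- simulate_dataset(small_cfg(seed = 31))
  fm <- family_mean_log2(dat$counts)
  cfg <- run_config(adjust_method = "BH")
  f1 <- low_expression_filter(fm, 3)
  expect_identical(colnames(low_expression_filter(f1, 3)$values),
                   colnames(f1$values))
  nz <- colMeans(dat$snps$values) > 0
  snps <- family_features(dat$snps$values[, nz, drop = FALSE], "snp_dosage",
                          dat$snps$batch)
  f2 <- relative_variance_filter(snps, 1)
  expect_identical(colnames(relative_variance_filter(f2, 1)$values),
                   colnames(f2$values))
  f3 <- correlation_prune(f1, 0.5)
  expect_identical(colnames(correlation_prune(f3, 0.5)$values),
                   colnames(f3$values))
})
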