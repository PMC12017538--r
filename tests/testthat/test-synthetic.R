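test_that("generator output respects shapes and downstream invariants", {
  cfg <- small_cfg(seed = 11)
  dat <- simulate_dataset(cfg)
  expect_equal(dim(dat$snps$values), c(36, 300))
  expect_true(all(dat$snps$values %in% 0:2))
  expect_equal(nrow(dat$phen), 36)
  expect_true(all(is.finite(dat$phen$bv)))
  expect_true(all(dat$counts$counts >= 0))
  expect_true(all(dat$counts$counts == round(dat$counts$counts)))
  # truth IDs are subsets of generated feature IDs
  expect_true(all(dat$truth$causal_snp_ids %in% colnames(dat$snps$values)))
  expect_true(all(dat$truth$signal_transcript_ids %in%
                    colnames(dat$counts$counts)))
  # batch layout: overlap families carry both labels
  expect_equal(sum(grepl(",", dat$phen$batch)), 3)
})

test_that("identical seed and config give bit-identical outputs", {
  a <- simulate_dataset(small_cfg(seed = 5))
  b <- simulate_dataset(small_cfg(seed = 5))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$snps$values, b$snps$values)
  expect_identical(a$phen$bv, b$phen$bv)
  d <- simulate_dataset(small_cfg(seed = 6))
  expect_false(identical(a$counts$counts, d$counts$counts))
})

test_that("breeding values are exactly additive when residual variance is zero", {
  cfg <- small_cfg(seed = 3, residual_var = 0, batch_frac_snps = 0,
                   ancestry_bv_sd = 0)
  fam <- simulate_families(cfg)
  tr <- fam$truth
  centered <- sweep(fam$snps$values[, tr$causal_snp_ids, drop = FALSE], 2,
                    2 * tr$allele_freqs[tr$causal_snp_ids], "-")
  recomputed <- drop(centered %*% tr$snp_effects)
  expect_equal(unname(recomputed), unname(tr$true_bv), tolerance = 1e-12)
})

test_that("with zero SNP effects the BV variance equals the residual variance", {
  # Monte-Carlo oracle on the generator itself
  vars <- vapply(1:200, function(s) {
    cfg <- synthetic_config(n_families_batch = c(20, 6, 10), n_overlap = 0,
                            n_transcripts = 1, n_snps = 50, n_causal_snps = 5,
                            n_signal_transcripts = 0, effect_scale = 0,
                            ancestry_bv_sd = 0,
                            residual_var = 0.25, seed = s)
    var(simulate_families(cfg)$phen$bv)
  }, 0)
  expect_equal(mean(vars), 0.25, tolerance = 0.02)
})

test_that("null expression signal gives Spearman centered on zero", {
  rs <- unlist(lapply(1:20, function(s) {
    cfg <- synthetic_config(n_families_batch = c(15, 5, 5), n_overlap = 0,
                            n_transcripts = 30, n_snps = 20, n_causal_snps = 5,
                            n_signal_transcripts = 30, expression_slope = 0,
                            batch_frac_transcripts = 0, seed = s)
    dat <- simulate_dataset(cfg)
    fm <- family_mean_log2(dat$counts)
    bv <- dat$phen$bv[match(rownames(fm$values), dat$phen$family)]
    apply(fm$values, 2, function(v) spearman_cor(v, bv))
  }))
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("replicates within a family agree more than replicates across families", {
  cfg <- synthetic_config(n_families_batch = c(12, 4, 4), n_overlap = 0,
                          n_transcripts = 400, n_snps = 20, n_causal_snps = 5,
                          n_signal_transcripts = 40, dispersion = 50,
                          replicate_probs = c(0, 0, 1), seed = 2)
  rep_ <- reproducibility_report(simulate_expression(
    cfg, simulate_families(cfg)$truth, simulate_families(cfg)$phen))
  within <- rep_$r[rep_$category == "within_family"]
  among <- rep_$r[rep_$category == "among_family"]
  expect_gt(mean(within), mean(among))
})

test_that("config validation catches impossible settings", {
  expect_error(synthetic_config(n_causal_snps = 100, n_snps = 50),
               "n_causal_snps")
  expect_error(synthetic_config(dispersion = 0))
  expect_error(synthetic_config(batch_frac_snps = 1.5))
})

test_that("prediction accuracy rises monotonically with the heritability dials", {
  run_acc <- function(n_signal, slope, seed) {
    cfg <- synthetic_config(n_families_batch = c(20, 6, 10), n_overlap = 3,
                            n_transcripts = 250, n_snps = 50,
                            n_causal_snps = 5,
                            n_signal_transcripts = n_signal,
                            expression_slope = slope, seed = seed)
    dat <- simulate_dataset(cfg)
    sp <- make_split(dat$phen, "1", c("2", "3"))
    phen_tr <- dat$phen[dat$phen$family %in% sp$train, ]
    class(phen_tr) <- c("phenotypes", "data.frame")
    fm <- family_mean_log2(dat$counts)
    s <- pearson_similarity(fm)
    m <- suppressMessages(kriging_fit(s, phen_tr))
    pr <- kriging_predict_set(m, s, sp$test)
    cor(pr$pred, dat$truth$true_bv[names(pr$pred)])
  }
  # dial: signal-transcript count at fixed slope
  fracs <- c(0, 25, 75, 150)
  acc <- vapply(fracs, function(k)
    mean(vapply(1:8, function(s) run_acc(k, 0.4, s), 0)), 0)
  expect_equal(cor(acc, seq_along(fracs), method = "spearman"), 1)
  # dial: slope at fixed signal count
  slopes <- c(0, 0.2, 0.5, 1)
  acc2 <- vapply(slopes, function(b)
    mean(vapply(1:8, function(s) run_acc(75, b, s), 0)), 0)
  expect_equal(cor(acc2, seq_along(slopes), method = "spearman"), 1)
})
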