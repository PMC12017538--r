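# Synthetic multi-batch family design: SNP dosages, additive breeding values,
# replicate-level negative-binomial RNA-seq counts, with hidden ground truth.

#' Configuration for the synthetic-data generator
#'
#' Emulates a multi-batch family study: families grown in three batches
#' (default 45/11/22, with 5 of the batch-one families also grown in batch
#' two), 1-3 biological replicates per family and batch, additive breeding
#' values driven by a subset of causal SNPs, heritable expression for a
#' minority of transcripts, and batch effects on subsets of both transcripts
#' and SNP calls.
#'
#' @param n_families_batch unique families per batch (batch-two count excludes
#'   the overlap families).
#' @param n_overlap number of batch-one families also grown in batch two.
#' @param replicate_probs sampling probabilities for 1, 2 or 3 biological
#'   replicates per family-batch.
#' @param n_transcripts,n_snps feature counts.
#' @param n_causal_snps SNPs with nonzero additive effect on the breeding value.
#' @param n_signal_transcripts transcripts whose expression tracks the
#'   breeding value.
#' @param effect_scale SD of causal-SNP additive effects.
#' @param qtl_frac,qtl_boost fraction of causal SNPs treated as moderate
#'   QTLs (at least one), with effect SD multiplied by `qtl_boost`; breeding
#'   values of quantitative traits typically mix many minor loci with a few
#'   detectable ones.
#' @param expression_slope SD of the per-transcript log2 expression shift per
#'   standardized unit of breeding value.
#' @param batch_frac_transcripts,batch_sd_transcripts fraction of transcripts
#'   with batch effects and the SD of their per-batch log2 shifts.
#' @param batch_frac_snps,batch_shift_snps fraction of SNPs with
#'   batch-dependent call bias and the allele-frequency shift used when
#'   resampling biased calls.
#' @param fst ancestry-cline differentiation of neutral SNPs: each family
#'   has a continuous ancestry coordinate q ~ N(0, 1) (a provenance
#'   gradient) and SNP j's allele frequency for a family is shifted by
#'   sqrt(fst p_j (1 - p_j)) q, so Var over the cline is fst p(1-p).
#'   A breeding population's parents share low-level coancestry even when
#'   pairwise relationships look minimal; this background structure is
#'   what makes genome-wide marker similarity informative about breeding
#'   values. `fst = 0` gives fully exchangeable families.
#' @param causal_fst cline differentiation at causal SNPs (default larger
#'   than neutral `fst`): directional selection shifts trait-locus allele
#'   frequencies along the cline more than drift shifts neutral loci.
#' @param ancestry_bv_sd SD of the ancestry-aligned polygenic background
#'   added to breeding values (the assayed SNPs capture only part of the
#'   genetic variance; the remainder co-varies with genome-wide ancestry).
#' @param ld_block,ld_noise linkage structure: SNPs come in blocks of
#'   `ld_block` (several SNPs called within the same expressed transcript
#'   are in near-complete LD); each non-lead member copies the block lead's
#'   dosage except with probability `ld_noise`, where it is drawn from its
#'   own frequency. `ld_block = 1` gives independent SNPs.
#' @param hwe_f heterozygote-deficit parameter in [0, 1]: with probability
#'   `hwe_f` a family's dosage call is homozygous-like (0 or 2 with
#'   probability 1-p, p), otherwise Binomial(2, p). Family genotypes called
#'   from pooled-seedling alignments are heterozygote-deficient relative to
#'   Hardy-Weinberg, inflating the dosage variance/mean ratio above 1;
#'   `hwe_f = 0` recovers plain Binomial(2, p) sampling.
#' @param dispersion negative-binomial size parameter for replicate counts
#'   (larger = closer to Poisson).
#' @param baseline_mean,baseline_sd log2-scale mean and SD of baseline
#'   transcript expression (expected counts).
#' @param family_noise_sd SD of family-level log2 expression noise.
#' @param module_frac,module_size,module_sd co-expression structure:
#'   a fraction of transcripts is organized into modules of `module_size`
#'   members sharing a family-level latent factor with SD `module_sd` and
#'   random-sign loadings. Bulk transcriptomes are strongly collinear, which
#'   is what correlation pruning exploits.
#' @param libsize_range multiplicative library-size factor range per replicate.
#' @param residual_var variance of the non-SNP component of breeding values.
#' @param seed integer seed; identical seed and config give bit-identical data.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_families_batch = c(45, 11, 22),
                             n_overlap = 5,
                             replicate_probs = c(0.1, 0.3, 0.6),
                             n_transcripts = 10000,
                             n_snps = 10000,
                             n_causal_snps = 100,
                             n_signal_transcripts = 500,
                             effect_scale = 0.1,
                             qtl_frac = 0.1,
                             qtl_boost = 5,
                             expression_slope = 0.2,
                             batch_frac_transcripts = 0.9,
                             batch_sd_transcripts = 1.0,
                             batch_frac_snps = 0.05,
                             batch_shift_snps = 0.3,
                             fst = 0.1,
                             causal_fst = 0.3,
                             ancestry_bv_sd = 0.6,
                             ld_block = 4,
                             ld_noise = 0.15,
                             hwe_f = 0.5,
                             dispersion = 5,
                             baseline_mean = 5,
                             baseline_sd = 2,
                             family_noise_sd = 0.4,
                             module_frac = 0.5,
                             module_size = 10,
                             module_sd = 0.5,
                             libsize_range = c(0.7, 1.3),
                             residual_var = 0.3,
                             seed = 1L) {
  stopifnot(length(n_families_batch) == 3, all(n_families_batch >= 1),
            n_overlap >= 0, n_overlap <= n_families_batch[1],
            length(replicate_probs) == 3, all(replicate_probs >= 0),
            n_transcripts >= 1, n_snps >= 1,
            n_signal_transcripts <= n_transcripts,
            effect_scale >= 0, expression_slope >= 0,
            qtl_frac >= 0, qtl_frac <= 1, qtl_boost >= 1,
            module_frac >= 0, module_frac <= 1, module_size >= 2,
            module_sd >= 0,
            batch_frac_transcripts >= 0, batch_frac_transcripts <= 1,
            batch_frac_snps >= 0, batch_frac_snps <= 1,
            hwe_f >= 0, hwe_f <= 1,
            fst >= 0, fst < 1,
            causal_fst >= 0, causal_fst < 1, ancestry_bv_sd >= 0,
            ld_block >= 1, ld_noise >= 0, ld_noise <= 1,
            dispersion > 0, family_noise_sd >= 0,
            length(libsize_range) == 2, libsize_range[1] > 0,
            residual_var >= 0)
  if (n_causal_snps > n_snps)
    stop("n_causal_snps exceeds n_snps")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate family SNP dosages and breeding values
#'
#' Per SNP j an allele frequency p_j ~ Uniform(0.05, 0.5) is drawn and family
#' dosages g_ij ~ Binomial(2, p_j). The true breeding value of family i is
#' BV_i = sum over causal j of a_j (g_ij - 2 p_j) + e_i with
#' e_i ~ Normal(0, residual_var). For a configured fraction of SNPs the
#' *observed* dosage in one batch is resampled with a batch-shifted allele
#' frequency, emulating platform-dependent genotype-call bias; true breeding
#' values are always computed from the unbiased dosages.
#'
#' The returned truth also carries the transcript-side ground truth (signal
#' transcript IDs and slopes, batch-affected transcript IDs and shifts) that
#' [simulate_expression()] consumes, so that one truth object describes the
#' whole dataset.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `snps` (a [family_features()] dosage matrix),
#'   `phen` (a [phenotypes()] table) and `truth` (hidden parameters).
#' @export
simulate_families <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  nb <- cfg$n_families_batch
  n_fam <- sum(nb)
  fam_ids <- sprintf("F%03d", seq_len(n_fam))
  # batch membership: first nb[1] in batch 1 (the first n_overlap of those
  # also in batch 2), next nb[2] only batch 2, last nb[3] only batch 3
  batches <- vector("list", n_fam)
  for (i in seq_len(n_fam)) {
    if (i <= nb[1]) batches[[i]] <- if (i <= cfg$n_overlap) c("1", "2") else "1"
    else if (i <= nb[1] + nb[2]) batches[[i]] <- "2"
    else batches[[i]] <- "3"
  }
  names(batches) <- fam_ids
  batch_label <- vapply(batches, paste, "", collapse = ",")
  geno_batch <- vapply(batches, `[`, "", 1)  # batch used for genotype calls

  snp_ids <- sprintf("SNP%05d", seq_len(cfg$n_snps))
  p <- runif(cfg$n_snps, 0.05, 0.5)
  # continuous ancestry cline: per-family coordinate q, per-SNP signed
  # cline loading scaled so allele-frequency variance along the cline is
  # fst p(1-p) (causal_fst at causal loci)
  q <- rnorm(n_fam)
  causal <- sort(sample.int(cfg$n_snps, cfg$n_causal_snps))
  fst_of <- rep(cfg$fst, cfg$n_snps)
  fst_of[causal] <- cfg$causal_fst
  cline <- sample(c(-1, 1), cfg$n_snps, replace = TRUE) *
    sqrt(fst_of * p * (1 - p))
  fam_freq <- function(j) pmin(pmax(p[j] + cline[j] * q, 0.01), 0.99)
  # dosage call: Binomial(2, family frequency), with a heterozygote-deficit
  # component (probability hwe_f of a homozygous-like call) emulating
  # genotypes called from pooled-family alignments
  draw_dosage <- function(pvec) {
    n <- length(pvec)
    homo <- runif(n) < cfg$hwe_f
    ifelse(homo, 2 * rbinom(n, 1, pvec), rbinom(n, 2, pvec))
  }
  g_true <- vapply(seq_len(cfg$n_snps),
                   function(j) draw_dosage(fam_freq(j)), numeric(n_fam))
  dimnames(g_true) <- list(fam_ids, snp_ids)
  # LD blocks: consecutive SNPs within a block copy the lead SNP's dosage
  # except for occasional recombination/genotyping discordance
  if (cfg$ld_block > 1) {
    lead <- cfg$ld_block * ((seq_len(cfg$n_snps) - 1) %/% cfg$ld_block) + 1
    for (j in which(lead != seq_len(cfg$n_snps))) {
      keep_own <- runif(n_fam) < cfg$ld_noise
      g_true[!keep_own, j] <- g_true[!keep_own, lead[j]]
    }
  }

  a <- rnorm(cfg$n_causal_snps, 0, cfg$effect_scale)
  # a few moderate QTLs among mostly minor loci
  n_qtl <- max(1L, round(cfg$qtl_frac * cfg$n_causal_snps))
  qtl <- sample.int(cfg$n_causal_snps, n_qtl)
  a[qtl] <- rnorm(n_qtl, 0, cfg$effect_scale * cfg$qtl_boost)
  centered <- sweep(g_true[, causal, drop = FALSE], 2, 2 * p[causal], "-")
  bv <- drop(centered %*% a) + cfg$ancestry_bv_sd * q +
    rnorm(n_fam, 0, sqrt(cfg$residual_var))

  # batch-dependent call bias: biased SNPs are re-called with a shifted
  # frequency for families genotyped in the affected batch
  g_obs <- g_true
  n_biased <- round(cfg$batch_frac_snps * cfg$n_snps)
  biased <- if (n_biased > 0) sort(sample.int(cfg$n_snps, n_biased)) else integer(0)
  biased_batch <- if (n_biased > 0)
    sample(c("1", "2", "3"), n_biased, replace = TRUE) else character(0)
  for (k in seq_along(biased)) {
    j <- biased[k]
    hit <- which(geno_batch == biased_batch[k])
    if (length(hit)) {
      p_shift <- pmin(pmax(fam_freq(j)[hit] + cfg$batch_shift_snps,
                           0.01), 0.99)
      g_obs[hit, j] <- draw_dosage(p_shift)
    }
  }

  # transcript-side truth, consumed by simulate_expression()
  tr_ids <- sprintf("TR%05d", seq_len(cfg$n_transcripts))
  signal <- sort(sample.int(cfg$n_transcripts, cfg$n_signal_transcripts))
  slopes <- rnorm(cfg$n_signal_transcripts, 0, cfg$expression_slope)
  n_batch_tr <- round(cfg$batch_frac_transcripts * cfg$n_transcripts)
  # batch-affected transcripts are drawn from the non-signal pool first:
  # transcripts with stable heritable family signal are the batch-robust
  # fraction the filtering cascade is meant to enrich
  nonsignal <- setdiff(seq_len(cfg$n_transcripts), signal)
  batch_tr <- if (n_batch_tr > 0) {
    if (n_batch_tr <= length(nonsignal)) sort(sample(nonsignal, n_batch_tr))
    else sort(c(nonsignal, sample(signal, n_batch_tr - length(nonsignal))))
  } else integer(0)
  batch_shifts <- matrix(rnorm(3 * n_batch_tr, 0, cfg$batch_sd_transcripts),
                         nrow = n_batch_tr, ncol = 3,
                         dimnames = list(tr_ids[batch_tr], c("1", "2", "3")))
  baseline <- rnorm(cfg$n_transcripts, cfg$baseline_mean, cfg$baseline_sd)
  baseline <- pmax(baseline, 0)
  names(baseline) <- tr_ids

  # co-expression modules: groups of transcripts sharing a family-level
  # latent factor (random-sign loadings)
  n_module_tr <- round(cfg$module_frac * cfg$n_transcripts)
  n_modules <- n_module_tr %/% cfg$module_size
  module_members <- if (n_modules > 0)
    sample.int(cfg$n_transcripts, n_modules * cfg$module_size) else integer(0)
  module_of <- rep(seq_len(n_modules), each = cfg$module_size)
  module_loading <- sample(c(-1, 1), length(module_members), replace = TRUE)

  truth <- list(
    true_bv = setNames(bv, fam_ids),
    causal_snp_ids = snp_ids[causal],
    snp_effects = setNames(a, snp_ids[causal]),
    allele_freqs = setNames(p, snp_ids),
    batch_biased_snp_ids = snp_ids[biased],
    batch_biased_snp_batch = setNames(biased_batch, snp_ids[biased]),
    ancestry = setNames(q, fam_ids),
    signal_transcript_ids = tr_ids[signal],
    signal_slopes = setNames(slopes, tr_ids[signal]),
    batch_affected_transcript_ids = tr_ids[batch_tr],
    batch_shifts = batch_shifts,
    baseline = baseline,
    module_transcript_ids = tr_ids[module_members],
    module_of = module_of,
    module_loading = module_loading,
    n_modules = n_modules,
    family_batches = batches
  )
  list(snps = family_features(g_obs, kind = "snp_dosage", batch = batch_label),
       phen = phenotypes(fam_ids, bv, batch_label),
       truth = truth)
}

#' Simulate replicate-level transcript counts
#'
#' The log2 expected expression of transcript t in family i is
#' baseline_t + b_t z(BV_i) for signal transcripts, plus a per-batch shift
#' for batch-affected transcripts, plus family-level Gaussian noise. Counts
#' for each biological replicate are drawn from a negative binomial with
#' mean libsize_factor * 2^log2mean and the configured dispersion. Families
#' grown in two batches get independent replicates in each batch.
#'
#' @param cfg a [synthetic_config()].
#' @param truth truth object from [simulate_families()].
#' @param phen matching [phenotypes()] table.
#' @return A [replicate_counts()] object.
#' @export
simulate_expression <- function(cfg, truth, phen) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  fam_ids <- phen$family
  bv <- truth$true_bv[fam_ids]
  z <- if (sd(bv) > 0) (bv - mean(bv)) / sd(bv) else bv * 0
  tr_ids <- names(truth$baseline)
  n_tr <- length(tr_ids)

  # family-level log2 expected expression (before batch shifts)
  b <- setNames(numeric(n_tr), tr_ids)
  b[truth$signal_transcript_ids] <- truth$signal_slopes
  fam_noise <- matrix(rnorm(length(fam_ids) * n_tr, 0, cfg$family_noise_sd),
                      nrow = length(fam_ids),
                      dimnames = list(fam_ids, tr_ids))
  log2mean <- outer(z, b) +
    matrix(truth$baseline, nrow = length(fam_ids), ncol = n_tr,
           byrow = TRUE, dimnames = list(fam_ids, tr_ids)) + fam_noise
  if (truth$n_modules > 0) {
    fac <- matrix(rnorm(length(fam_ids) * truth$n_modules, 0, cfg$module_sd),
                  nrow = length(fam_ids))
    log2mean[, truth$module_transcript_ids] <-
      log2mean[, truth$module_transcript_ids] +
      fac[, truth$module_of] * rep(truth$module_loading,
                                   each = length(fam_ids))
  }

  # replicate layout: per family-batch membership, 1-3 replicates
  rep_fam <- character(0); rep_batch <- character(0)
  for (f in fam_ids) {
    for (bt in truth$family_batches[[f]]) {
      k <- sample.int(3, 1, prob = cfg$replicate_probs)
      rep_fam <- c(rep_fam, rep(f, k))
      rep_batch <- c(rep_batch, rep(bt, k))
    }
  }
  rep_ids <- sprintf("%s_b%s_r%d", rep_fam, rep_batch,
                     stats::ave(seq_along(rep_fam),
                                paste(rep_fam, rep_batch), FUN = seq_along))
  shift <- matrix(0, nrow = length(rep_ids), ncol = n_tr,
                  dimnames = list(rep_ids, tr_ids))
  if (length(truth$batch_affected_transcript_ids))
    shift[, truth$batch_affected_transcript_ids] <-
      truth$batch_shifts[, rep_batch, drop = FALSE] |> t()
  lib <- runif(length(rep_ids), cfg$libsize_range[1], cfg$libsize_range[2])
  mu <- lib * 2^(log2mean[rep_fam, , drop = FALSE] + shift)
  counts <- matrix(rnbinom(length(mu), size = cfg$dispersion, mu = mu),
                   nrow = nrow(mu), dimnames = list(rep_ids, tr_ids))
  replicate_counts(counts,
                   family = setNames(rep_fam, rep_ids),
                   batch = setNames(rep_batch, rep_ids))
}

#' Simulate a complete dataset (SNPs, phenotypes, counts, truth)
#'
#' Convenience wrapper chaining [simulate_families()] and
#' [simulate_expression()].
#'
#' @param cfg a [synthetic_config()].
#' @return list with `counts`, `snps`, `phen`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  fam <- simulate_families(cfg)
  counts <- simulate_expression(cfg, fam$truth, fam$phen)
  list(counts = counts, snps = fam$snps, phen = fam$phen, truth = fam$truth)
}
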