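# ALL/setA/setB/setC feature-selection cascades for transcripts and SNPs:
# batch ANOVA with local-FDR adjustment, relative variance, greedy
# correlation pruning, and phenotype-association screens.

#' Filter report
#'
#' Bookkeeping record attached (as attribute `filter_report`) to every
#' filtered matrix: stage label, feature counts in/out, removed IDs, and the
#' parameters used.
#'
#' @param stage stage label.
#' @param n_in,n_out feature counts before and after.
#' @param removed character vector of removed feature IDs.
#' @param params named list of parameters used.
#' @return list of class `filter_report`.
#' @export
filter_report <- function(stage, n_in, n_out, removed, params = list()) {
  stopifnot(n_out <= n_in, length(removed) == n_in - n_out)
  structure(list(stage = stage, n_in = n_in, n_out = n_out,
                 removed = removed, params = params),
            class = "filter_report")
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report [%s]: %d -> %d features\n",
              x$stage, x$n_in, x$n_out))
  invisible(x)
}

#' One-way ANOVA F-test
#'
#' Classical between/within mean-squares F-test across k groups. When every
#' group mean equals the overall mean and there is no within-group
#' variation, F is 0/0; the convention p = 1 is used so that batch filters
#' never remove perfectly flat features.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return list with `statistic` (F), `p_value`, `df1`, `df2`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n_k <- lengths(groups)
  if (any(n_k < 1)) stop("empty group")
  n <- sum(n_k); k <- length(groups)
  if (n <= k) stop("total sample size must exceed the number of groups")
  y <- unlist(groups, use.names = FALSE)
  gm <- mean(y)
  means <- vapply(groups, mean, 0)
  ssb <- sum(n_k * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1; df2 <- n - k
  if (ssw == 0 && ssb == 0)
    return(list(statistic = 0, p_value = 1, df1 = df1, df2 = df2))
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p_value = pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

# vectorized one-way ANOVA p-values for every column of `x` grouped by `g`
.column_anova_p <- function(x, g) {
  g <- as.factor(g)
  n <- nrow(x); k <- nlevels(g)
  stopifnot(k >= 2, n > k)
  n_k <- as.vector(table(g))
  gmeans <- rowsum(x, g) / n_k                 # k x p group means
  grand <- colMeans(x)
  ssb <- colSums(n_k * sweep(gmeans, 2, grand)^2)
  sst <- colSums(sweep(x, 2, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ssw == 0 & ssb <= 1e-24] <- 1  # flat feature convention
  p[ssw == 0 & ssb > 1e-24] <- 0
  p
}

#' Two-groups local false discovery rate
#'
#' Empirical-Bayes lfdr: the null proportion pi0 is estimated on the grid
#' lambda = 0.05, 0.10, ..., 0.95 via pi0(lambda) = mean(p > lambda) /
#' (1 - lambda) and extrapolated to lambda -> 1 with a cubic smoothing
#' spline; the marginal density of probit-transformed p-values is estimated
#' with a Gaussian kernel; lfdr_i = min(1, pi0 f0(z_i) / f(z_i)) with f0 the
#' standard normal density. The result is regularized to be monotone
#' non-increasing as p decreases.
#'
#' @param p numeric p-values in [0, 1]; at least 2 distinct values, and at
#'   least 100 recommended (warns below).
#' @param pi0_lambda grid for the pi0 estimate.
#' @param adjust kernel bandwidth adjustment for the density estimate.
#' @return list with `lfdr` (same length/order as `p`) and `pi0`.
#' @export
estimate_lfdr <- function(p, pi0_lambda = seq(0.05, 0.95, by = 0.05),
                          adjust = 1.5) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (length(unique(p)) < 2) stop("need at least 2 distinct p-values")
  if (length(p) < 100)
    warning("lfdr estimation is unreliable with fewer than 100 p-values")
  pi0_l <- vapply(pi0_lambda, function(l) mean(p > l) / (1 - l), 0)
  sp <- smooth.spline(pi0_lambda, pi0_l, df = 3)
  pi0 <- predict(sp, x = max(pi0_lambda))$y
  pi0 <- min(max(pi0, 1e-8), 1)
  eps <- 1e-15
  z <- qnorm(pmin(pmax(p, eps), 1 - eps))
  d <- density(z, adjust = adjust)
  ds <- smooth.spline(d$x, d$y)
  f <- pmax(predict(ds, x = z)$y, 1e-12)
  lfdr <- pmin(pi0 * dnorm(z) / f, 1)
  o <- order(p)
  lfdr[o] <- cummax(lfdr[o])  # non-decreasing in p
  lfdr <- pmin(pmax(lfdr, 0), 1)
  list(lfdr = lfdr, pi0 = pi0)
}

# families grown in more than one batch are confounded with batch and are
# excluded from batch ANOVAs (they stay in the returned matrices)
.single_batch_mask <- function(batch) !grepl(",", batch, fixed = TRUE)

#' Batch-effect filter for transcripts (setA)
#'
#' Per-transcript one-way ANOVA of family-mean log2 expression by batch,
#' computed on families grown in a single batch only (multi-batch families
#' are confounded with batch and are left out of the test, but kept in the
#' returned matrix). P-values are adjusted by local FDR (or BH) and
#' transcripts with adjusted value below the cutoff are removed.
#'
#' @param fm a `transcript_log2` [family_features()] with batch labels.
#' @param cfg a [run_config()].
#' @return filtered [family_features()] with `filter_report` attribute; the
#'   report's params carry the raw and adjusted values.
#' @export
batch_filter_transcripts <- function(fm, cfg = run_config()) {
  stopifnot(inherits(fm, "family_features"), fm$kind == "transcript_log2",
            !is.null(fm$batch))
  mask <- .single_batch_mask(fm$batch)
  p <- .column_anova_p(fm$values[mask, , drop = FALSE], fm$batch[mask])
  adj <- if (cfg$adjust_method == "lfdr") estimate_lfdr(p)$lfdr
         else stats::p.adjust(p, "BH")
  keep <- adj >= cfg$lfdr_cutoff
  out <- family_features(fm$values[, keep, drop = FALSE], fm$kind, fm$batch)
  attr(out, "filter_report") <- filter_report(
    "setA_batch", ncol(fm$values), sum(keep), colnames(fm$values)[!keep],
    params = list(cutoff = cfg$lfdr_cutoff, method = cfg$adjust_method,
                  p_raw = p, p_adjusted = adj))
  out
}

#' Batch-effect filter for SNPs (the SNP ALL set)
#'
#' Per-SNP one-way ANOVA of dosage by batch (single-batch families only);
#' SNPs with unadjusted p below the cutoff are removed — no multiple-testing
#' correction, following the SNP-filtering convention of the cascades.
#'
#' @param fm a `snp_dosage` [family_features()] with batch labels.
#' @param alpha unadjusted p cutoff (default 0.05).
#' @return filtered [family_features()] with `filter_report` attribute.
#' @export
batch_filter_snps <- function(fm, alpha = 0.05) {
  stopifnot(inherits(fm, "family_features"), fm$kind == "snp_dosage",
            !is.null(fm$batch))
  mask <- .single_batch_mask(fm$batch)
  p <- .column_anova_p(fm$values[mask, , drop = FALSE], fm$batch[mask])
  keep <- p >= alpha
  out <- family_features(fm$values[, keep, drop = FALSE], fm$kind, fm$batch)
  attr(out, "filter_report") <- filter_report(
    "ALL_snp_batch", ncol(fm$values), sum(keep), colnames(fm$values)[!keep],
    params = list(alpha = alpha, p_raw = p))
  out
}

#' Relative-variance filter for SNPs (setA)
#'
#' Keeps SNPs whose sample variance of dosages divided by the mean dosage
#' exceeds the cutoff (strict >). The variance uses the n-1 denominator.
#'
#' @param fm a `snp_dosage` [family_features()].
#' @param cutoff ratio cutoff (default 1).
#' @return filtered [family_features()] with `filter_report` attribute.
#' @export
relative_variance_filter <- function(fm, cutoff = 1) {
  stopifnot(inherits(fm, "family_features"), fm$kind == "snp_dosage")
  m <- colMeans(fm$values)
  if (any(m == 0)) stop("SNPs with zero mean dosage must be excluded upstream")
  v <- apply(fm$values, 2, var)
  keep <- v / m > cutoff
  out <- family_features(fm$values[, keep, drop = FALSE], fm$kind, fm$batch)
  attr(out, "filter_report") <- filter_report(
    "setA_relvar", ncol(fm$values), sum(keep), colnames(fm$values)[!keep],
    params = list(cutoff = cutoff, ratio = v / m))
  out
}

#' Greedy correlation pruning (setB)
#'
#' Removes collinear features: while any feature pair has |Pearson r| above
#' the cutoff, the pair with the largest |r| is found and the member with the
#' larger mean absolute correlation to all remaining features is removed
#' (ties broken by removing the later column). A cutoff of 0.5 corresponds
#' to one feature explaining more than 25% of another's variance.
#'
#' @param fm a [family_features()] object with >= 2 features.
#' @param r_cutoff cutoff on |r| (default 0.5).
#' @return filtered [family_features()] with `filter_report` attribute.
#' @export
correlation_prune <- function(fm, r_cutoff = 0.5) {
  stopifnot(inherits(fm, "family_features"))
  if (ncol(fm$values) < 2) stop("need at least 2 features to prune")
  cc <- abs(cor(fm$values))
  cc[!is.finite(cc)] <- 0  # zero-variance features correlate with nothing
  removed <- greedy_prune_cpp(cc, r_cutoff)  # 1-based removal order
  keep <- setdiff(seq_len(ncol(cc)), removed)
  out <- family_features(fm$values[, keep, drop = FALSE], fm$kind, fm$batch)
  attr(out, "filter_report") <- filter_report(
    "setB_prune", ncol(fm$values), length(keep),
    colnames(fm$values)[removed], params = list(r_cutoff = r_cutoff))
  out
}

#' Phenotype-correlation screen for transcripts (setC)
#'
#' Keeps transcripts whose Spearman correlation with the training-family
#' breeding values exceeds the cutoff in absolute value (strict >). Only the
#' training phenotypes are accepted, so test phenotypes cannot leak into the
#' screen. Constant features get r = 0 and are removed.
#'
#' @param fm a `transcript_log2` [family_features()] (all families).
#' @param phen_train [phenotypes()] restricted to the training families.
#' @param r_cutoff cutoff on |Spearman r| (default 0.05).
#' @return filtered [family_features()] with `filter_report` attribute.
#' @export
phenotype_screen_transcripts <- function(fm, phen_train, r_cutoff = 0.05) {
  stopifnot(inherits(fm, "family_features"), fm$kind == "transcript_log2",
            inherits(phen_train, "phenotypes"))
  ids <- intersect(phen_train$family, rownames(fm$values))
  if (length(ids) < 3) stop("need >= 3 training families")
  x <- fm$values[ids, , drop = FALSE]
  bv <- phen_train$bv[match(ids, phen_train$family)]
  rs <- .rank_standardize(x)
  rb <- .rank_standardize(matrix(bv, ncol = 1))
  r <- drop(crossprod(rs$z, rb$z))
  r[rs$degenerate | rb$degenerate] <- 0
  keep <- abs(r) > r_cutoff
  out <- family_features(fm$values[, keep, drop = FALSE], fm$kind, fm$batch)
  attr(out, "filter_report") <- filter_report(
    "setC_phen", ncol(fm$values), sum(keep), colnames(fm$values)[!keep],
    params = list(r_cutoff = r_cutoff, r = r))
  out
}

#' Phenotype-association screen for SNPs (setC)
#'
#' Per SNP, a one-way ANOVA of training-family breeding values grouped by
#' dosage class {0, 1, 2}; SNPs with unadjusted p below alpha are kept.
#' Empty dosage classes are dropped from a SNP's test; SNPs with fewer than
#' two non-empty classes (or no residual degrees of freedom) are removed as
#' untestable.
#'
#' @param fm a `snp_dosage` [family_features()] (all families).
#' @param phen_train [phenotypes()] restricted to the training families.
#' @param alpha unadjusted p cutoff (default 0.05).
#' @return filtered [family_features()] with `filter_report` attribute.
#' @export
phenotype_screen_snps <- function(fm, phen_train, alpha = 0.05) {
  stopifnot(inherits(fm, "family_features"), fm$kind == "snp_dosage",
            inherits(phen_train, "phenotypes"))
  ids <- intersect(phen_train$family, rownames(fm$values))
  if (length(ids) < 3) stop("need >= 3 training families")
  x <- fm$values[ids, , drop = FALSE]
  bv <- phen_train$bv[match(ids, phen_train$family)]
  p <- apply(x, 2, function(dos) {
    cls <- split(bv, dos)
    cls <- cls[lengths(cls) > 0]
    if (length(cls) < 2 || length(bv) <= length(cls)) return(NA_real_)
    one_way_anova(cls)$p_value
  })
  keep <- !is.na(p) & p < alpha
  out <- family_features(fm$values[, keep, drop = FALSE], fm$kind, fm$batch)
  attr(out, "filter_report") <- filter_report(
    "setC_snp_phen", ncol(fm$values), sum(keep), colnames(fm$values)[!keep],
    params = list(alpha = alpha, p = p))
  out
}
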