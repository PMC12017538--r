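# Shared fixtures and independent oracles built in code.

# small multi-batch synthetic configuration for fast tests
small_cfg <- function(seed = 1, ...) {
  synthetic_config(n_families_batch = c(20, 6, 10), n_overlap = 3,
                   n_transcripts = 300, n_snps = 300, n_causal_snps = 30,
                   n_signal_transcripts = 30, seed = seed, ...)
}

# hand-written replicate count fixture: 4 replicates, 2 families, 2 batches
tiny_counts <- function() {
  m <- matrix(c(0L, 5L, 8L,
                2L, 0L, 1L,
                3L, 5L, 2L,
                1L, 1L, 9L), nrow = 4, byrow = TRUE,
              dimnames = list(c("r1", "r2", "r3", "r4"),
                              c("t1", "t2", "t3")))
  replicate_counts(m,
                   family = c(r1 = "A", r2 = "A", r3 = "B", r4 = "B"),
                   batch = c(r1 = "1", r2 = "1", r3 = "2", r4 = "2"))
}

# independent Spearman oracle for tie-free vectors: 1 - 6 sum d^2 / (n(n^2-1))
spearman_formula_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# independent re-implementation of the greedy correlation-pruning rule
greedy_prune_oracle <- function(x, cutoff) {
  cc <- abs(cor(x))
  cc[!is.finite(cc)] <- 0
  active <- seq_len(ncol(cc))
  removed <- integer(0)
  repeat {
    if (length(active) < 2) break
    sub <- cc[active, active, drop = FALSE]
    diag(sub) <- -Inf
    if (max(sub) <= cutoff) break
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    i <- active[idx[1]]; j <- active[idx[2]]
    mi <- mean(cc[i, setdiff(active, i)])
    mj <- mean(cc[j, setdiff(active, j)])
    drop_ <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    removed <- c(removed, drop_)
    active <- setdiff(active, drop_)
  }
  sort(active)
}

# write a small VCF v4.2 text file; rows is a list of character vectors
# c(CHROM, POS, REF, ALT, QUAL, gt1, gt2, ...)
write_tiny_vcf <- function(rows, samples, path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(rows, function(r)
    paste(c(r[1], r[2], ".", r[3], r[4], r[5], ".", ".", "GT",
            r[-(1:5)]), collapse = "\t"), "")
  writeLines(c(hdr, body), path)
  path
}

# random symmetric positive-definite matrix with family dimnames
random_spd <- function(n, ids = sprintf("F%02d", seq_len(n))) {
  a <- matrix(rnorm(n * n), n)
  s <- crossprod(a) / n + diag(n) * 0.5
  dimnames(s) <- list(ids, ids)
  s
}
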