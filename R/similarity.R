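# Family-by-family similarity: Pearson correlation across standardized
# features, and the VanRaden (method 1) genomic relationship matrix.

#' Pearson similarity matrix across families
#'
#' Each feature is centered and scaled to unit variance across families;
#' the similarity of two families is the mean product of their standardized
#' feature values, i.e. the Pearson correlation of their (standardized)
#' feature profiles. Zero-variance features carry no similarity information
#' and are dropped with a warning. Standardization can be disabled, in which
#' case the plain Pearson correlation of raw family rows is used.
#'
#' @param fm a [family_features()] object.
#' @param standardize center/scale features before correlating (default TRUE).
#' @return list of class `similarity_matrix` with `entries` (symmetric,
#'   unit diagonal), `source_kind`, `n_features`.
#' @export
pearson_similarity <- function(fm, standardize = TRUE) {
  stopifnot(inherits(fm, "family_features"))
  x <- fm$values
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance feature(s) dropped")
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need at least 2 features with nonzero variance")
  if (standardize) x <- scale(x)
  s <- suppressWarnings(cor(t(x)))
  if (anyNA(s)) {
    warning(sum(rowSums(is.na(s)) > 0),
            " constant family profile(s): undefined correlations set to 0")
    s[is.na(s)] <- 0
  }
  s <- (s + t(s)) / 2
  diag(s) <- 1
  structure(list(entries = s, source_kind = fm$kind, n_features = ncol(x)),
            class = "similarity_matrix")
}

#' @exportS3Method base::print
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix [%s]: %d families, %d features\n",
              x$source_kind, nrow(x$entries), x$n_features))
  invisible(x)
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' G = M M' / (2 * sum_j p_j (1 - p_j)) where M is the dosage matrix with
#' column j centered by 2 p_j and p_j is the alternate-allele frequency of
#' SNP j estimated from the input families. Monomorphic SNPs (p = 0 or 1)
#' are excluded with a warning. Centering by the alternate rather than the
#' minor allele only flips column signs of M and leaves G unchanged.
#'
#' @param fm a `snp_dosage` [family_features()] object.
#' @param allele_freqs optional externally supplied alternate-allele
#'   frequencies (named by SNP); by default estimated in-sample.
#' @return list of class `grm` with `entries`, `allele_freqs`, `denominator`.
#' @export
vanraden_grm <- function(fm, allele_freqs = NULL) {
  stopifnot(inherits(fm, "family_features"), fm$kind == "snp_dosage")
  x <- fm$values
  p <- if (is.null(allele_freqs)) colMeans(x) / 2
       else allele_freqs[colnames(x)]
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs monomorphic: GRM undefined")
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic SNP(s) excluded from GRM")
    x <- x[, poly, drop = FALSE]
    p <- p[poly]
  }
  m <- sweep(x, 2, 2 * p, "-")
  denom <- 2 * sum(p * (1 - p))
  g <- tcrossprod(m) / denom
  g <- (g + t(g)) / 2
  structure(list(entries = g, allele_freqs = p, denominator = denom),
            class = "grm")
}

#' @exportS3Method base::print
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d families, %d SNPs, mean diagonal %.3f\n",
              nrow(x$entries), length(x$allele_freqs), mean(diag(x$entries))))
  invisible(x)
}

#' Train-versus-test relationship entries of a GRM
#'
#' Flat list of G[i, j] for i in the training set and j in the test set,
#' with summary quantiles — the data behind a train/test relationship
#' histogram.
#'
#' @param g a [vanraden_grm()] object.
#' @param train_ids,test_ids disjoint family ID sets present in `g`.
#' @return list with `values` (length |train| * |test|) and `quantiles`.
#' @export
grm_cross_entries <- function(g, train_ids, test_ids) {
  stopifnot(inherits(g, "grm"))
  if (length(intersect(train_ids, test_ids)))
    stop("train and test family sets overlap")
  miss <- setdiff(c(train_ids, test_ids), rownames(g$entries))
  if (length(miss)) stop("families absent from GRM: ", paste(miss, collapse = ", "))
  vals <- as.vector(g$entries[train_ids, test_ids, drop = FALSE])
  list(values = vals,
       quantiles = quantile(vals, c(0, 0.25, 0.5, 0.75, 1)))
}
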