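# Replicate-to-family aggregation, low-expression filtering, and
# rank-correlation reproducibility summaries.

#' Family-mean log2 expression
#'
#' For each family and transcript, takes the mean of raw counts across the
#' family's biological replicates, adds one (so that zero counts map to
#' zero), and applies log2. The order is fixed: mean of raw counts first,
#' then +1, then log2.
#'
#' @param rc a [replicate_counts()] object.
#' @return A [family_features()] object with `kind = "transcript_log2"`.
#'   Families grown in several batches get a comma-separated batch label.
#' @export
family_mean_log2 <- function(rc) {
  stopifnot(inherits(rc, "replicate_counts"))
  fam <- rc$family
  fams <- unique(fam)
  means <- rowsum(rc$counts, group = fam, reorder = FALSE) /
    as.vector(table(fam)[unique(fam)])
  vals <- log2(means + 1)
  rownames(vals) <- fams
  fb <- vapply(fams, function(f)
    paste(sort(unique(rc$batch[fam == f])), collapse = ","), "")
  family_features(vals, kind = "transcript_log2", batch = fb)
}

#' Low-expression filter
#'
#' Keeps transcripts whose mean log2 family-mean expression across all
#' families is at least `min_mean_log2` (inclusive).
#'
#' @param fm a `transcript_log2` [family_features()] object.
#' @param min_mean_log2 threshold on the log2 scale (default 3).
#' @return A filtered [family_features()] object with a `filter_report`
#'   attribute (see [filter_report()]).
#' @export
low_expression_filter <- function(fm, min_mean_log2 = 3) {
  stopifnot(inherits(fm, "family_features"), fm$kind == "transcript_log2")
  m <- colMeans(fm$values)
  keep <- m >= min_mean_log2
  if (!any(keep)) warning("low-expression filter removed every transcript")
  out <- family_features(fm$values[, keep, drop = FALSE],
                         kind = fm$kind, batch = fm$batch)
  attr(out, "filter_report") <- filter_report(
    stage = "low_expression", n_in = ncol(fm$values), n_out = sum(keep),
    removed = colnames(fm$values)[!keep],
    params = list(min_mean_log2 = min_mean_log2))
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of the average-rank transforms of the two vectors
#' (ties receive average ranks). A constant vector makes the correlation
#' undefined; by convention 0 is returned with attribute
#' `degenerate = TRUE` so that all-pairs reports never abort.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1]; attribute `degenerate` flags undefined
#'   cases.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(structure(0, degenerate = TRUE))
  structure(cor(rx, ry), degenerate = FALSE)
}

# rank-transform columns and scale to unit norm so crossprod gives all
# pairwise Spearman correlations in one pass; constant columns flagged
.rank_standardize <- function(m) {
  r <- apply(m, 2, rank)
  ctr <- sweep(r, 2, colMeans(r))
  ss <- sqrt(colSums(ctr^2))
  degen <- ss == 0
  ss[degen] <- 1
  list(z = sweep(ctr, 2, ss, "/"), degenerate = degen)
}

#' Replicate reproducibility report
#'
#' Pairwise Spearman correlations of log2(count + 1) across all transcripts,
#' split into four categories: replicate pairs within a family (same batch),
#' replicate pairs among different families within a batch, replicate pairs
#' across batches, and pairwise correlations of family-mean log2 counts.
#' Uses every transcript present, unfiltered.
#'
#' @param rc a [replicate_counts()] object.
#' @return data.frame with columns `id1`, `id2`, `category`, `r`. Categories
#'   with fewer than one pair are omitted with a warning.
#' @export
reproducibility_report <- function(rc) {
  stopifnot(inherits(rc, "replicate_counts"))
  lg <- log2(t(rc$counts) + 1)  # transcripts x replicates
  rs <- .rank_standardize(lg)
  cc <- crossprod(rs$z)
  cc[rs$degenerate, ] <- 0; cc[, rs$degenerate] <- 0
  reps <- colnames(lg)
  fam <- rc$family[reps]; bat <- rc$batch[reps]
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  same_fam <- fam[idx[, 1]] == fam[idx[, 2]]
  same_bat <- bat[idx[, 1]] == bat[idx[, 2]]
  category <- ifelse(!same_bat, "cross_batch",
                     ifelse(same_fam, "within_family", "among_family"))
  out <- data.frame(id1 = reps[idx[, 1]], id2 = reps[idx[, 2]],
                    category = category, r = cc[idx],
                    stringsAsFactors = FALSE)
  # family-mean pairwise correlations
  fm <- family_mean_log2(rc)
  if (nrow(fm$values) >= 2) {
    rsf <- .rank_standardize(t(fm$values))
    cf <- crossprod(rsf$z)
    cf[rsf$degenerate, ] <- 0; cf[, rsf$degenerate] <- 0
    fi <- which(upper.tri(cf), arr.ind = TRUE)
    fams <- rownames(fm$values)
    out <- rbind(out, data.frame(id1 = fams[fi[, 1]], id2 = fams[fi[, 2]],
                                 category = "family_mean", r = cf[fi],
                                 stringsAsFactors = FALSE))
  }
  expected <- c("within_family", "among_family", "cross_batch", "family_mean")
  absent <- setdiff(expected, unique(out$category))
  if (length(absent))
    warning("categories with no pairs omitted: ", paste(absent, collapse = ", "))
  out
}
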