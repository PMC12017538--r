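# Domain containers and plain-text interchange (TSV matrices, VCF genotypes).

#' Replicate-level transcript count matrix
#'
#' Container for raw RNA-seq read counts per biological replicate, together
#' with the replicate-to-family and replicate-to-batch maps. Rows are
#' biological replicates, columns are transcripts.
#'
#' @param counts non-negative integer matrix; rownames are replicate IDs,
#'   colnames are transcript IDs.
#' @param family named character vector mapping replicate ID to family ID.
#' @param batch named character vector mapping replicate ID to batch label.
#' @return An object of class `replicate_counts`.
#' @export
replicate_counts <- function(counts, family, batch) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have replicate rownames and transcript colnames")
  if (anyDuplicated(colnames(counts)))
    stop("transcript IDs must be unique")
  if (anyDuplicated(rownames(counts)))
    stop("replicate IDs must be unique")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  reps <- rownames(counts)
  missing_fam <- setdiff(reps, names(family))
  missing_bat <- setdiff(reps, names(batch))
  if (length(missing_fam) || length(missing_bat))
    stop("replicates absent from family/batch map: ",
         paste(union(missing_fam, missing_bat), collapse = ", "))
  structure(list(counts = counts,
                 family = as.character(family[reps]) |> setNames(reps),
                 batch  = as.character(batch[reps])  |> setNames(reps)),
            class = "replicate_counts")
}

#' @exportS3Method base::print
print.replicate_counts <- function(x, ...) {
  cat(sprintf("replicate_counts: %d replicates x %d transcripts, %d families, %d batches\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$family)), length(unique(x$batch))))
  invisible(x)
}

#' Family-level feature matrix
#'
#' Families by features: either log2 family-mean transcript expression
#' (`kind = "transcript_log2"`) or SNP alternate-allele dosages in {0,1,2}
#' (`kind = "snp_dosage"`).
#'
#' @param values numeric matrix; rownames are family IDs, colnames feature IDs.
#' @param kind `"transcript_log2"` or `"snp_dosage"`.
#' @param batch named character vector mapping family ID to batch label.
#'   Families present in more than one batch carry a comma-separated label
#'   (see [make_split()]).
#' @return An object of class `family_features`.
#' @export
family_features <- function(values, kind = c("transcript_log2", "snp_dosage"),
                            batch = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("values must have family rownames and feature colnames")
  if (anyDuplicated(rownames(values))) stop("family IDs must be unique")
  if (any(!is.finite(values))) stop("feature matrix contains missing/non-finite entries")
  if (kind == "snp_dosage" && !all(values %in% c(0, 1, 2)))
    stop("snp_dosage values must all be in {0, 1, 2}")
  if (!is.null(batch)) {
    miss <- setdiff(rownames(values), names(batch))
    if (length(miss)) stop("families absent from batch map: ", paste(miss, collapse = ", "))
    batch <- as.character(batch[rownames(values)]) |> setNames(rownames(values))
  }
  structure(list(values = values, kind = kind, batch = batch),
            class = "family_features")
}

#' @exportS3Method base::print
print.family_features <- function(x, ...) {
  cat(sprintf("family_features [%s]: %d families x %d features\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Family phenotype table
#'
#' One breeding value per family, with the family's batch label.
#'
#' @param family character vector of family IDs.
#' @param bv numeric breeding values (one per family).
#' @param batch batch label per family.
#' @return A `data.frame` of class `phenotypes` with columns
#'   `family`, `bv`, `batch`.
#' @export
phenotypes <- function(family, bv, batch) {
  family <- as.character(family)
  if (anyDuplicated(family)) stop("one breeding value per family required")
  if (length(bv) != length(family) || length(batch) != length(family))
    stop("family, bv, batch must have equal length")
  if (any(!is.finite(bv))) stop("breeding values must be finite")
  structure(data.frame(family = family, bv = as.numeric(bv),
                       batch = as.character(batch), stringsAsFactors = FALSE),
            class = c("phenotypes", "data.frame"))
}

#' Pipeline configuration with the study's default thresholds
#'
#' Collects every tunable threshold of the filtering cascades and the
#' prediction models. Defaults: low-expression cutoff of 3 on the log2
#' family-mean scale; lfdr < 0.05 removal for transcript batch effects;
#' correlation pruning at |r| > 0.5 (features explaining > 25% of another's
#' variance); transcript-phenotype screen |r| > 0.05; SNP batch and phenotype
#' ANOVA at unadjusted p < 0.05; relative variance > 1; kriging weight
#' theta = 1; elastic-net grid alpha 0.1..0.9 by 0.1, lambda {1, 0.1, 0.01,
#' 0.001}, 25 bootstraps.
#'
#' @param min_mean_log2 low-expression threshold on the log2 family-mean scale.
#' @param lfdr_cutoff transcripts with adjusted batch-ANOVA value below this
#'   are removed.
#' @param prune_r correlation-pruning cutoff on |r|.
#' @param transcript_phen_r phenotype-screen cutoff on |Spearman r|.
#' @param snp_batch_alpha unadjusted ANOVA p cutoff for the SNP batch filter.
#' @param snp_phen_alpha unadjusted ANOVA p cutoff for the SNP phenotype screen.
#' @param rel_var_cutoff relative-variance (variance/mean dosage) cutoff.
#' @param theta kriging similarity weight in [0, 1].
#' @param alpha_grid,lambda_grid elastic-net tuning grids.
#' @param n_bootstrap bootstrap resamples used during grid tuning.
#' @param standardize_features standardize features before building the
#'   kriging similarity matrix (default FALSE: the similarity of two
#'   families is the plain Pearson correlation of their feature profiles,
#'   the construction whose family-by-family values the multi-batch study
#'   design reports; see [pearson_similarity()]).
#' @param adjust_method `"lfdr"` (two-groups local FDR) or `"BH"`.
#' @param seed integer seed used by stochastic stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(min_mean_log2 = 3,
                       lfdr_cutoff = 0.05,
                       prune_r = 0.5,
                       transcript_phen_r = 0.05,
                       snp_batch_alpha = 0.05,
                       snp_phen_alpha = 0.05,
                       rel_var_cutoff = 1,
                       theta = 1,
                       alpha_grid = seq(0.1, 0.9, by = 0.1),
                       lambda_grid = c(1, 0.1, 0.01, 0.001),
                       n_bootstrap = 25,
                       standardize_features = FALSE,
                       adjust_method = c("lfdr", "BH"),
                       seed = 1L) {
  adjust_method <- match.arg(adjust_method)
  stopifnot(min_mean_log2 >= 0, lfdr_cutoff > 0, lfdr_cutoff < 1,
            prune_r > 0, prune_r <= 1, transcript_phen_r >= 0,
            snp_batch_alpha > 0, snp_batch_alpha < 1,
            snp_phen_alpha > 0, snp_phen_alpha < 1,
            rel_var_cutoff >= 0, theta >= 0, theta <= 1,
            all(alpha_grid >= 0 & alpha_grid <= 1), all(lambda_grid >= 0),
            n_bootstrap >= 1)
  structure(list(min_mean_log2 = min_mean_log2, lfdr_cutoff = lfdr_cutoff,
                 prune_r = prune_r, transcript_phen_r = transcript_phen_r,
                 snp_batch_alpha = snp_batch_alpha,
                 snp_phen_alpha = snp_phen_alpha,
                 rel_var_cutoff = rel_var_cutoff, theta = theta,
                 alpha_grid = alpha_grid, lambda_grid = lambda_grid,
                 n_bootstrap = n_bootstrap,
                 standardize_features = isTRUE(standardize_features),
                 adjust_method = adjust_method,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a replicate-level count matrix from TSV
#'
#' The matrix file is UTF-8 TSV with a header row of transcript IDs and the
#' replicate ID in the first column. The map file has columns
#' `replicate`, `family`, `batch`.
#'
#' @param path TSV count matrix.
#' @param map_path TSV replicate-to-family/batch map.
#' @return A [replicate_counts()] object.
#' @export
read_count_matrix <- function(path, map_path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE, comment.char = "")
  if (ncol(df) == 0) stop("count matrix has no transcript columns (missing header?)")
  if (!all(vapply(df, is.numeric, NA))) stop("non-numeric count entries")
  m <- as.matrix(df)
  map <- read.table(map_path, header = TRUE, sep = "\t",
                    colClasses = "character", comment.char = "")
  need <- c("replicate", "family", "batch")
  if (!all(need %in% names(map)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  replicate_counts(m,
                   family = setNames(map$family, map$replicate),
                   batch  = setNames(map$batch, map$replicate))
}

#' Write a replicate-level count matrix to TSV
#'
#' Inverse of [read_count_matrix()]; writes the matrix and its
#' replicate map.
#'
#' @param rc a [replicate_counts()] object.
#' @param path,map_path output TSV paths.
#' @export
write_count_matrix <- function(rc, path, map_path) {
  stopifnot(inherits(rc, "replicate_counts"))
  .write_tsv_matrix(rc$counts, path, id_col = "replicate")
  map <- data.frame(replicate = rownames(rc$counts),
                    family = unname(rc$family), batch = unname(rc$batch))
  write.table(map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a family-level feature matrix from TSV
#'
#' @param path TSV with header row of feature IDs, family ID in column one.
#' @param kind feature kind, as in [family_features()].
#' @param batch optional named batch map.
#' @return A [family_features()] object.
#' @export
read_feature_matrix <- function(path, kind = c("transcript_log2", "snp_dosage"),
                                batch = NULL) {
  kind <- match.arg(kind)
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE, comment.char = "")
  if (!all(vapply(df, is.numeric, NA))) stop("non-numeric feature entries")
  family_features(as.matrix(df), kind = kind, batch = batch)
}

#' Write a family-level feature matrix to TSV
#'
#' @param fm a [family_features()] object.
#' @param path output TSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "family_features"))
  .write_tsv_matrix(fm$values, path, id_col = "family")
  invisible(NULL)
}

.write_tsv_matrix <- function(m, path, id_col) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  # format(..., digits = 17) keeps doubles lossless to ~1e-16 relative
  body <- apply(m, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
}

#' Read a phenotype table from TSV
#'
#' @param path TSV with columns `family`, `bv`, `batch`.
#' @return A [phenotypes()] object.
#' @export
read_phenotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric", "character"),
                   comment.char = "")
  phenotypes(df$family, df$bv, df$batch)
}

#' Write a phenotype table to TSV
#' @param phen a [phenotypes()] object.
#' @param path output TSV path.
#' @export
write_phenotypes <- function(phen, path) {
  write.table(as.data.frame(phen), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Read family genotypes from a VCF into a dosage matrix
#'
#' Each VCF sample is one family treated as a diploid individual. Sites are
#' restricted to biallelic SNVs and filtered on variant quality (QUAL > 30),
#' minor allele frequency computed across the families (MAF > 0.05), and
#' completeness (no missing genotypes at a retained site). Genotypes are
#' recoded to alternate-allele dosage 0/1/2.
#'
#' @param path VCF v4.x file (uncompressed or bgzipped).
#' @param qual_min minimum QUAL (strict `>`).
#' @param maf_min minimum minor allele frequency (strict `>`).
#' @param batch optional family-to-batch map passed to [family_features()].
#' @return A [family_features()] object with `kind = "snp_dosage"`.
#' @export
read_genotypes_vcf <- function(path, qual_min = 30, maf_min = 0.05,
                               batch = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) stop("VCF has no genotype samples")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  snv <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt, fixed = TRUE)
  multi <- grepl(",", alt, fixed = TRUE) | nchar(ref) != 1 | nchar(alt) != 1
  if (any(multi))
    warning(sum(multi), " non-biallelic-SNV record(s) skipped")
  dosage <- function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(sub(":.*$", "", g), "[/|]")[[1]]
    if (length(al) != 2 || any(!al %in% c("0", "1", "."))) return(NA_real_)
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  keep <- which(snv & !is.na(qual) & qual > qual_min)
  if (!length(keep)) stop("no sites pass the QUAL/SNV filters: empty matrix")
  d <- matrix(NA_real_, nrow = length(keep), ncol = ncol(gt),
              dimnames = list(NULL, colnames(gt)))
  ids <- character(length(keep))
  for (i in seq_along(keep)) {
    r <- keep[i]
    d[i, ] <- vapply(gt[r, ], dosage, numeric(1))
    ids[i] <- paste0(fix[r, "CHROM"], "_", fix[r, "POS"])
  }
  nondip <- is.na(d) & !is.na(gt[keep, , drop = FALSE])
  if (any(nondip))
    warning(sum(rowSums(nondip) > 0), " site(s) with unparseable/non-diploid GT treated as missing")
  complete <- rowSums(is.na(d)) == 0
  p_alt <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  ok <- complete & maf > maf_min
  if (!any(ok)) stop("all sites filtered out (QUAL/MAF/missingness): empty matrix")
  m <- t(d[ok, , drop = FALSE])
  colnames(m) <- ids[ok]
  family_features(m, kind = "snp_dosage", batch = batch)
}
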