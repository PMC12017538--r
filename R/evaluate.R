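# Cross-batch experiment runner and accuracy metrics.

#' Cross-batch train/test split
#'
#' Families grown in a single batch go to training or test according to
#' their batch; families grown in more than one batch are always assigned
#' to the training set (their batch membership overlaps the split), never
#' to the prediction set. Output sets are disjoint.
#'
#' @param phen a [phenotypes()] table; multi-batch families carry a
#'   comma-separated batch label.
#' @param train_batches,test_batches character vectors of batch labels.
#' @return list with `train` and `test` family ID vectors.
#' @export
make_split <- function(phen, train_batches, test_batches) {
  stopifnot(inherits(phen, "phenotypes"),
            !length(intersect(train_batches, test_batches)))
  bsets <- strsplit(phen$batch, ",", fixed = TRUE)
  multi <- lengths(bsets) > 1
  in_train <- vapply(bsets, function(b) any(b %in% train_batches), NA)
  in_test <- vapply(bsets, function(b) all(b %in% test_batches), NA)
  train <- phen$family[in_train | multi]
  test <- setdiff(phen$family[in_test & !multi], train)
  if (!length(test)) stop("empty test set")
  list(train = train, test = test)
}

#' Prediction accuracy (r, p) by simple linear regression
#'
#' Pearson correlation between predicted and observed breeding values, with
#' the two-sided p-value of the simple-regression t-test on n - 2 degrees
#' of freedom. Zero-variance predictions make r undefined: the result is
#' flagged degenerate with r = 0, p = 1.
#'
#' @param pred a [prediction_result()] (or named numeric vector).
#' @param phen a [phenotypes()] table covering the predicted families.
#' @return list with `r`, `p`, `n`, `degenerate`.
#' @export
accuracy <- function(pred, phen) {
  v <- if (inherits(pred, "prediction_result")) pred$pred else pred
  stopifnot(inherits(phen, "phenotypes"))
  ids <- names(v)
  miss <- setdiff(ids, phen$family)
  if (length(miss)) stop("families without phenotypes: ", paste(miss, collapse = ", "))
  obs <- phen$bv[match(ids, phen$family)]
  n <- length(ids)
  if (n < 3) stop("need at least 3 test families")
  if (sd(v) == 0 || sd(obs) == 0)
    return(list(r = 0, p = 1, n = n, degenerate = TRUE))
  r <- cor(v, obs)
  tstat <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE), n = n,
       degenerate = FALSE)
}

#' Compare a combined model with a single-datatype model
#'
#' Default: nested linear-model F-test of `obs ~ pred_single` against
#' `obs ~ pred_single + pred_combined`, with p from F(1, n - 3) — does the
#' combined prediction explain observed breeding values beyond the single
#' datatype? A Hotelling-Williams test of the dependent correlations
#' r(obs, combined) vs r(obs, single) is available as an alternative.
#' Near-collinear predictors (|r| > 0.9999) are flagged and given p = 1.
#'
#' @param obs observed breeding values.
#' @param pred_single,pred_combined predictions aligned to `obs`.
#' @param method `"nested_F"` or `"hotelling_williams"`.
#' @return list with `p`, `statistic`, `method`, `degenerate`.
#' @export
compare_models <- function(obs, pred_single, pred_combined,
                           method = c("nested_F", "hotelling_williams")) {
  method <- match.arg(method)
  n <- length(obs)
  stopifnot(length(pred_single) == n, length(pred_combined) == n, n >= 4)
  if (sd(pred_single) == 0 || sd(pred_combined) == 0 ||
      abs(cor(pred_single, pred_combined)) > 0.9999)
    return(list(p = 1, statistic = 0, method = method, degenerate = TRUE))
  if (method == "nested_F") {
    rss_r <- sum(resid(lm(obs ~ pred_single))^2)
    rss_f <- sum(resid(lm(obs ~ pred_single + pred_combined))^2)
    f <- (rss_r - rss_f) / (rss_f / (n - 3))
    list(p = pf(f, 1, n - 3, lower.tail = FALSE), statistic = f,
         method = method, degenerate = FALSE)
  } else {
    r13 <- cor(obs, pred_combined); r23 <- cor(obs, pred_single)
    r12 <- cor(pred_combined, pred_single)
    detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
    rbar <- (r13 + r23) / 2
    tstat <- (r13 - r23) * sqrt((n - 1) * (1 + r12) /
      (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3))
    list(p = 2 * pt(abs(tstat), n - 3, lower.tail = FALSE), statistic = tstat,
         method = method, degenerate = FALSE)
  }
}

# transcript cascade: ALL (low expression) -> setA (batch/lfdr) ->
# setB (correlation prune) -> setC (phenotype screen, training only)
.transcript_stages <- function(fm, phen_train, cfg) {
  all_ <- low_expression_filter(fm, cfg$min_mean_log2)
  seta <- batch_filter_transcripts(all_, cfg)
  setb <- correlation_prune(seta, cfg$prune_r)
  setc <- phenotype_screen_transcripts(setb, phen_train, cfg$transcript_phen_r)
  list(ALL = all_, setA = seta, setB = setb, setC = setc)
}

# SNP cascade: ALL (batch ANOVA, unadjusted) -> setA (relative variance) ->
# setB (correlation prune) -> setC (phenotype ANOVA, training only)
.snp_stages <- function(fm, phen_train, cfg) {
  mono <- apply(fm$values, 2, function(v) length(unique(v)) == 1)
  if (any(mono))
    fm <- family_features(fm$values[, !mono, drop = FALSE], fm$kind, fm$batch)
  all_ <- batch_filter_snps(fm, cfg$snp_batch_alpha)
  seta <- relative_variance_filter(all_, cfg$rel_var_cutoff)
  setb <- correlation_prune(seta, cfg$prune_r)
  setc <- phenotype_screen_snps(setb, phen_train, cfg$snp_phen_alpha)
  list(ALL = all_, setA = seta, setB = setb, setC = setc)
}

.predict_cell <- function(model, fm, split, phen_train, cfg) {
  if (model == "kriging") {
    s <- pearson_similarity(fm, standardize = cfg$standardize_features)
    m <- kriging_fit(s, phen_train, theta = cfg$theta)
    kriging_predict_set(m, s, split$test)
  } else {
    xtr <- fm$values[split$train, , drop = FALSE]
    ytr <- phen_train$bv[match(split$train, phen_train$family)]
    tuned <- tune_elasticnet(xtr, ytr, cfg)
    fit <- elasticnet_fit(xtr, ytr, tuned$alpha, tuned$lambda)
    pred <- predict(fit, fm$values[split$test, , drop = FALSE])
    prediction_result(pred, "elasticnet", NA_character_)
  }
}

#' Run the full cross-batch prediction experiment
#'
#' Executes the grid {kriging, elastic net} x {snps, transcripts, combined}
#' x {ALL, setA, setB, setC} for one train/test split: builds the transcript
#' and SNP filter cascades (phenotype screens and elastic-net tuning see
#' training families only), predicts the test families, and reports
#' accuracy per cell plus nested-model comparisons of combined against
#' single-datatype predictions. Cell failures are recorded and the grid
#' continues.
#'
#' @param data list with `counts` ([replicate_counts()]), `snps`
#'   (`snp_dosage` [family_features()]), `phen` ([phenotypes()]), as
#'   produced by [simulate_dataset()] or read from files.
#' @param train_batches,test_batches batch labels defining the split.
#' @param cfg a [run_config()]; `cfg$seed` seeds the stochastic stages.
#' @param models subset of `c("kriging", "elasticnet")`.
#' @return list of class `evaluation_report` with `results` (one row per
#'   grid cell), `comparisons`, `predictions`, `split`, `stage_sizes`.
#' @export
run_experiment <- function(data, train_batches, test_batches,
                           cfg = run_config(),
                           models = c("kriging", "elasticnet")) {
  stopifnot(all(models %in% c("kriging", "elasticnet")))
  set.seed(cfg$seed)
  split <- make_split(data$phen, train_batches, test_batches)
  phen_train <- data$phen[data$phen$family %in% split$train, ]
  class(phen_train) <- c("phenotypes", "data.frame")
  fm_tr <- family_mean_log2(data$counts)
  stages <- list(
    transcripts = .transcript_stages(fm_tr, phen_train, cfg),
    snps = .snp_stages(data$snps, phen_train, cfg))
  stage_names <- c("ALL", "setA", "setB", "setC")

  results <- list(); preds <- list(); comparisons <- list()
  for (model in models) {
    for (stg in stage_names) {
      cell_preds <- list()
      for (dt in c("transcripts", "snps")) {
        pr <- tryCatch({
          p <- .predict_cell(model, stages[[dt]][[stg]], split, phen_train, cfg)
          p$datatype <- dt; p$stage <- stg; p
        }, error = function(e) e)
        key <- paste(model, dt, stg, sep = ".")
        if (inherits(pr, "error")) {
          results[[key]] <- data.frame(model = model, datatype = dt,
                                       stage = stg, r = NA, p = NA,
                                       n = NA, error = conditionMessage(pr))
        } else {
          a <- accuracy(pr, data$phen)
          results[[key]] <- data.frame(model = model, datatype = dt,
                                       stage = stg, r = a$r, p = a$p,
                                       n = a$n, error = NA_character_)
          preds[[key]] <- pr
          cell_preds[[dt]] <- pr
        }
      }
      key <- paste(model, "combined", stg, sep = ".")
      if (length(cell_preds) == 2) {
        comb <- combine_predictions(cell_preds$transcripts, cell_preds$snps)
        a <- accuracy(comb, data$phen)
        results[[key]] <- data.frame(model = model, datatype = "combined",
                                     stage = stg, r = a$r, p = a$p,
                                     n = a$n, error = NA_character_)
        preds[[key]] <- comb
        obs <- data$phen$bv[match(names(comb$pred), data$phen$family)]
        for (dt in c("transcripts", "snps")) {
          cm <- compare_models(obs, cell_preds[[dt]]$pred[names(comb$pred)],
                               comb$pred)
          comparisons[[paste(model, stg, dt, sep = ".")]] <-
            data.frame(model = model, stage = stg, against = dt,
                       p = cm$p, statistic = cm$statistic)
        }
      } else {
        results[[key]] <- data.frame(model = model, datatype = "combined",
                                     stage = stg, r = NA, p = NA, n = NA,
                                     error = "single-datatype cell failed")
      }
    }
  }
  structure(list(
    results = do.call(rbind, c(results, list(make.row.names = FALSE))),
    comparisons = if (length(comparisons))
      do.call(rbind, c(comparisons, list(make.row.names = FALSE))) else NULL,
    predictions = preds,
    split = list(train_batches = train_batches, test_batches = test_batches,
                 train = split$train, test = split$test),
    stage_sizes = lapply(stages, function(s)
      vapply(s, function(m) ncol(m$values), 0L))),
    class = "evaluation_report")
}

#' @exportS3Method base::print
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: train batches {%s} (n=%d) -> test batches {%s} (n=%d)\n",
              paste(x$split$train_batches, collapse = ","), length(x$split$train),
              paste(x$split$test_batches, collapse = ","), length(x$split$test)))
  print(x$results, digits = 3)
  invisible(x)
}
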