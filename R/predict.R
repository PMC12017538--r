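# Breeding-value prediction: similarity-matrix kriging (BLUP-style weighted
# average of training phenotypes) and elastic-net regression by coordinate
# descent with bootstrap grid tuning.

#' Per-family prediction result
#'
#' @param pred named numeric vector of predicted breeding values (names are
#'   the test family IDs).
#' @param model `"kriging"`, `"elasticnet"` or `"combined"`.
#' @param datatype `"snps"`, `"transcripts"` or `"combined"`.
#' @param stage filter-stage label (`"ALL"`, `"setA"`, `"setB"`, `"setC"`).
#' @return list of class `prediction_result`.
#' @export
prediction_result <- function(pred, model, datatype, stage = NA_character_) {
  if (any(!is.finite(pred))) stop("predictions must be finite")
  if (is.null(names(pred))) stop("predictions must be named by family")
  structure(list(pred = pred, model = model, datatype = datatype,
                 stage = stage), class = "prediction_result")
}

#' @exportS3Method base::print
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result [%s/%s/%s]: %d families\n",
              x$model, x$datatype, x$stage, length(x$pred)))
  invisible(x)
}

#' Fit a kriging model on a similarity matrix
#'
#' Builds the composite training-block matrix Sigma = theta * S + (1 -
#' theta) * I, where S is the omic similarity among training families and I
#' represents an environmental component independent across individuals.
#' Sigma is inverted through its eigendecomposition; when it is singular or
#' near-singular (fewer informative features than training families make a
#' correlation matrix rank-deficient), eigenvalues below `tol` times the
#' largest are truncated, giving the pseudo-inverse solve on the retained
#' subspace (noted via a message).
#'
#' @param s a [pearson_similarity()] or [vanraden_grm()] object (or a plain
#'   symmetric matrix with family dimnames) covering all training families.
#' @param phen_train [phenotypes()] for the training families.
#' @param theta similarity weight in [0, 1] (default 1).
#' @param center use centered kriging, predicting mean + weighted centered
#'   phenotypes (default TRUE); `FALSE` gives the literal raw weighted
#'   average of training phenotypes.
#' @param tol relative eigenvalue cutoff for the pseudo-inverse (default
#'   1e-8).
#' @return list of class `kriging_model`.
#' @export
kriging_fit <- function(s, phen_train, theta = 1, center = TRUE,
                        tol = 1e-8) {
  stopifnot(theta >= 0, theta <= 1, inherits(phen_train, "phenotypes"))
  sm <- if (inherits(s, "similarity_matrix") || inherits(s, "grm")) s$entries else s
  train <- phen_train$family
  miss <- setdiff(train, rownames(sm))
  if (length(miss)) stop("training families absent from similarity matrix: ",
                         paste(miss, collapse = ", "))
  sigma <- theta * sm[train, train, drop = FALSE] +
    (1 - theta) * diag(length(train))
  es <- eigen(sigma, symmetric = TRUE)
  keep <- es$values > tol * max(abs(es$values), .Machine$double.eps)
  if (!any(keep)) stop("Sigma has no usable eigenvalues")
  if (!all(keep))
    message(sum(!keep), " near-zero eigenvalue(s) of Sigma truncated ",
            "(pseudo-inverse solve)")
  sigma_inv <- es$vectors[, keep, drop = FALSE] %*%
    (t(es$vectors[, keep, drop = FALSE]) / es$values[keep])
  y <- setNames(phen_train$bv, train)
  structure(list(train = train, y = y, sigma = sigma,
                 sigma_inv = sigma_inv, theta = theta,
                 mu = mean(y), center = center),
            class = "kriging_model")
}

#' Kriging prediction for one test individual
#'
#' Given the similarity vector rho between a test family and each training
#' family (taken from the same similarity matrix used at fit time), computes
#' weights omega = Sigma^-1 rho and predicts, in the centered form,
#' yhat = mu + rho' Sigma^-1 (Y - mu). With `center = FALSE` at fit time the
#' literal weighted average rho' Sigma^-1 Y is returned. rho is scaled by
#' theta, matching the composite-matrix construction.
#'
#' @param model a [kriging_fit()] model.
#' @param rho numeric similarity vector aligned to the training family
#'   order (names checked when present).
#' @return scalar predicted breeding value.
#' @export
kriging_predict <- function(model, rho) {
  stopifnot(inherits(model, "kriging_model"))
  if (length(rho) != length(model$train))
    stop("rho length must match the number of training families")
  if (!is.null(names(rho)) && !identical(names(rho), model$train))
    rho <- rho[model$train]
  omega <- drop(model$sigma_inv %*% (model$theta * rho))
  if (model$center) model$mu + sum(omega * (model$y - model$mu))
  else sum(omega * model$y)
}

#' Kriging predictions for a set of test families
#'
#' Convenience wrapper: pulls each test family's similarity-to-training
#' vector out of the full similarity matrix and applies [kriging_predict()].
#'
#' @param model a [kriging_fit()] model.
#' @param s the similarity object the model was fitted from (must also
#'   cover the test families).
#' @param test_ids test family IDs.
#' @param datatype,stage labels stored in the result.
#' @return a [prediction_result()].
#' @export
kriging_predict_set <- function(model, s, test_ids,
                                datatype = NA_character_,
                                stage = NA_character_) {
  sm <- if (inherits(s, "similarity_matrix") || inherits(s, "grm")) s$entries else s
  miss <- setdiff(test_ids, rownames(sm))
  if (length(miss)) stop("test families absent from similarity matrix: ",
                         paste(miss, collapse = ", "))
  pred <- vapply(test_ids, function(id)
    kriging_predict(model, sm[model$train, id]), 0)
  prediction_result(setNames(pred, test_ids), "kriging", datatype, stage)
}

#' Fit an elastic net by cyclic coordinate descent
#'
#' Minimizes (1/2n) sum_i (y_i - b0 - x_i' b)^2 + lambda (0.5 (1 - alpha)
#' ||b||_2^2 + alpha ||b||_1) with an unpenalized intercept. Features are
#' standardized internally (mean 0, variance 1 with the 1/n denominator);
#' coefficients are returned on the original scale. Convergence is declared
#' when the largest coefficient change in a sweep is below `tol`; the
#' objective is recorded every sweep and is non-increasing.
#'
#' @param x numeric matrix (training families x features) or a
#'   [family_features()] object.
#' @param y numeric response (training breeding values), length nrow(x).
#' @param alpha mixing parameter in [0, 1] (1 = lasso, 0 = ridge).
#' @param lambda penalty strength >= 0.
#' @param tol convergence tolerance on coefficient changes (default 1e-7).
#' @param max_sweeps sweep budget (default 1e5); exceeding it is an error.
#' @return list of class `elasticnet_model` with `beta0`, `beta` (original
#'   scale, named), `alpha`, `lambda`, standardization parameters, and the
#'   per-sweep `objective` trajectory.
#' @export
elasticnet_fit <- function(x, y, alpha, lambda, tol = 1e-7,
                           max_sweeps = 1e5) {
  if (inherits(x, "family_features")) x <- x$values
  x <- as.matrix(x)
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0, nrow(x) == length(y))
  n <- nrow(x)
  ctr <- colMeans(x)
  xs <- sweep(x, 2, ctr)
  scl <- sqrt(colSums(xs^2) / n)
  zero_var <- scl == 0
  scl[zero_var] <- 1
  xs <- sweep(xs, 2, scl, "/")
  ybar <- mean(y)
  yc <- y - ybar
  # pathwise warm start from the smallest fully-shrinking lambda down to the
  # target: cold starts at small lambda converge very slowly when p >> n
  lambda_max <- max(abs(crossprod(xs, yc)) / n) / max(alpha, 1e-3)
  beta <- NULL
  if (lambda < lambda_max) {
    path <- exp(seq(log(lambda_max), log(max(lambda, 1e-8)), length.out = 15))
    for (l in path[-length(path)]) {
      beta <- enet_cd_cpp(xs, yc, alpha, l, tol, as.integer(max_sweeps), beta)$beta
    }
  }
  fit <- enet_cd_cpp(xs, yc, alpha, lambda, tol, as.integer(max_sweeps), beta)
  if (!fit$converged)
    stop(sprintf("coordinate descent did not converge in %d sweeps (last objective %.6g)",
                 fit$sweeps, utils::tail(fit$objective, 1)))
  beta_std <- fit$beta
  beta_std[zero_var] <- 0
  beta <- beta_std / scl
  names(beta) <- colnames(x)
  beta0 <- ybar - sum(beta * ctr)
  structure(list(beta0 = beta0, beta = beta, alpha = alpha, lambda = lambda,
                 center = ctr, scale = scl, objective = fit$objective,
                 sweeps = fit$sweeps),
            class = "elasticnet_model")
}

#' Predict from a fitted elastic net
#'
#' @param object an [elasticnet_fit()] model.
#' @param newx matrix (or [family_features()]) whose columns must include
#'   every feature the model was fitted on.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.elasticnet_model <- function(object, newx, ...) {
  if (inherits(newx, "family_features")) newx <- newx$values
  miss <- setdiff(names(object$beta), colnames(newx))
  if (length(miss)) stop("features absent at predict time: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  drop(object$beta0 + newx[, names(object$beta), drop = FALSE] %*% object$beta)
}

#' Bootstrap grid tuning of the elastic net
#'
#' For every (alpha, lambda) grid point, the training families are
#' bootstrapped `n_bootstrap` times (default 25, at the family level); the
#' model is fitted on each resample and scored by RMSE on the out-of-bag
#' families; the grid point with the lowest mean out-of-bag RMSE wins, with
#' ties broken toward the smaller lambda, then the smaller alpha. The same
#' resamples are reused across grid points. A resample whose out-of-bag set
#' is empty is redrawn.
#'
#' @param x training feature matrix (families x features) or
#'   [family_features()].
#' @param y training breeding values.
#' @param cfg a [run_config()] supplying `alpha_grid`, `lambda_grid`,
#'   `n_bootstrap`.
#' @return list with `alpha`, `lambda`, and the full `rmse` grid.
#' @export
tune_elasticnet <- function(x, y, cfg = run_config()) {
  if (inherits(x, "family_features")) x <- x$values
  n <- nrow(x)
  boots <- lapply(seq_len(cfg$n_bootstrap), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (length(oob) > 0) return(list(idx = idx, oob = oob))
      message("bootstrap resample had empty out-of-bag set; redrawn")
    }
  })
  lambdas <- sort(cfg$lambda_grid, decreasing = TRUE)
  grid <- expand.grid(alpha = cfg$alpha_grid, lambda = lambdas)
  rmse_acc <- matrix(0, length(cfg$alpha_grid), length(lambdas),
                     dimnames = list(NULL, as.character(lambdas)))
  for (bt in boots) {
    xb <- x[bt$idx, , drop = FALSE]
    ctr <- colMeans(xb)
    xs <- sweep(xb, 2, ctr)
    scl <- sqrt(colSums(xs^2) / nrow(xs))
    scl[scl == 0] <- 1
    xs <- sweep(xs, 2, scl, "/")
    ybar <- mean(y[bt$idx])
    xo <- sweep(sweep(x[bt$oob, , drop = FALSE], 2, ctr), 2, scl, "/")
    for (a in seq_along(cfg$alpha_grid)) {
      beta <- NULL  # warm start along the descending lambda path
      for (l in seq_along(lambdas)) {
        fit <- enet_cd_cpp(xs, y[bt$idx] - ybar, cfg$alpha_grid[a],
                           lambdas[l], 1e-7, 100000L, beta)
        beta <- fit$beta
        pred <- ybar + drop(xo %*% beta)
        rmse_acc[a, l] <- rmse_acc[a, l] +
          sqrt(mean((y[bt$oob] - pred)^2)) / length(boots)
      }
    }
  }
  grid$rmse <- as.vector(rmse_acc)
  best <- min(grid$rmse)
  cand <- grid[grid$rmse <= best, , drop = FALSE]
  cand <- cand[order(cand$lambda, cand$alpha), , drop = FALSE]
  list(alpha = cand$alpha[1], lambda = cand$lambda[1], rmse = grid)
}

#' Average two prediction results across data types
#'
#' Per-family arithmetic mean of two predictions made with the same model
#' on different data types; the combined result carries datatype
#' `"combined"`.
#'
#' @param a,b [prediction_result()] objects over the same test families.
#' @return a [prediction_result()].
#' @export
combine_predictions <- function(a, b) {
  stopifnot(inherits(a, "prediction_result"), inherits(b, "prediction_result"))
  if (!setequal(names(a$pred), names(b$pred)))
    stop("prediction results cover different family sets")
  if (!identical(a$model, b$model))
    stop("can only combine predictions from the same model")
  ids <- names(a$pred)
  prediction_result((a$pred + b$pred[ids]) / 2, a$model, "combined", a$stage)
}
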