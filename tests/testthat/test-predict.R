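test_that("kriging reproduces hand-worked identity-Sigma examples", {
  s <- diag(2); dimnames(s) <- list(c("A", "B"), c("A", "B"))
  phen <- phenotypes(c("A", "B"), c(1, 3), c("1", "1"))
  m <- kriging_fit(s, phen, theta = 1)
  # mu = 2; rho = (1, 0): yhat = 2 + 1 * (1 - 2) = 1
  expect_equal(kriging_predict(m, c(A = 1, B = 0)), 1)
  # no similarity: prediction falls back to the training mean
  expect_equal(kriging_predict(m, c(A = 0, B = 0)), 2)
})

test_that("kriging agrees with a dense linear-solve oracle on random SPD systems", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    sig <- random_spd(n)
    y <- rnorm(n)
    rho <- rnorm(n)
    phen <- phenotypes(rownames(sig), y, rep("1", n))
    m <- kriging_fit(sig, phen, theta = 1)
    yhat <- kriging_predict(m, setNames(rho, rownames(sig)))
    oracle <- mean(y) + drop(rho %*% solve(sig, y - mean(y)))
    expect_equal(yhat, oracle, tolerance = 1e-10)
  }
})

test_that("raw-weight kriging reproduces the literal weighted average", {
  set.seed(42)
  sig <- random_spd(5)
  y <- rnorm(5)
  rho <- rnorm(5)
  phen <- phenotypes(rownames(sig), y, rep("1", 5))
  m <- kriging_fit(sig, phen, theta = 1, center = FALSE)
  expect_equal(kriging_predict(m, setNames(rho, rownames(sig))),
               drop(rho %*% solve(sig, y)), tolerance = 1e-12)
})

test_that("theta = 0 removes all similarity information and predicts the mean", {
  set.seed(43)
  sig <- random_spd(6)
  y <- rnorm(6)
  phen <- phenotypes(rownames(sig), y, rep("1", 6))
  m <- kriging_fit(sig, phen, theta = 0)
  expect_equal(kriging_predict(m, setNames(rnorm(6), rownames(sig))),
               mean(y), tolerance = 1e-12)
})

test_that("elastic net recovers OLS at lambda = 0 and shrinks to the mean at large lambda", {
  set.seed(44)
  x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "x1"))
  y <- 1.5 + 2 * x[, 1] + rnorm(30, 0, 0.2)
  f <- elasticnet_fit(x, y, alpha = 0.5, lambda = 0)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(f$beta), unname(ols[2]), tolerance = 1e-6)
  expect_equal(f$beta0, unname(ols[1]), tolerance = 1e-6)
  big <- elasticnet_fit(x, y, alpha = 0.5, lambda = 1e4)
  expect_equal(unname(big$beta), 0)
  expect_equal(unname(predict(big, x)), rep(mean(y), 30))
})

test_that("orthonormal designs match the soft-threshold/ridge-scaling closed form", {
  set.seed(45)
  n <- 8; p <- 3
  z <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  q <- qr.Q(qr(z)) * sqrt(n)  # centered columns with (1/n) X'X = I
  colnames(q) <- paste0("x", 1:p)
  y <- rnorm(n)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (alpha in c(0.2, 0.5, 0.9)) for (lambda in c(0.05, 0.3)) {
    f <- elasticnet_fit(q, y, alpha, lambda)
    bols <- drop(crossprod(q, y - mean(y))) / n
    closed <- soft(bols, lambda * alpha) / (1 + lambda * (1 - alpha))
    expect_equal(unname(f$beta), unname(closed), tolerance = 1e-6)
  }
})

test_that("the coordinate-descent objective never increases and glmnet agrees", {
  skip_if_not_installed("glmnet")
  set.seed(46)
  x <- matrix(rnorm(40 * 60), 40, 60, dimnames = list(NULL, paste0("f", 1:60)))
  y <- drop(x[, 1:4] %*% c(1, -1, 0.5, 0.5)) + rnorm(40, 0, 0.5)
  y <- y / sd(y)  # glmnet interprets lambda on the unit-sd response scale
  f <- elasticnet_fit(x, y, alpha = 0.6, lambda = 0.1)
  expect_true(all(diff(f$objective) <= 1e-12))
  g <- glmnet::glmnet(x, y, alpha = 0.6, lambda = 0.1,
                      thresh = 1e-14, maxit = 1e7)
  expect_lt(max(abs(unname(f$beta) - as.vector(g$beta))), 5e-3)
  expect_lt(abs(f$beta0 - as.numeric(g$a0)), 5e-3)
})

test_that("bootstrap tuning is deterministic under a fixed seed", {
  set.seed(47)
  x <- matrix(rnorm(25 * 30), 25, 30, dimnames = list(NULL, paste0("f", 1:30)))
  y <- drop(x[, 1:3] %*% c(1, 1, -1)) + rnorm(25, 0, 0.3)
  cfg <- run_config(alpha_grid = c(0.2, 0.8), lambda_grid = c(1, 0.01),
                    n_bootstrap = 10)
  set.seed(99); t1 <- tune_elasticnet(x, y, cfg)
  set.seed(99); t2 <- tune_elasticnet(x, y, cfg)
  expect_identical(t1, t2)
  expect_true(t1$alpha %in% cfg$alpha_grid)
  expect_true(t1$lambda %in% cfg$lambda_grid)
})

test_that("stronger signal drives the tuned lambda downward", {
  # Monte-Carlo: mean selected lambda under high noise >= under low noise
  cfg <- run_config(alpha_grid = c(0.5), lambda_grid = c(1, 0.1, 0.01),
                    n_bootstrap = 8)
  sel <- sapply(c(5, 0.2), function(noise_sd) {
    mean(sapply(1:6, function(s) {
      set.seed(200 + s)
      x <- matrix(rnorm(30 * 20), 30, 20,
                  dimnames = list(NULL, paste0("f", 1:20)))
      y <- drop(x[, 1:3] %*% c(2, -2, 2)) + rnorm(30, 0, noise_sd)
      tune_elasticnet(x, y, cfg)$lambda
    }))
  })
  expect_gte(sel[1], sel[2])
})

test_that("combining predictions averages per family and validates inputs", {
  a <- prediction_result(c(A = 2, B = 0), "kriging", "snps", "setC")
  b <- prediction_result(c(B = 4, A = 4), "kriging", "transcripts", "setC")
  comb <- combine_predictions(a, b)
  expect_equal(comb$pred, c(A = 3, B = 2))
  expect_identical(comb$datatype, "combined")
  expect_equal(combine_predictions(a, a)$pred, a$pred)
  bad <- prediction_result(c(A = 1, C = 1), "kriging", "transcripts", "setC")
  expect_error(combine_predictions(a, bad), "different family sets")
  wrong_model <- prediction_result(c(A = 1, B = 1), "elasticnet", "snps", "setC")
  expect_error(combine_predictions(a, wrong_model), "same model")
})
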