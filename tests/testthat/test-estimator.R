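test_that("implied covariance reproduces closed forms", {
  # no paths: Sigma is S restricted to observed rows
  ram <- to_ram(parse_model("x1 ~~ x2"))
  fi <- ram$free_index
  theta <- ifelse(fi$row == fi$col, c(2, 3)[fi$row], 0.5)
  Sigma <- implied_covariance(ram, theta)
  expect_equal(Sigma, matrix(c(2, 0.5, 0.5, 3), 2,
                             dimnames = list(c("x1", "x2"), c("x1", "x2"))))

  # single path y <- x: Sigma = [[v, bv], [bv, b^2 v + r]]
  ram <- to_ram(parse_model("y ~ x"))
  fi <- ram$free_index
  b <- 0.7; v <- 2; r <- 0.5
  theta <- numeric(3)
  theta[fi$matrix == "A"] <- b
  theta[fi$label == "x~~x"] <- v
  theta[fi$label == "y~~y"] <- r
  Sigma <- implied_covariance(ram, theta)
  expect_equal(unname(Sigma[ram$observed_vars == "x", ram$observed_vars == "x"]), v)
  expect_equal(unname(Sigma["y", "x"]), b * v)
  expect_equal(unname(Sigma["y", "y"]), b^2 * v + r)
})

test_that("implied cov(Treatment, mediator) is coefficient times var(Treatment)", {
  ram <- to_ram(parse_model(model2_syntax))
  fi <- ram$free_index
  theta <- numeric(nrow(fi))
  theta[fi$row == fi$col & fi$matrix == "S"] <- 1
  theta[fi$label == "MMDs~Treatment"] <- -3.030
  Sigma <- implied_covariance(ram, theta)
  expect_equal(unname(Sigma["Treatment", "MMDs"]),
               -3.030 * unname(Sigma["Treatment", "Treatment"]))
})

test_that("ml_discrepancy matches closed forms and is a proper discrepancy", {
  S <- matrix(c(2, 0.3, 0.3, 1), 2)
  expect_equal(ml_discrepancy(S, S), 0)
  expect_equal(ml_discrepancy(diag(2), 2 * diag(2)), 2 * log(2) + 1 - 2,
               tolerance = 1e-12)
  # strictly positive for perturbed SPD matrices
  set.seed(4)
  for (i in 1:20) {
    p <- sample(2:5, 1)
    A <- matrix(rnorm(p * p), p)
    S <- crossprod(A) + diag(p)
    P <- matrix(rnorm(p * p, sd = 0.1), p)
    Sig <- S + crossprod(P) + diag(p) * 0.01
    expect_gt(ml_discrepancy(S, Sig, p), 0)
  }
  expect_error(ml_discrepancy(diag(2), matrix(c(1, 2, 2, 1), 2)),
               "not positive definite")
})

test_that("ml_discrepancy agrees with a per-observation MVN density oracle", {
  # oracle: sum pointwise multivariate-normal log-densities (quadratic
  # forms per row) under Sigma and under the n-denominator MLE covariance;
  # -2/n times the difference equals F_ML
  set.seed(5)
  n <- 400; p <- 3
  X <- matrix(rnorm(n * p), n, p) %*% matrix(c(1, 0.4, 0, 0, 1, 0.2, 0, 0, 1), p)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S_n <- crossprod(Xc) / n
  A <- matrix(rnorm(p * p, sd = 0.2), p)
  Sigma <- S_n + crossprod(A)

  ld <- function(M) {
    Minv <- solve(M)
    -0.5 * sum(apply(Xc, 1, function(r) drop(t(r) %*% Minv %*% r))) -
      n / 2 * (p * log(2 * pi) + determinant(M)$modulus[1])
  }
  oracle <- -2 * (ld(Sigma) - ld(S_n)) / n
  expect_equal(ml_discrepancy(S_n, Sigma, p), oracle, tolerance = 1e-10)
})

test_that("path-model ML estimates equal closed-form regression solutions", {
  d <- toy_two_predictor()
  fit <- fit_sem(d, "y ~ x1 + x2")
  ols <- coef(lm(y ~ x1 + x2, d))
  est <- coef(fit)
  expect_equal(unname(est["y~x1"]), unname(ols["x1"]), tolerance = 1e-6)
  expect_equal(unname(est["y~x2"]), unname(ols["x2"]), tolerance = 1e-6)

  d1 <- toy_regression()
  fit1 <- fit_sem(d1, "y ~ x")
  expect_equal(unname(coef(fit1)["y~x"]),
               unname(coef(lm(y ~ x, d1))["x"]), tolerance = 1e-6)
  # just-identified: implied covariance reproduces the sample moments
  expect_lt(fit1$discrepancy, 1e-10)
  expect_equal(implied_covariance(fit1$ram, fit1$theta),
               fit1$moments$S_obs, tolerance = 1e-6)
})

test_that("fits are invariant to observed-column order and fully deterministic", {
  cfg <- default_truth("model2")
  d <- generate_trial(cfg, n = 1500, seed = 11)
  f1 <- fit_sem(d, model2_syntax)
  f2 <- fit_sem(d[, rev(names(d))], model2_syntax)
  expect_identical(f1$theta, f2$theta)
  f3 <- fit_sem(d, model2_syntax)
  expect_identical(f1$theta, f3$theta)
  expect_identical(f1$se, f3$se)
  expect_identical(f1$param_table, f3$param_table)
})

test_that("standard errors shrink as 1/sqrt(n) and fixed loadings report SE 0", {
  ses <- sapply(c(500, 2000, 8000), function(n) {
    fit <- fit_sem(toy_regression(n = n, seed = 9), "y ~ x")
    standard_errors(fit)[["y~x"]]
  })
  slope <- coef(lm(log(ses) ~ log(c(500, 2000, 8000))))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)

  fit <- fit_sem(toy_cfa(), "F =~ y1 + y2 + y3")
  tab <- fit$param_table
  marker <- tab[tab$op == "=~" & tab$rhs == "y1", ]
  expect_false(marker$free)
  expect_identical(marker$se, 0)
  expect_identical(marker$estimate, 1)
})

test_that("listwise deletion drops incomplete rows before computing moments", {
  d <- toy_two_predictor(n = 300)
  d$x1[c(5, 17)] <- NA
  mo <- sample_moments(d, c("x1", "x2", "y"))
  expect_equal(mo$n, 298)
  expect_equal(mo$n_input, 300)
  fit <- fit_sem(d, "y ~ x1 + x2")
  expect_equal(fit$moments$n, 298)
})

test_that("a Heywood case is reported as a warning state, not an error", {
  # correlations imply a standardized loading above 1 for y1
  R <- matrix(c(1, 0.8, 0.8,
                0.8, 1, 0.4,
                0.8, 0.4, 1), 3, byrow = TRUE,
              dimnames = list(c("y1", "y2", "y3"), c("y1", "y2", "y3")))
  mo <- structure(list(S_obs = R, n = 500, n_input = 500,
                       var_names = c("y1", "y2", "y3")),
                  class = "sem_moments")
  fit <- fit_sem(mo, "F =~ y1 + y2 + y3")
  expect_true(any(grepl("Heywood", fit$warnings)))
  expect_true(any(fit$theta[fit$ram$free_index$row == fit$ram$free_index$col &
                              fit$ram$free_index$matrix == "S"] < 0))
})
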