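test_that("standardization uses implied sds and inverts exactly", {
  # equal variances: standardized equals raw
  S <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("y", "x"), c("y", "x")))
  mo <- structure(list(S_obs = S, n = 200, n_input = 200,
                       var_names = c("y", "x")), class = "sem_moments")
  fit <- fit_sem(mo, "y ~ x")
  tab <- fit$param_table
  expect_equal(tab$std_estimate[tab$op == "~"], tab$estimate[tab$op == "~"],
               tolerance = 1e-8)

  # std then re-derive raw via the inverse sd ratio: exact recovery
  d <- generate_trial(default_truth("model2"), n = 2000, seed = 21)
  fit2 <- fit_sem(d, model2_syntax)
  std <- standardize(fit2)
  mats <- latentmed:::ram_fill(fit2$ram, fit2$theta)
  E <- solve(diag(nrow(mats$A)) - mats$A)
  sds <- sqrt(diag(E %*% mats$S %*% t(E)))
  names(sds) <- fit2$ram$var_names
  reg <- std[std$op == "~", ]
  back <- reg$std_estimate * sds[reg$lhs] / sds[reg$rhs]
  expect_equal(unname(back), reg$estimate, tolerance = 1e-10)
})

test_that("standardized loadings recover generating correlations in a CFA", {
  lam <- c(0.8, 0.7, 0.6)
  fit <- fit_sem(toy_cfa(n = 4000, lambda = lam, seed = 31), "F =~ y1 + y2 + y3")
  tab <- fit$param_table
  got <- tab$std_estimate[tab$op == "=~"][match(paste0("y", 1:3),
                                               tab$rhs[tab$op == "=~"])]
  expect_equal(got, lam, tolerance = 0.05)
  expect_true(all(abs(got) <= 1))
})

test_that("saturated models hit the exact fit-index limits", {
  fit <- fit_sem(toy_two_predictor(), "y ~ x1 + x2")
  ix <- fit_indices(fit)
  expect_true(ix$saturated)
  expect_lt(abs(ix$chi_square), 1e-6)
  expect_equal(ix$cfi, 1)
  expect_equal(ix$rmsea, 0)
  expect_lt(ix$srmr, 1e-6)
  expect_true(all(unlist(ix$pass_flags)))
})

test_that("adequacy cutoffs are strict inequalities at the quoted values", {
  d <- generate_trial(default_truth("model2"), n = 2500, seed = 41)
  fit <- fit_sem(d, model2_syntax)
  ix <- fit_indices(fit)
  expect_equal(unlist(lapply(ix$thresholds, unlist)),
               c(chi_over_df = 2.0, cfi = 0.9, rmsea = 0.05, srmr = 0.08))
  # placing each cutoff exactly at the observed value must fail the flag
  at <- fit_indices(fit, thresholds = list(chi_over_df = ix$chi_over_df,
                                           cfi = ix$cfi, rmsea = ix$rmsea,
                                           srmr = ix$srmr))
  expect_false(at$pass_flags$chi_over_df)
  expect_false(at$pass_flags$cfi)
  expect_false(at$pass_flags$rmsea)
  expect_false(at$pass_flags$srmr)
})

test_that("fit indices match a direct formula oracle on a restricted model", {
  d <- toy_cfa(n = 1500, seed = 51)
  fit <- fit_sem(d, "F =~ y1 + y2 + y3\ny1 ~~ 0*y1")  # df > 0 restriction
  ix <- fit_indices(fit)
  S <- fit$moments$S_obs; n <- fit$moments$n; p <- 3
  Sigma <- implied_covariance(fit$ram, fit$theta)
  Fml <- log(det(Sigma)) + sum(diag(S %*% solve(Sigma))) - log(det(S)) - p
  chi <- (n - 1) * Fml
  df <- p * (p + 1) / 2 - fit$n_free
  Fb <- log(prod(diag(S))) - log(det(S))
  chib <- (n - 1) * Fb
  expect_equal(ix$chi_square, chi, tolerance = 1e-8)
  expect_equal(ix$df, df)
  expect_equal(ix$cfi, 1 - max(chi - df, 0) / max(chib - (p*(p+1)/2 - p), chi - df, 0),
               tolerance = 1e-8)
  expect_equal(ix$rmsea, sqrt(max(chi - df, 0) / (df * (n - 1))), tolerance = 1e-8)
  Dm <- diag(1 / sqrt(diag(S)))
  Rr <- Dm %*% (S - Sigma) %*% Dm
  expect_equal(ix$srmr, sqrt(mean(Rr[upper.tri(Rr, diag = TRUE)]^2)),
               tolerance = 1e-8)
  expect_equal(ix$aic, -2 * fit$loglik + 2 * fit$n_free)
})

test_that("SRMR is invariant to rescaling a variable", {
  d <- toy_cfa(n = 1200, seed = 61)
  f1 <- fit_sem(d, "F =~ y1 + y2 + y3\ny1 ~~ 0.5*y1")
  d2 <- d; d2$y2 <- d2$y2 * 10
  f2 <- fit_sem(d2, "F =~ y1 + y2 + y3\ny1 ~~ 0.5*y1")
  expect_equal(fit_indices(f1)$srmr, fit_indices(f2)$srmr, tolerance = 1e-6)
})

test_that("AIC ranking orders models and refuses mismatched samples", {
  mk_fit <- function(aic, k, n, p = 6) {
    structure(list(loglik = -(aic - 2 * k) / 2, n_free = k,
                   moments = list(n = n), ram = list(p = p)),
              class = "sem_fit")
  }
  rk <- compare_models(list(full = mk_fit(33289, 33, 892),
                            reduced = mk_fit(27914, 15, 892)))
  expect_equal(rk$model, c("reduced", "full"))
  expect_equal(rk$delta_aic, c(0, 33289 - 27914))
  # identical AIC: tie broken by fewer free parameters
  rk2 <- compare_models(list(a = mk_fit(1000, 20, 500), b = mk_fit(1000, 10, 500)))
  expect_equal(rk2$model, c("b", "a"))
  expect_error(compare_models(list(a = mk_fit(1, 2, 100), b = mk_fit(1, 2, 99))),
               "different numbers of rows")
})

test_that("the smaller model usually wins AIC when the extra path is null", {
  wins <- 0L
  for (s in 1:40) {
    set.seed(1000 + s)
    n <- 300
    x <- rnorm(n); z <- rnorm(n)
    d <- data.frame(x = x, z = z, y = 0.5 * x + rnorm(n))
    small <- fit_sem(d, "y ~ x\nx ~~ z")
    big <- fit_sem(d, "y ~ x + z")
    if (compare_models(list(small = small, big = big))$model[1] == "small")
      wins <- wins + 1L
  }
  expect_gt(wins, 20L)
})

test_that("backward elimination keeps strong mediators and obeys the strict rule", {
  d <- generate_trial(default_truth("model2"), n = 4000, seed = 71)
  res <- backward_eliminate(d, model2_syntax, outcome = "HRQoL",
                            protected = c("Treatment"))
  # both mediators are strongly significant in truth: spec unchanged
  expect_equal(res$spec$regressions$HRQoL,
               parse_model(model2_syntax)$regressions$HRQoL)
  expect_true(all(res$trace$action == "evaluated"))

  # strictness: retained iff p < alpha
  p_obs <- res$fit$param_table
  p_mmd <- p_obs$p_value[p_obs$op == "~" & p_obs$lhs == "HRQoL" &
                           p_obs$rhs == "MMDs"]
  keep <- backward_eliminate(d, model2_syntax, outcome = "HRQoL",
                             alpha = p_mmd * 1.0000001,
                             protected = c("Treatment", "PI_MBS"))
  expect_true("MMDs" %in% keep$spec$regressions$HRQoL)
  drop <- backward_eliminate(d, model2_syntax, outcome = "HRQoL",
                             alpha = p_mmd,
                             protected = c("Treatment", "PI_MBS"))
  expect_false("MMDs" %in% drop$spec$regressions$HRQoL)
})

test_that("a true-null mediator is eliminated and protected vars never are", {
  cfg <- null_mediator_config()
  removed <- character(0)
  for (s in 1:5) {
    d <- generate_trial(cfg, n = 4000, seed = 100 + s)
    res <- backward_eliminate(d, null_mediator_syntax, outcome = "HRQoL",
                              protected = c("Treatment", "MMDs"))
    rem <- res$trace$variable[res$trace$action == "removed"]
    removed <- c(removed, rem)
    expect_false(any(c("Treatment", "MMDs") %in% rem))
    # trace is reproducible under the same data
    res2 <- backward_eliminate(d, null_mediator_syntax, outcome = "HRQoL",
                               protected = c("Treatment", "MMDs"))
    expect_identical(res$trace, res2$trace)
  }
  expect_true("Null_med" %in% removed)
})
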