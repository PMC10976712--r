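test_that("the default configuration reproduces the trial layout", {
  cfg <- default_truth("model2")
  d <- generate_trial(cfg)
  expect_equal(nrow(d), 892L)
  expect_equal(sum(d$Treatment == 0), 299L)  # deterministic block allocation
  expect_equal(sum(d$Treatment == 1), 593L)
  expect_true(all(d$Treatment %in% c(0, 1)))
  expect_setequal(names(d), c("patient_id", "Treatment", "PI_MBS", "MMDs",
                              "MSQ_EF", "MSQ_RP", "MSQ_RR"))
})

test_that("generating truth equals the published coefficients", {
  cfg2 <- default_truth("model2")
  expect_equal(unname(cfg2$a["PI_MBS"]), -0.932)
  expect_equal(unname(cfg2$b["PI_MBS"]), -9.322)
  expect_equal(cfg2$c_prime, 1.667)
  cfg1 <- default_truth("model1")
  expect_equal(cfg1$c_prime, 5.111)
  expect_equal(unname(cfg1$a["MMDs"]), -3.030)
  expect_equal(unname(cfg1$b["MMDs"]), -1.446)
  # allocation-implied treatment variance
  expect_equal(cfg1$var_treatment, (593 / 892) * (299 / 892), tolerance = 1e-12)
})

test_that("same seed gives byte-identical CSVs, different seeds differ", {
  cfg <- default_truth("model2", n_patients = 200)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trial(generate_trial(cfg, seed = 5), f1, truth_sidecar = FALSE)
  write_trial(generate_trial(cfg, seed = 5), f2, truth_sidecar = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".csv")
  write_trial(generate_trial(cfg, seed = 6), f3, truth_sidecar = FALSE)
  expect_false(identical(readLines(f1), readLines(f3)))
  unlink(c(f1, f2, f3))
})

test_that("a null configuration produces no treatment associations", {
  cfg <- default_truth("model2", n_patients = 1e5)
  cfg$a[] <- 0; cfg$b[] <- 0; cfg$c_prime <- 0
  d <- generate_trial(cfg, seed = 13)
  for (v in c("PI_MBS", "MMDs", "MSQ_EF", "MSQ_RP", "MSQ_RR"))
    expect_lt(abs(cor(d$Treatment, d[[v]])), 0.02)
})

test_that("sample covariance matches the generating implied covariance", {
  cfg <- default_truth("model2", n_patients = 1e5)
  d <- generate_trial(cfg, seed = 17)
  pop <- truth_observed_cov(cfg)
  emp <- cov(d[, rownames(pop)])
  rel <- abs(emp - pop) / (abs(pop) + 0.05 * sqrt(diag(pop) %o% diag(pop)))
  expect_lt(max(rel), 0.02)
})

test_that("calibrated variances reproduce the published standardized solution", {
  cfg <- default_truth("model2", n_patients = 5e4)
  d <- generate_trial(cfg, seed = 19)
  fit <- fit_sem(d, model2_syntax)
  tab <- fit$param_table
  pub <- reference_estimates("model2")
  for (i in which(pub$op %in% c("=~", "~"))) {
    got <- tab$std_estimate[tab$lhs == pub$lhs[i] & tab$op == pub$op[i] &
                              tab$rhs == pub$rhs[i]]
    expect_lt(abs(got - pub$std_estimate[i]), 0.021,
              label = sprintf("|std(%s %s %s) - published|", pub$lhs[i],
                              pub$op[i], pub$rhs[i]))
  }
})

test_that("MCAR masking hits its rates and respects listwise expectations", {
  cfg <- default_truth("model2", n_patients = 1e5)
  d <- generate_trial(cfg, seed = 23)
  expect_identical(apply_missingness(d, c(PI_MBS = 0), seed = 1), d)
  dm <- apply_missingness(d, c(PI_MBS = 0.061, MSQ_EF = 0.025), seed = 2)
  expect_lt(abs(mean(is.na(dm$PI_MBS)) - 0.061), 0.005)
  expect_lt(abs(mean(is.na(dm$MSQ_EF)) - 0.025), 0.005)
  # listwise-complete fraction ~ product of per-column completeness
  frac <- mean(complete.cases(dm))
  expect_lt(abs(frac - (1 - 0.061) * (1 - 0.025)), 0.005)
  expect_error(apply_missingness(d, c(PI_MBS = 1)), "rates")
  expect_error(apply_missingness(d, c(nope = 0.1)), "unknown columns")
})

test_that("PI_MBS discretization stays on the 7-point scale", {
  cfg <- default_truth("model2", n_patients = 5000)
  cfg$discretize_pimbs <- TRUE
  d <- generate_trial(cfg, seed = 29)
  expect_true(all(d$PI_MBS %in% -3:3))
})

test_that("shrinking the PI_MBS outcome path shrinks its fitted share", {
  base <- default_truth("model2")
  shares <- sapply(c(1, 0.75, 0.5, 0.25, 0), function(s) {
    cfg <- base
    cfg$b["PI_MBS"] <- base$b[["PI_MBS"]] * s
    d <- generate_trial(cfg, n = 6000, seed = 37)
    fit <- fit_sem(d, model2_syntax)
    tab <- decompose_effects(fit, "Treatment", "HRQoL")
    tab$pct_of_total[tab$effect == "indirect:PI_MBS"]
  })
  expect_true(all(diff(shares) < 0))
  expect_lt(abs(shares[5]), 10)  # sampling noise around zero
})

test_that("an invalid configuration is refused with a clear message", {
  cfg <- default_truth("model2")
  cfg$mediator_resid_cov[1, 2] <- cfg$mediator_resid_cov[2, 1] <- 1e6
  expect_error(generate_trial(cfg), "not positive definite")
  cfg2 <- default_truth("model2")
  cfg2$missingness <- c(PI_MBS = 1.2)
  expect_error(generate_trial(cfg2), "missingness")
})
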