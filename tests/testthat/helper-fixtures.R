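# shared fixtures: all synthetic data is generated in code, seeded

toy_regression <- function(n = 500, b = 0.5, seed = 1) {
  set.seed(seed)
  d <- data.frame(x = rnorm(n))
  d$y <- b * d$x + rnorm(n)
  d
}

# two correlated predictors, one outcome: closed-form OLS oracle applies
toy_two_predictor <- function(n = 800, b1 = 0.7, b2 = -0.3, seed = 2) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- 0.5 * x1 + rnorm(n)
  data.frame(x1 = x1, x2 = x2, y = b1 * x1 + b2 * x2 + rnorm(n))
}

# single-factor CFA data with known standardized loadings
toy_cfa <- function(n = 2000, lambda = c(0.8, 0.7, 0.6), seed = 3) {
  set.seed(seed)
  eta <- rnorm(n)
  d <- sapply(seq_along(lambda), function(j)
    lambda[j] * eta + rnorm(n, sd = sqrt(1 - lambda[j]^2)))
  colnames(d) <- paste0("y", seq_along(lambda))
  as.data.frame(d)
}

model2_syntax <- canonical_model("model2")
model1_syntax <- canonical_model("model1")

# model-2 truth extended with one extra mediator whose outcome path is
# exactly zero (used by the elimination tests)
null_mediator_config <- function(resid_var = 1, a_null = -0.3) {
  cfg <- default_truth("model2")
  meds <- c(cfg$mediators, "Null_med")
  cfg$mediators <- meds
  cfg$a <- c(cfg$a, Null_med = a_null)
  cfg$b <- c(cfg$b, Null_med = 0)
  k <- length(meds)
  rv <- c(diag(cfg$mediator_resid_cov), Null_med = resid_var)
  R <- matrix(0.3, k, k); diag(R) <- 1
  cov <- R * tcrossprod(sqrt(rv))
  dimnames(cov) <- list(meds, meds)
  cfg$mediator_resid_cov <- cov
  cfg
}

null_mediator_syntax <- paste(
  "HRQoL =~ MSQ_EF + MSQ_RP + MSQ_RR",
  "HRQoL ~ PI_MBS + MMDs + Null_med + Treatment",
  "PI_MBS ~ Treatment", "MMDs ~ Treatment", "Null_med ~ Treatment",
  "PI_MBS ~~ MMDs", "PI_MBS ~~ Null_med", "MMDs ~~ Null_med",
  sep = "\n")

# population covariance over the observed variables implied by a
# generator configuration, computed by direct matrix algebra (independent
# of the package's RAM identity)
truth_observed_cov <- function(cfg) {
  meds <- cfg$mediators
  k <- length(meds)
  vt <- cfg$var_treatment
  Sx <- matrix(0, k + 1, k + 1,
               dimnames = list(c("Treatment", meds), c("Treatment", meds)))
  Sx["Treatment", "Treatment"] <- vt
  Sx["Treatment", meds] <- Sx[meds, "Treatment"] <- cfg$a * vt
  Sx[meds, meds] <- tcrossprod(cfg$a) * vt + cfg$mediator_resid_cov
  w <- c(cfg$c_prime, cfg$b)
  var_h <- drop(t(w) %*% Sx %*% w) + cfg$disturbance
  cov_xh <- drop(Sx %*% w)
  inds <- names(cfg$loadings)
  vars <- c("Treatment", meds, inds)
  S <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  S[c("Treatment", meds), c("Treatment", meds)] <- Sx
  for (j in inds) {
    S[c("Treatment", meds), j] <- S[j, c("Treatment", meds)] <-
      cfg$loadings[[j]] * cov_xh
    for (j2 in inds)
      S[j, j2] <- cfg$loadings[[j]] * cfg$loadings[[j2]] * var_h
    S[j, j] <- cfg$loadings[[j]]^2 * var_h + cfg$indicator_resid[[j]]
  }
  S
}
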