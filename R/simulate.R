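#' Canonical model syntax for the two mediation models
#'
#' `"model1"` regresses the latent HRQoL outcome on monthly migraine days
#' (MMDs) and four canonical-symptom mediators (proportions of attacks with
#' severe pain, nausea, pulsating/throbbing quality, light sensitivity)
#' plus the treatment indicator; `"model2"` replaces the canonical symptoms
#' with the patient-identified most-bothersome-symptom improvement score
#' (PI_MBS). Both measure HRQoL by the three MSQ domain change scores
#' (MSQ_EF as marker, MSQ_RP, MSQ_RR) and free the residual covariances
#' among the mediators.
#'
#' @param model `"model1"` or `"model2"`.
#' @return A model-syntax string for [parse_model()].
#' @export
canonical_model <- function(model = c("model1", "model2")) {
  model <- match.arg(model)
  meds <- canonical_mediators(model)
  cov_lines <- if (length(meds) > 1) {
    pr <- t(utils::combn(meds, 2))
    paste(pr[, 1], "~~", pr[, 2])
  } else character(0)
  paste(c(
    "HRQoL =~ MSQ_EF + MSQ_RP + MSQ_RR",
    paste("HRQoL ~", paste(c(meds, "Treatment"), collapse = " + ")),
    paste(meds, "~ Treatment"),
    cov_lines), collapse = "\n")
}

canonical_mediators <- function(model) {
  switch(model,
         model1 = c("MMDs", "Severe_migraine", "Nausea",
                    "Pulsating_throbbing", "Light_sensitivity"),
         model2 = c("PI_MBS", "MMDs"),
         stop("unknown model: ", model))
}

#' Published reference estimates for the two mediation models
#'
#' Reads the bundled transcription of the published parameter table of the
#' DELIVER eptinezumab trial mediation analysis (raw estimate, SE, z,
#' p-value, standardized estimate for every loading and regression of both
#' models). Used as the generating truth of [default_truth()] and by
#' [worked_example_check()].
#'
#' @param model Optional `"model1"`/`"model2"` filter.
#' @return A data.frame with columns `model`, `lhs`, `op`, `rhs`,
#'   `estimate`, `se`, `z`, `p_value`, `std_estimate`.
#' @export
reference_estimates <- function(model = NULL) {
  path <- system.file("extdata", "published_estimates.csv",
                      package = "latentmed", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(model)) tab <- tab[tab$model == model, , drop = FALSE]
  tab
}

#' Published reference mediation decomposition
#'
#' The bundled transcription of the published direct/indirect/total effect
#' table (both models), including the printed integer percent
#' contributions where the source prints them.
#'
#' @param model Optional `"model1"`/`"model2"` filter.
#' @return A data.frame with columns `model`, `effect`, `estimate`, `se`,
#'   `z`, `std_estimate`, `pct_of_total`.
#' @export
reference_mediation <- function(model = NULL) {
  path <- system.file("extdata", "published_mediation.csv",
                      package = "latentmed", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(model)) tab <- tab[tab$model == model, , drop = FALSE]
  tab
}

#' Generating truth calibrated to the published estimates
#'
#' Builds a complete generator configuration whose path coefficients equal
#' the published raw estimates and whose (unpublished) variances are
#' derived so that the standardized coefficients match the published
#' standardized column: the treatment variance comes from the 299:593
#' placebo:active allocation, each mediator's total variance from its
#' treatment path's raw/standardized ratio, the latent outcome's variance
#' from the median of the per-path `|raw| * sd(x) / |std|` estimates, and
#' indicator residual variances from the loadings. The mediator residual
#' correlation is not published; an exchangeable `resid_cor` (default 0.3)
#' is used.
#'
#' @param model `"model1"` or `"model2"`.
#' @param n_patients Number of patients (default 892).
#' @param allocation Integer vector `c(placebo, active)` (default
#'   `c(299, 593)`).
#' @param resid_cor Exchangeable residual correlation among mediators.
#' @param missingness Named per-column MCAR rates (default none).
#' @param seed Default seed used by [generate_trial()].
#' @return An object of class `trial_config`.
#' @export
default_truth <- function(model = c("model1", "model2"), n_patients = 892,
                          allocation = c(placebo = 299, active = 593),
                          resid_cor = 0.3, missingness = numeric(0),
                          seed = 1L) {
  model <- match.arg(model)
  ref <- reference_estimates(model)
  meds <- canonical_mediators(model)

  p_active <- allocation[[2]] / sum(allocation)
  var_t <- p_active * (1 - p_active)
  sd_t <- sqrt(var_t)

  pick <- function(lhs, op, rhs) {
    r <- ref[ref$lhs == lhs & ref$op == op & ref$rhs == rhs, ]
    stopifnot(nrow(r) == 1L)
    r
  }
  a <- b <- sd_m <- stats::setNames(numeric(length(meds)), meds)
  sd_h_est <- numeric(0)
  for (m in meds) {
    ra <- pick(m, "~", "Treatment")
    rb <- pick("HRQoL", "~", m)
    a[m] <- ra$estimate; b[m] <- rb$estimate
    sd_m[m] <- abs(ra$estimate) * sd_t / abs(ra$std_estimate)
    sd_h_est <- c(sd_h_est, abs(rb$estimate) * sd_m[m] / abs(rb$std_estimate))
  }
  rc <- pick("HRQoL", "~", "Treatment")
  c_prime <- rc$estimate
  sd_h_est <- c(sd_h_est, abs(c_prime) * sd_t / abs(rc$std_estimate))
  sd_h <- stats::median(sd_h_est)
  var_h <- sd_h^2

  # mediator covariance: treatment-induced part + exchangeable residual part
  k <- length(meds)
  resid_var <- sd_m^2 - a^2 * var_t
  if (any(resid_var <= 0))
    stop("calibration failed: non-positive mediator residual variance")
  R <- matrix(resid_cor, k, k); diag(R) <- 1
  med_resid_cov <- R * tcrossprod(sqrt(resid_var))
  dimnames(med_resid_cov) <- list(meds, meds)

  # disturbance: var(H) minus the structural part w' Sigma_x w
  Sigma_x <- matrix(0, k + 1, k + 1,
                    dimnames = list(c("Treatment", meds), c("Treatment", meds)))
  Sigma_x["Treatment", "Treatment"] <- var_t
  Sigma_x["Treatment", meds] <- Sigma_x[meds, "Treatment"] <- a * var_t
  Sigma_x[meds, meds] <- tcrossprod(a) * var_t + med_resid_cov
  w <- c(c_prime, b)
  disturbance <- var_h - drop(t(w) %*% Sigma_x %*% w)
  if (disturbance <= 0)
    stop("calibration failed: non-positive latent disturbance variance")

  loadings <- ind_resid <- numeric(0)
  for (ind in c("MSQ_EF", "MSQ_RP", "MSQ_RR")) {
    rl <- pick("HRQoL", "=~", ind)
    loadings[ind] <- rl$estimate
    var_ind <- (rl$estimate * sd_h / rl$std_estimate)^2
    ind_resid[ind] <- var_ind - rl$estimate^2 * var_h
    if (ind_resid[ind] <= 0)
      stop("calibration failed: non-positive indicator residual variance for ", ind)
  }

  structure(
    list(model = model, n_patients = as.integer(n_patients),
         allocation = allocation, allocation_mode = "block",
         mediators = meds, a = a, b = b, c_prime = c_prime,
         var_treatment = var_t, mediator_resid_cov = med_resid_cov,
         disturbance = disturbance, var_latent = var_h,
         loadings = loadings, indicator_resid = ind_resid,
         discretize_pimbs = FALSE, missingness = missingness,
         seed = as.integer(seed)),
    class = "trial_config")
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf("Synthetic trial configuration (%s): n = %d, allocation %d:%d (%s)\n",
              x$model, x$n_patients, x$allocation[[1]], x$allocation[[2]],
              x$allocation_mode))
  cat("  mediators:", paste(x$mediators, collapse = ", "), "\n")
  cat(sprintf("  direct effect %.3f, latent variance %.1f (disturbance %.1f)\n",
              x$c_prime, x$var_latent, x$disturbance))
  invisible(x)
}

validate_config <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  if (config$n_patients < 1) stop("n_patients must be positive")
  if (any(config$allocation < 0) || sum(config$allocation) <= 0)
    stop("invalid allocation")
  ev <- eigen(config$mediator_resid_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("mediator residual covariance block is not positive definite")
  if (config$disturbance <= 0 || any(config$indicator_resid <= 0))
    stop("non-positive residual variance in configuration")
  if (any(config$missingness < 0) || any(config$missingness >= 1))
    stop("missingness rates must lie in [0, 1)")
  invisible(config)
}

#' Generate a synthetic patient-level trial dataset
#'
#' Draws treatment assignment (deterministic block allocation by default:
#' exactly the configured placebo:active counts, order shuffled; Bernoulli
#' mode optional), mediator change scores as treatment effect plus
#' correlated Gaussian noise, the latent outcome as direct effect plus
#' mediator contributions plus disturbance, and the three MSQ indicator
#' change scores as loading times latent plus residual. PI_MBS can
#' optionally be discretized to the 7-point -3..+3 improvement scale (then
#' still analyzed as continuous). MCAR missingness is applied per the
#' configured rates. Fully seeded and reproducible.
#'
#' @param config A `trial_config` (see [default_truth()]).
#' @param n Optional override of `config$n_patients` (allocation counts are
#'   rescaled proportionally in block mode).
#' @param seed Optional override of `config$seed`.
#' @return A data.frame with `patient_id`, `Treatment` (0/1), one column
#'   per mediator, and `MSQ_EF`, `MSQ_RP`, `MSQ_RR`; the generating config
#'   is attached as attribute `"truth"`.
#' @export
generate_trial <- function(config, n = NULL, seed = NULL) {
  validate_config(config)
  n <- if (is.null(n)) config$n_patients else as.integer(n)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  meds <- config$mediators
  k <- length(meds)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  if (config$allocation_mode == "block") {
    n_active <- round(n * config$allocation[[2]] / sum(config$allocation))
    treatment <- sample(c(rep(0L, n - n_active), rep(1L, n_active)))
  } else {
    treatment <- stats::rbinom(n, 1L, config$allocation[[2]] / sum(config$allocation))
  }

  L <- chol(config$mediator_resid_cov)
  U <- matrix(stats::rnorm(n * k), n, k) %*% L
  M <- outer(treatment, config$a) + U
  colnames(M) <- meds

  H <- config$c_prime * treatment + drop(M %*% config$b) +
    stats::rnorm(n, sd = sqrt(config$disturbance))

  inds <- names(config$loadings)
  Y <- sapply(inds, function(j)
    config$loadings[[j]] * H + stats::rnorm(n, sd = sqrt(config$indicator_resid[[j]])))

  out <- data.frame(patient_id = seq_len(n), Treatment = treatment, M, Y,
                    check.names = FALSE)
  if (config$discretize_pimbs && "PI_MBS" %in% meds)
    out$PI_MBS <- pmax(-3, pmin(3, round(out$PI_MBS)))
  if (length(config$missingness))
    out <- apply_missingness(out, config$missingness, seed = seed + 1L)
  attr(out, "truth") <- config
  out
}

#' Mask cells completely at random
#'
#' @param data A data.frame.
#' @param rates Named numeric vector of per-column missingness
#'   probabilities in `[0, 1)`.
#' @param seed Integer seed (masking is reproducible).
#' @return The data with masked cells set `NA`.
#' @export
apply_missingness <- function(data, rates, seed = 1L) {
  if (any(rates < 0) || any(rates >= 1))
    stop("missingness rates must lie in [0, 1)")
  bad <- setdiff(names(rates), names(data))
  if (length(bad)) stop("unknown columns in rates: ", paste(bad, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (cn in names(rates)) {
    if (rates[[cn]] == 0) next
    mask <- stats::runif(nrow(data)) < rates[[cn]]
    data[[cn]][mask] <- NA
  }
  data
}

#' Analytic mediation decomposition of a generating configuration
#'
#' The population direct, per-mediator indirect, and total effects implied
#' by a generator configuration, with raw-scale percent contributions —
#' the values an infinitely large generated trial would recover.
#'
#' @param config A `trial_config`.
#' @return A data.frame with `effect`, `estimate`, `pct_of_total`.
#' @export
truth_decomposition <- function(config) {
  validate_config(config)
  ind <- config$a * config$b
  total <- config$c_prime + sum(ind)
  est <- c(config$c_prime, ind, sum(ind), total)
  data.frame(
    effect = c("direct", paste0("indirect:", config$mediators),
               "indirect_total", "total"),
    estimate = est, pct_of_total = 100 * est / total,
    stringsAsFactors = FALSE)
}

# preserve the caller's RNG state around seeded draws
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write a generated trial to CSV (with a JSON truth sidecar)
#'
#' @param data A generated trial data.frame.
#' @param path Output CSV path; when `truth_sidecar` is `TRUE` and the
#'   generating configuration is attached, `<path>.truth.json` records the
#'   generating parameters for recovery tests.
#' @param truth_sidecar Write the sidecar?
#' @return `path`, invisibly.
#' @export
write_trial <- function(data, path, truth_sidecar = TRUE) {
  utils::write.csv(data, path, row.names = FALSE)
  truth <- attr(data, "truth")
  if (truth_sidecar && !is.null(truth)) {
    obj <- truth
    obj$mediator_resid_cov <- unname(apply(truth$mediator_resid_cov, 1, as.list))
    class(obj) <- NULL
    jsonlite::write_json(obj, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
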