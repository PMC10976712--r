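#' Standardized solution of a fitted model
#'
#' Rescales every raw parameter estimate by the ratio of the predictor's
#' standard deviation over the outcome's, taking standard deviations from
#' the model-implied covariance of the full variable vector so latent
#' variables are standardized too. Loadings (latent -> indicator) are
#' standardized as `raw * sd(latent) / sd(indicator)`; covariances become
#' correlations; variances become the proportion of the variable's implied
#' variance (residual proportion for endogenous variables).
#'
#' @param fit A `sem_fit`.
#' @param .param_table Internal: a pre-built parameter table to annotate.
#' @return A data.frame with `lhs`, `op`, `rhs`, `estimate`,
#'   `std_estimate`. Paths touching a variable with non-positive implied
#'   variance get `NA` standardized values.
#' @export
standardize <- function(fit, .param_table = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  ram <- fit$ram
  mats <- ram_fill(ram, fit$theta)
  m <- length(ram$var_names)
  E <- solve(diag(m) - mats$A)
  C <- E %*% mats$S %*% t(E)
  v <- diag(C)
  sds <- ifelse(v > 0, sqrt(v), NA_real_)
  names(sds) <- ram$var_names

  tab <- if (is.null(.param_table))
    fit$param_table[, c("lhs", "op", "rhs", "estimate")]
  else .param_table[, c("lhs", "op", "rhs", "estimate")]

  std <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    lhs <- tab$lhs[i]; rhs <- tab$rhs[i]; est <- tab$estimate[i]
    std[i] <- switch(tab$op[i],
      "=~" = est * sds[[lhs]] / sds[[rhs]],
      "~"  = est * sds[[rhs]] / sds[[lhs]],
      "~~" = if (lhs == rhs) est / (sds[[lhs]]^2) else est / (sds[[lhs]] * sds[[rhs]]),
      NA_real_)
  }
  tab$std_estimate <- std
  tab
}

#' Goodness-of-fit indices of a fitted model
#'
#' Computes the chi-square (`scale * F_ML`, `scale = n - 1` under the
#' default Wishart convention), chi-square/df, CFI against the independence
#' baseline (all covariances zero, variances free — which fits in closed
#' form), RMSEA, SRMR over the `p(p+1)/2` unique correlation-metric
#' residuals including the diagonal, and AIC (`-2 logLik + 2 n_free`).
#' Pass flags apply the conventional adequacy cutoffs: chi-square/df < 2.0,
#' CFI > 0.9, RMSEA < 0.05, SRMR < 0.08.
#'
#' For a saturated model (df = 0) the limits are used: RMSEA 0, CFI 1,
#' and the result is flagged `saturated`.
#'
#' @param fit A `sem_fit`.
#' @param thresholds Named list of cutoffs
#'   (`chi_over_df`, `cfi`, `rmsea`, `srmr`).
#' @return An object of class `sem_fit_indices`: `chi_square`, `df`,
#'   `chi_over_df`, `cfi`, `rmsea`, `srmr`, `aic`, `baseline` (chi-square
#'   and df of the independence model), `pass_flags`, `saturated`, `n`.
#' @export
fit_indices <- function(fit, thresholds = list(chi_over_df = 2.0, cfi = 0.9,
                                               rmsea = 0.05, srmr = 0.08)) {
  stopifnot(inherits(fit, "sem_fit"))
  S <- fit$moments$S_obs
  p <- nrow(S)
  n <- fit$moments$n
  scale <- fit$chi_scale
  moments <- p * (p + 1) / 2
  df <- moments - fit$n_free
  chi <- scale * fit$discrepancy

  # independence baseline: Sigma_b = diag(S); F_b has closed form
  F_b <- sum(log(diag(S))) - 2 * sum(log(diag(chol(S))))
  chi_b <- scale * F_b
  df_b <- moments - p

  cfi <- if (df == 0) 1 else {  # saturated limit
    num <- max(chi - df, 0)
    den <- max(chi_b - df_b, chi - df, 0)
    if (den <= 0) 1 else 1 - num / den
  }
  rmsea <- if (df > 0) sqrt(max(chi - df, 0) / (df * (n - 1))) else 0
  Sigma <- implied_covariance(fit$ram, fit$theta)
  d <- sqrt(diag(S))
  Rstd <- (S - Sigma) / tcrossprod(d)
  srmr <- sqrt(sum(Rstd[upper.tri(Rstd, diag = TRUE)]^2) / moments)
  aic <- -2 * fit$loglik + 2 * fit$n_free

  chi_over_df <- if (df > 0) chi / df else NA_real_
  pass <- list(
    chi_over_df = !is.na(chi_over_df) && chi_over_df < thresholds$chi_over_df,
    cfi = cfi > thresholds$cfi,
    rmsea = rmsea < thresholds$rmsea,
    srmr = srmr < thresholds$srmr)
  if (df == 0) pass$chi_over_df <- TRUE  # saturated: trivially adequate

  structure(list(chi_square = chi, df = df, chi_over_df = chi_over_df,
                 cfi = cfi, rmsea = rmsea, srmr = srmr, aic = aic,
                 baseline = list(chi_square = chi_b, df = df_b),
                 pass_flags = pass, thresholds = thresholds,
                 saturated = df == 0, n = n),
            class = "sem_fit_indices")
}

#' @export
print.sem_fit_indices <- function(x, ...) {
  cat(sprintf("chi-square = %.3f on %d df (chi2/df = %s), n = %d%s\n",
              x$chi_square, x$df,
              if (is.na(x$chi_over_df)) "-" else sprintf("%.3f", x$chi_over_df),
              x$n, if (x$saturated) " [saturated]" else ""))
  cat(sprintf("CFI = %.4f, RMSEA = %.4f, SRMR = %.4f, AIC = %.1f\n",
              x$cfi, x$rmsea, x$srmr, x$aic))
  ok <- unlist(x$pass_flags)
  cat("adequacy:", paste(sprintf("%s %s", names(ok), ifelse(ok, "pass", "FAIL")),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' @param fits Named (or unnamed) list of `sem_fit` objects fitted to the
#'   same rows.
#' @return A data.frame ranked by ascending AIC (ties broken by fewer free
#'   parameters) with columns `model`, `aic`, `delta_aic`, `n_free`, `df`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("model", seq_along(fits))
  ns <- vapply(fits, function(f) f$moments$n, 0)
  if (length(unique(ns)) > 1)
    stop("models were fitted to different numbers of rows (",
         paste(ns, collapse = ", "), "); AIC comparison refused")
  tab <- data.frame(
    model = names(fits),
    aic = vapply(fits, function(f) -2 * f$loglik + 2 * f$n_free, 0),
    n_free = vapply(fits, function(f) f$n_free, 0),
    df = vapply(fits, function(f) f$ram$p * (f$ram$p + 1) / 2 - f$n_free, 0),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic, tab$n_free), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab[, c("model", "aic", "delta_aic", "n_free", "df")]
}

#' Backward elimination of non-significant mediators
#'
#' Starting from a full model, repeatedly refits and removes the mediator
#' whose association with the outcome has the largest p-value at or above
#' `alpha`; elimination stops when every remaining mediator's
#' outcome-association p-value is strictly below `alpha`. Removing a
#' mediator drops its outcome path, its treatment path, and any
#' covariances involving it. Protected variables are never candidates.
#'
#' @param data Data.frame of observed variables.
#' @param full_spec A `sem_spec` (or syntax string) containing the outcome
#'   regression on mediators and treatment.
#' @param outcome Name of the outcome variable (typically the latent).
#' @param alpha Significance level; mediators are retained when
#'   `p < alpha` (strict).
#' @param protected Character vector of variables never removed (the
#'   treatment is always protected).
#' @param treatment Name of the treatment variable.
#' @param ... Passed to [fit_sem()].
#' @return A list: `spec` (reduced `sem_spec`), `fit` (final `sem_fit`),
#'   `trace` (data.frame with one row per step and candidate: step,
#'   variable, p_value, action).
#' @export
backward_eliminate <- function(data, full_spec, outcome, alpha = 0.05,
                               protected = character(0),
                               treatment = "Treatment", ...) {
  if (is.character(full_spec)) full_spec <- parse_model(full_spec)
  protected <- union(protected, treatment)
  spec <- full_spec
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    fit <- tryCatch(fit_sem(data, spec, ...), error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) {
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, variable = NA_character_, p_value = NA_real_,
        action = paste0("non-convergence: ",
                        if (inherits(fit, "error")) conditionMessage(fit)
                        else "optimizer did not converge"),
        stringsAsFactors = FALSE)
      break
    }
    tab <- fit$param_table
    cand <- tab[tab$op == "~" & tab$lhs == outcome &
                  !(tab$rhs %in% protected) & tab$free, , drop = FALSE]
    if (!nrow(cand)) break
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, variable = cand$rhs, p_value = cand$p_value,
      action = "evaluated", stringsAsFactors = FALSE)
    worst <- cand[which.max(cand$p_value), ]
    if (is.na(worst$p_value) || worst$p_value < alpha) break
    spec <- drop_mediator(spec, worst$rhs, outcome)
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, variable = worst$rhs, p_value = worst$p_value,
      action = "removed", stringsAsFactors = FALSE)
  }
  final_fit <- fit_sem(data, spec, ...)
  list(spec = spec, fit = final_fit, trace = do.call(rbind, trace))
}

# remove a mediator variable from a spec: its outcome path, every
# regression it appears in (either side), and its covariances
drop_mediator <- function(spec, var, outcome) {
  regs <- spec$regressions
  regs[[outcome]] <- setdiff(regs[[outcome]], var)
  regs[[var]] <- NULL
  regs <- lapply(regs, function(x) setdiff(x, var))
  regs <- regs[lengths(regs) > 0]
  covs <- spec$covariances
  if (nrow(covs))
    covs <- covs[covs[, 1] != var & covs[, 2] != var, , drop = FALSE]
  fixed <- spec$fixed_params
  if (length(fixed)) {
    drop <- grepl(paste0("(^|~)", var, "($|~)"), names(fixed)) |
      grepl(paste0("^", var, "(~|=~)"), names(fixed)) |
      grepl(paste0("(~|=~|~~)", var, "$"), names(fixed))
    fixed <- fixed[!drop]
  }
  used <- unique(c(unlist(spec$latent_defs, use.names = FALSE),
                   names(regs), unlist(regs, use.names = FALSE),
                   as.vector(covs)))
  observed <- spec$observed_vars[spec$observed_vars %in% used]
  out <- structure(
    list(latent_defs = spec$latent_defs, regressions = regs,
         covariances = covs, fixed_params = fixed,
         observed_vars = observed, latent_vars = spec$latent_vars),
    class = "sem_spec")
  validate_spec(out)
  out
}
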