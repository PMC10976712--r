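#' Recompute the published mediation table from the published coefficients
#'
#' Every cell of the published direct/indirect/total effect table that is
#' an arithmetic function of the published coefficient table is recomputed
#' from scratch — per-mediator indirect effects (products `a * b`), summed
#' indirect and total effects, standardized twins (products of the
#' standardized coefficients), independence-form delta-method SEs and z
#' scores for the per-mediator rows, and integer percent contributions —
#' and compared with the published value.
#'
#' Because the published inputs are rounded to 3 decimals, agreement is
#' judged at table precision with first-order propagation of the +-0.0005
#' input rounding (plus half an output ulp): the recomputed value must lie
#' within that interval of the printed one. Summary-row SEs
#' (`indirect_total`, `total`) need the unpublished parameter covariance
#' and are reported but not judged (`checked = FALSE`).
#'
#' @return A data.frame with one row per compared cell: `model`, `effect`,
#'   `quantity`, `recomputed`, `published`, `tolerance`, `checked`,
#'   `pass`. Attribute `"all_pass"` summarizes the judged cells.
#' @export
worked_example_check <- function() {
  rows <- list()
  add <- function(model, effect, quantity, value, published, tol,
                  checked = TRUE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, effect = effect, quantity = quantity,
      recomputed = value, published = published, tolerance = tol,
      checked = checked,
      pass = if (!checked || is.na(published)) NA else abs(value - published) <= tol,
      stringsAsFactors = FALSE)
  }
  # first-order propagation of the 5e-4 rounding radius of each input,
  # plus half an ulp of the printed output
  prop_tol <- function(f, inputs, out_digits = 3) {
    h <- 5e-4
    tot <- 0
    for (i in seq_along(inputs)) {
      up <- dn <- inputs
      up[i] <- up[i] + h; dn[i] <- dn[i] - h
      tot <- tot + abs(do.call(f, as.list(up)) - do.call(f, as.list(dn))) / 2
    }
    tot + 0.5 * 10^(-out_digits)
  }

  for (model in c("model1", "model2")) {
    est <- reference_estimates(model)
    med <- reference_mediation(model)
    reg <- est[est$op == "~", ]
    direct <- reg[reg$lhs == "HRQoL" & reg$rhs == "Treatment", ]
    meds <- canonical_mediators(model)

    ind <- ind_std <- stats::setNames(numeric(length(meds)), meds)
    for (m in meds) {
      am <- reg[reg$lhs == m & reg$rhs == "Treatment", ]
      bm <- reg[reg$lhs == "HRQoL" & reg$rhs == m, ]
      pub <- med[med$effect == paste0("indirect:", m), ]

      f_prod <- function(a, b) a * b
      ind[m] <- am$estimate * bm$estimate
      add(model, paste0("indirect:", m), "estimate", ind[m], pub$estimate,
          prop_tol(f_prod, c(am$estimate, bm$estimate)))
      ind_std[m] <- am$std_estimate * bm$std_estimate
      add(model, paste0("indirect:", m), "std_estimate", ind_std[m],
          pub$std_estimate, prop_tol(f_prod, c(am$std_estimate, bm$std_estimate)))

      f_se <- function(a, sa, b, sb) sobel_se(a, sa, b, sb)
      se <- sobel_se(am$estimate, am$se, bm$estimate, bm$se)
      add(model, paste0("indirect:", m), "se", se, pub$se,
          prop_tol(f_se, c(am$estimate, am$se, bm$estimate, bm$se)))
      f_z <- function(a, sa, b, sb) abs(a * b) / sobel_se(a, sa, b, sb)
      add(model, paste0("indirect:", m), "z", f_z(am$estimate, am$se,
                                                  bm$estimate, bm$se),
          pub$z, prop_tol(f_z, c(am$estimate, am$se, bm$estimate, bm$se)))
    }

    ab <- unlist(lapply(meds, function(m) {
      c(reg$estimate[reg$lhs == m & reg$rhs == "Treatment"],
        reg$estimate[reg$lhs == "HRQoL" & reg$rhs == m])
    }))
    ab_std <- unlist(lapply(meds, function(m) {
      c(reg$std_estimate[reg$lhs == m & reg$rhs == "Treatment"],
        reg$std_estimate[reg$lhs == "HRQoL" & reg$rhs == m])
    }))
    f_sum_prod <- function(...) {
      x <- c(...)
      sum(x[seq(1, length(x), 2)] * x[seq(2, length(x), 2)])
    }
    it_pub <- med[med$effect == "indirect_total", ]
    add(model, "indirect_total", "estimate", sum(ind), it_pub$estimate,
        prop_tol(f_sum_prod, ab))
    add(model, "indirect_total", "std_estimate", sum(ind_std),
        it_pub$std_estimate, prop_tol(f_sum_prod, ab_std))
    add(model, "indirect_total", "se",
        sqrt(sum(vapply(meds, function(m) {
          am <- reg[reg$lhs == m & reg$rhs == "Treatment", ]
          bm <- reg[reg$lhs == "HRQoL" & reg$rhs == m, ]
          sobel_se(am$estimate, am$se, bm$estimate, bm$se)^2
        }, 0))), it_pub$se, NA_real_, checked = FALSE)

    tot_pub <- med[med$effect == "total", ]
    f_total <- function(...) { x <- c(...); x[1] + f_sum_prod(x[-1]) }
    total <- direct$estimate + sum(ind)
    add(model, "total", "estimate", total, tot_pub$estimate,
        prop_tol(f_total, c(direct$estimate, ab)))
    add(model, "total", "std_estimate", direct$std_estimate + sum(ind_std),
        tot_pub$std_estimate, prop_tol(f_total, c(direct$std_estimate, ab_std)))

    # integer percent contributions, half-up, on the raw scale
    for (m in meds) {
      pub <- med[med$effect == paste0("indirect:", m), ]
      add(model, paste0("indirect:", m), "pct_of_total",
          round_half_up(100 * ind[m] / total), pub$pct_of_total, 0)
    }
    dir_pub <- med[med$effect == "direct", ]
    add(model, "direct", "pct_of_total",
        round_half_up(100 * direct$estimate / total), dir_pub$pct_of_total, 0)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, all_pass = all(out$pass[out$checked & !is.na(out$pass)]))
}

#' Read a patient-level dataset from CSV
#'
#' @param path CSV file with a header row naming the observed variables.
#' @param required Optional character vector of columns that must be
#'   present.
#' @return A data.frame; empty cells become `NA`.
#' @export
read_dataset <- function(path, required = NULL) {
  if (!file.exists(path)) stop(input_error("dataset not found: ", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  if (!nrow(d)) stop(input_error("dataset has 0 rows: ", path))
  if (!is.null(required)) {
    miss <- setdiff(required, names(d))
    if (length(miss))
      stop(input_error("dataset lacks required columns: ",
                       paste(miss, collapse = ", ")))
    for (v in required) {
      bad <- which(!is.na(d[[v]]) & is.na(suppressWarnings(as.numeric(d[[v]]))))
      if (length(bad))
        stop(input_error(sprintf("non-numeric value in column '%s', row %d",
                                 v, bad[1])))
      d[[v]] <- as.numeric(d[[v]])
    }
  }
  d
}

input_error <- function(...) {
  structure(class = c("latentmed_input_error", "error", "condition"),
            list(message = paste0(...), call = sys.call(-1)))
}
convergence_error <- function(...) {
  structure(class = c("latentmed_convergence_error", "error", "condition"),
            list(message = paste0(...), call = sys.call(-1)))
}

#' Exit code for a pipeline condition
#'
#' Maps run-time failures onto the command-line contract: 0 success,
#' 2 input/validation error, 3 non-convergence, 1 other error.
#'
#' @param cond A condition object (or `NULL` for success).
#' @return Integer exit code.
#' @export
exit_code <- function(cond) {
  if (is.null(cond)) return(0L)
  if (inherits(cond, "latentmed_input_error")) return(2L)
  if (inherits(cond, "latentmed_convergence_error")) return(3L)
  1L
}

#' Run the full analysis pipeline
#'
#' Loads (or generates) a patient-level dataset, optionally runs backward
#' mediator elimination from a full specification, fits the named models,
#' computes fit indices, mediation decompositions, and the AIC ranking,
#' and (optionally) writes a report directory. Deterministic under a fixed
#' configuration and seed.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{data}{path to a CSV, or `NULL` to use `generator`}
#'     \item{generator}{list: `model` (`"model1"`/`"model2"`), optional
#'       `n`, `seed`, `resid_cor`, `missingness`}
#'     \item{models}{named list of model-syntax strings; default the
#'       canonical syntax for the generator's model}
#'     \item{elimination}{optional list: `full` (syntax), `outcome`,
#'       `alpha`, `protected`}
#'     \item{treatment, outcome}{variable names (defaults `Treatment`,
#'       `HRQoL`)}
#'     \item{se_method}{`"independence"` (default) or `"full"`}
#'     \item{thresholds}{fit-index cutoffs (defaults 2.0/0.9/0.05/0.08)}
#'     \item{output_dir}{optional report directory}
#'     \item{seed}{integer seed}
#'   }
#' @return An object of class `analysis_report`: per-model `fits`,
#'   `indices`, `mediation`, plus `ranking`, `elimination`, `data_log`,
#'   and `provenance` (config digest, seed, package version).
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  treatment <- if (is.null(config$treatment)) "Treatment" else config$treatment
  outcome <- if (is.null(config$outcome)) "HRQoL" else config$outcome
  se_method <- if (is.null(config$se_method)) "independence" else config$se_method

  if (!is.null(config$data)) {
    data <- read_dataset(config$data)
  } else if (!is.null(config$generator)) {
    g <- config$generator
    truth <- default_truth(
      model = if (is.null(g$model)) "model2" else g$model,
      resid_cor = if (is.null(g$resid_cor)) 0.3 else g$resid_cor,
      missingness = if (is.null(g$missingness)) numeric(0)
                    else unlist(g$missingness),
      seed = seed)
    data <- generate_trial(truth, n = g$n, seed = seed)
  } else {
    stop(input_error("config must provide 'data' or 'generator'"))
  }
  if (!nrow(data)) stop(input_error("dataset has 0 rows"))

  models <- config$models
  if (is.null(models)) {
    mk <- if (!is.null(config$generator$model)) config$generator$model else "model2"
    models <- stats::setNames(list(canonical_model(mk)), mk)
  }

  elimination <- NULL
  if (!is.null(config$elimination)) {
    e <- config$elimination
    elimination <- backward_eliminate(
      data, e$full,
      outcome = if (is.null(e$outcome)) outcome else e$outcome,
      alpha = if (is.null(e$alpha)) 0.05 else e$alpha,
      protected = if (is.null(e$protected)) character(0) else e$protected,
      treatment = treatment)
    models <- c(models, list(selected = spec_to_text(elimination$spec)))
  }

  thresholds <- utils::modifyList(
    list(chi_over_df = 2.0, cfi = 0.9, rmsea = 0.05, srmr = 0.08),
    if (is.null(config$thresholds)) list() else config$thresholds)

  fits <- indices <- mediation <- list()
  data_log <- list()
  for (nm in names(models)) {
    fit <- fit_sem(data, models[[nm]])
    if (!fit$converged)
      stop(convergence_error("model '", nm, "' did not converge: ",
                             fit$optimizer$message))
    fits[[nm]] <- fit
    indices[[nm]] <- fit_indices(fit, thresholds)
    mediation[[nm]] <- decompose_effects(fit, treatment, outcome,
                                         se_method = se_method)
    data_log[[nm]] <- list(n_input = fit$moments$n_input, n_used = fit$moments$n,
                           n_deleted = fit$moments$n_input - fit$moments$n)
  }
  ranking <- if (length(fits) >= 2) compare_models(fits) else NULL

  report <- structure(
    list(fits = fits, indices = indices, mediation = mediation,
         ranking = ranking, elimination = elimination, data_log = data_log,
         provenance = list(
           seed = seed,
           config_digest = config_digest(config),
           package_version = as.character(utils::packageVersion("latentmed")),
           r_version = R.version.string,
           timestamp = NA_character_)),  # stamped at write time, not here,
    class = "analysis_report")          # so report objects hash stably
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# order-independent digest of the configuration: serialize canonically
# and hash with a 31-bit multiplicative rolling hash (provenance only,
# not cryptographic)
config_digest <- function(config) {
  canon <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                            digits = NA)
  bytes <- utf8ToInt(as.character(canon))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Latent-outcome mediation analysis report\n")
  for (nm in names(x$fits)) {
    cat(sprintf("\n== %s (n = %d, free parameters = %d) ==\n",
                nm, x$fits[[nm]]$moments$n, x$fits[[nm]]$n_free))
    print(x$indices[[nm]])
    print(x$mediation[[nm]])
  }
  if (!is.null(x$ranking)) {
    cat("\nModel ranking by AIC:\n")
    print(x$ranking, row.names = FALSE)
  }
  invisible(x)
}

#' Write an analysis report to files
#'
#' Per model: a coefficient-table CSV (`<model>_parameters.csv`) and a
#' mediation-table CSV (`<model>_mediation.csv`, full precision; a
#' human-readable `<model>_mediation_formatted.csv` with integer
#' percents). Plus `report.json` with the fit indices, ranking,
#' elimination trace, deletion log, and provenance.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$fits)) {
    write_param_table(report$fits[[nm]], file.path(dir, paste0(nm, "_parameters.csv")))
    utils::write.csv(as.data.frame(report$mediation[[nm]]),
                     file.path(dir, paste0(nm, "_mediation.csv")),
                     row.names = FALSE)
    utils::write.csv(format_mediation(report$mediation[[nm]]),
                     file.path(dir, paste0(nm, "_mediation_formatted.csv")),
                     row.names = FALSE)
  }
  idx <- lapply(report$indices, function(ix)
    ix[c("chi_square", "df", "chi_over_df", "cfi", "rmsea", "srmr", "aic",
         "pass_flags", "saturated", "n")])
  obj <- list(indices = idx,
              ranking = report$ranking,
              elimination_trace = report$elimination$trace,
              data_log = report$data_log,
              provenance = report$provenance)
  jsonlite::write_json(obj, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(dir)
}
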