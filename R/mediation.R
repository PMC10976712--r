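#' Delta-method (Sobel) standard error of a product of coefficients
#'
#' First-order delta-method standard error of `a * b` assuming the two
#' estimates are uncorrelated: `sqrt(b^2 se_a^2 + a^2 se_b^2)`.
#'
#' @param a,b Coefficient estimates.
#' @param se_a,se_b Their standard errors (non-negative).
#' @param cov_ab Optional sampling covariance of `a` and `b`; when supplied
#'   the full first-order form `sqrt(b^2 se_a^2 + a^2 se_b^2 + 2 a b cov_ab)`
#'   is used.
#' @return The standard error of the product (0 when both SEs are 0).
#' @export
sobel_se <- function(a, se_a, b, se_b, cov_ab = 0) {
  stopifnot(se_a >= 0, se_b >= 0)
  v <- b^2 * se_a^2 + a^2 * se_b^2 + 2 * a * b * cov_ab
  sqrt(max(v, 0))
}

#' Decompose a treatment effect into direct and mediator-specific
#' indirect effects
#'
#' For every mediator `m` lying on a `treatment -> m -> outcome` route the
#' indirect effect is the product `a_m * b_m` of the treatment -> mediator
#' and mediator -> outcome coefficients; the total effect is the direct
#' path plus the sum of indirect effects. Standard errors of the products
#' use the first-order delta method; with `se_method = "independence"`
#' (default) the `a` and `b` sampling covariances are ignored (the Sobel
#' form), with `"full"` the fitted parameter covariance matrix is used,
#' including for the summed indirect and total effects. Standardized twins
#' of all effects are built from the standardized coefficients.
#'
#' @param fit A converged `sem_fit`.
#' @param treatment Treatment variable name.
#' @param outcome Outcome variable name (typically the latent).
#' @param se_method `"independence"` or `"full"`.
#' @return An object of class `mediation_table`: a data.frame with rows
#'   `direct`, `indirect:<mediator>` for each mediator, `indirect_total`,
#'   and `total`; columns `effect`, `estimate`, `se`, `z`, `p_value`,
#'   `std_estimate`, `pct_of_total`. Mediators missing either route
#'   component are skipped with a warning.
#' @export
decompose_effects <- function(fit, treatment, outcome,
                              se_method = c("independence", "full")) {
  stopifnot(inherits(fit, "sem_fit"))
  se_method <- match.arg(se_method)
  tab <- fit$param_table
  reg <- tab[tab$op == "~", , drop = FALSE]

  direct <- reg[reg$lhs == outcome & reg$rhs == treatment, , drop = FALSE]
  if (nrow(direct) != 1L)
    stop(sprintf("no direct path %s ~ %s in the fitted model", outcome, treatment))

  # mediators: variables regressed on treatment that the outcome is
  # regressed on
  on_treat <- reg$lhs[reg$rhs == treatment & reg$lhs != outcome]
  into_outcome <- reg$rhs[reg$lhs == outcome & reg$rhs != treatment]
  mediators <- intersect(into_outcome, on_treat)
  orphans <- setdiff(into_outcome, c(mediators, treatment))
  if (length(orphans))
    warning("outcome predictors without a treatment path, excluded from ",
            "the decomposition: ", paste(orphans, collapse = ", "))

  V <- fit$vcov
  labels <- fit$ram$free_index$label
  par_cov <- function(l1, l2) {
    if (is.null(V)) return(0)
    i <- match(l1, labels); j <- match(l2, labels)
    if (is.na(i) || is.na(j)) 0 else V[i, j]
  }

  rows <- list()
  a_lab <- b_lab <- character(0)
  for (m in mediators) {
    am <- reg[reg$lhs == m & reg$rhs == treatment, ]
    bm <- reg[reg$lhs == outcome & reg$rhs == m, ]
    a <- am$estimate; b <- bm$estimate
    cov_ab <- if (se_method == "full")
      par_cov(param_label(m, "~", treatment), param_label(outcome, "~", m)) else 0
    se <- sobel_se(a, am$se, b, bm$se, cov_ab)
    rows[[m]] <- data.frame(
      effect = paste0("indirect:", m), estimate = a * b, se = se,
      std_estimate = am$std_estimate * bm$std_estimate,
      stringsAsFactors = FALSE)
    a_lab <- c(a_lab, param_label(m, "~", treatment))
    b_lab <- c(b_lab, param_label(outcome, "~", m))
  }

  ind_est <- sum(vapply(rows, function(r) r$estimate, 0))
  ind_std <- sum(vapply(rows, function(r) r$std_estimate, 0))

  # delta method for the summed indirect over the stacked (a, b) vector
  ind_se <- if (length(mediators)) {
    if (!is.null(V) && se_method == "full") {
      av <- vapply(a_lab, function(l) fit$theta[match(l, labels)], 0)
      bv <- vapply(b_lab, function(l) fit$theta[match(l, labels)], 0)
      g <- numeric(length(labels))
      for (k in seq_along(mediators)) {
        g[match(a_lab[k], labels)] <- g[match(a_lab[k], labels)] + bv[k]
        g[match(b_lab[k], labels)] <- g[match(b_lab[k], labels)] + av[k]
      }
      sqrt(max(drop(t(g) %*% V %*% g), 0))
    } else {
      sqrt(sum(vapply(rows, function(r) r$se^2, 0)))
    }
  } else 0

  tot_est <- direct$estimate + ind_est
  tot_std <- direct$std_estimate + ind_std
  tot_se <- if (!is.null(V) && se_method == "full") {
    g <- numeric(length(labels))
    for (k in seq_along(mediators)) {
      av <- fit$theta[match(a_lab[k], labels)]
      bv <- fit$theta[match(b_lab[k], labels)]
      g[match(a_lab[k], labels)] <- g[match(a_lab[k], labels)] + bv
      g[match(b_lab[k], labels)] <- g[match(b_lab[k], labels)] + av
    }
    dl <- match(param_label(outcome, "~", treatment), labels)
    g[dl] <- g[dl] + 1
    sqrt(max(drop(t(g) %*% V %*% g), 0))
  } else {
    sqrt(direct$se^2 + ind_se^2)
  }

  out <- rbind(
    data.frame(effect = "direct", estimate = direct$estimate,
               se = direct$se, std_estimate = direct$std_estimate,
               stringsAsFactors = FALSE),
    do.call(rbind, unname(rows)),
    data.frame(effect = "indirect_total", estimate = ind_est, se = ind_se,
               std_estimate = ind_std, stringsAsFactors = FALSE),
    data.frame(effect = "total", estimate = tot_est, se = tot_se,
               std_estimate = tot_std, stringsAsFactors = FALSE))
  out$z <- ifelse(out$se > 0, out$estimate / out$se, NA_real_)
  out$p_value <- ifelse(is.na(out$z), NA_real_, 2 * stats::pnorm(-abs(out$z)))
  out <- out[, c("effect", "estimate", "se", "z", "p_value", "std_estimate")]
  rownames(out) <- NULL
  out <- structure(out, class = c("mediation_table", "data.frame"),
                   treatment = treatment, outcome = outcome,
                   mediators = mediators, se_method = se_method)
  percent_contributions(out)
}

#' Percent contributions of direct and mediator-specific effects
#'
#' Each component's share of the total effect, `100 * component / total`,
#' computed on the raw (unstandardized) scale. Full precision is kept in
#' the `pct_of_total` column; [format_mediation()] rounds half-up to
#' integers for reporting. When the total effect is within `tol` of zero
#' the percentages are undefined and set `NA` with a warning.
#'
#' @param table A `mediation_table`.
#' @param tol Tolerance for a zero total effect.
#' @return The table with a `pct_of_total` column (the summary rows
#'   `indirect_total` and `total` included).
#' @export
percent_contributions <- function(table, tol = 1e-10) {
  stopifnot(inherits(table, "mediation_table"))
  total <- table$estimate[table$effect == "total"]
  if (length(total) != 1L) stop("table has no total row")
  if (abs(total) <= tol) {
    warning("total effect is (numerically) zero; percent contributions undefined")
    table$pct_of_total <- NA_real_
  } else {
    table$pct_of_total <- 100 * table$estimate / total
  }
  table
}

#' Round half away from zero
#'
#' Published clinical tables round halves up (away from zero), unlike
#' base R's round-half-even; this helper implements that reporting
#' convention.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Human-readable mediation table
#'
#' Rounds effects to 3 decimals and percent contributions half-up to
#' integers, the conventions of published mediation tables. The input
#' table keeps full precision.
#'
#' @param table A `mediation_table`.
#' @return A data.frame formatted for display.
#' @export
format_mediation <- function(table) {
  stopifnot(inherits(table, "mediation_table"))
  out <- as.data.frame(table)
  for (cn in c("estimate", "se", "z", "std_estimate"))
    out[[cn]] <- round_half_up(out[[cn]], 3)
  out$p_value <- ifelse(out$p_value < 0.001, "<0.001",
                        sprintf("%.3f", out$p_value))
  out$pct_of_total <- ifelse(is.na(out$pct_of_total), NA,
                             round_half_up(out$pct_of_total))
  out
}

#' @export
print.mediation_table <- function(x, ...) {
  cat(sprintf("Mediation decomposition: %s -> {%s} -> %s (SEs: %s)\n",
              attr(x, "treatment"),
              paste(attr(x, "mediators"), collapse = ", "),
              attr(x, "outcome"), attr(x, "se_method")))
  print(format_mediation(x), row.names = FALSE)
  invisible(x)
}

#' Total treatment effect by path enumeration
#'
#' Independent route to the total effect: sums the products of edge
#' coefficients over every directed path from treatment to outcome in the
#' fitted path matrix. Used as a cross-check of the decomposition identity
#' `total = direct + sum(indirect)`.
#'
#' @param fit A `sem_fit`.
#' @param treatment,outcome Variable names.
#' @return Scalar total effect.
#' @export
total_effect_paths <- function(fit, treatment, outcome) {
  A <- ram_fill(fit$ram, fit$theta)$A
  vars <- fit$ram$var_names
  from <- match(treatment, vars); to <- match(outcome, vars)
  stopifnot(!is.na(from), !is.na(to))
  # sum over all directed paths = (I - A)^{-1} restricted to regressions;
  # done explicitly by depth-first enumeration to stay independent of the
  # matrix identity used elsewhere
  total <- 0
  walk <- function(node, prod, visited) {
    nexts <- which(A[, node] != 0)
    for (nx in nexts) {
      if (nx %in% visited) next
      val <- prod * A[nx, node]
      if (nx == to) total <<- total + val
      else walk(nx, val, c(visited, nx))
    }
  }
  walk(from, 1, from)
  total
}
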