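#' Sample moments from a patient-level table
#'
#' Computes the observed covariance matrix of the model variables after
#' listwise deletion of rows with any missing value on those variables.
#' The unbiased (n - 1) denominator is used.
#'
#' @param data A data.frame with one row per analysis unit.
#' @param vars Character vector of observed variable names to retain.
#' @return An object of class `sem_moments`: `S_obs` (covariance matrix),
#'   `n` (rows after deletion), `n_input` (rows before deletion),
#'   `var_names`.
#' @export
sample_moments <- function(data, vars) {
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("data is missing model variables: ", paste(miss, collapse = ", "))
  X <- data[, vars, drop = FALSE]
  for (v in vars)
    if (!is.numeric(X[[v]]))
      stop("non-numeric column: ", v)
  keep <- stats::complete.cases(X)
  Xc <- as.matrix(X[keep, , drop = FALSE])
  n <- nrow(Xc)
  if (n < length(vars) + 1L)
    stop(sprintf("too few complete rows (%d) for %d variables", n, length(vars)))
  structure(list(S_obs = stats::cov(Xc), n = n, n_input = nrow(X),
                 var_names = vars),
            class = "sem_moments")
}

#' Model-implied covariance matrix
#'
#' Evaluates `Sigma(theta) = F (I - A)^-1 S (I - A)^-T F^T` at a free
#' parameter vector.
#'
#' @param ram A `sem_ram`.
#' @param theta Numeric vector of free-parameter values, in `free_index`
#'   order.
#' @return Symmetric `p x p` matrix over the observed variables.
#' @export
implied_covariance <- function(ram, theta) {
  mats <- ram_fill(ram, theta)
  m <- length(ram$var_names)
  IA <- diag(m) - mats$A
  E <- tryCatch(solve(IA), error = function(e)
    stop("singular (I - A): the directed paths form a non-recursive cycle ",
         "or an exactly collinear system"))
  C <- E %*% mats$S %*% t(E)
  Sigma <- ram$F %*% C %*% t(ram$F)
  (Sigma + t(Sigma)) / 2
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p`, the normal-theory
#' maximum-likelihood fit function. It is zero if and only if
#' `Sigma = S` and positive otherwise.
#'
#' @param S_obs Observed covariance matrix (positive definite).
#' @param sigma Model-implied covariance matrix (positive definite).
#' @param p Number of observed variables (defaults to `nrow(S_obs)`).
#' @return Non-negative scalar.
#' @export
ml_discrepancy <- function(S_obs, sigma, p = nrow(S_obs)) {
  ld_S <- determinant_pd(S_obs, "S_obs")
  ld_Sig <- determinant_pd(sigma, "sigma")
  ld_Sig$logdet + sum(diag(S_obs %*% ld_Sig$inv)) - ld_S$logdet - p
}

# log-determinant + inverse via Cholesky; errors if not positive definite
determinant_pd <- function(M, what) {
  R <- tryCatch(chol(M), error = function(e)
    stop(sprintf("matrix '%s' is not positive definite", what)))
  list(logdet = 2 * sum(log(diag(R))), inv = chol2inv(R))
}

# objective and analytic gradient of F_ML(theta); returns a large finite
# value outside the positive-definite region so nlminb can backtrack
make_objective <- function(ram, S_obs) {
  p <- ram$p
  m <- length(ram$var_names)
  ld_S <- 2 * sum(log(diag(chol(S_obs))))
  Fm <- ram$F
  fi <- ram$free_index
  isA <- fi$matrix == "A"
  isDiag <- !isA & fi$row == fi$col

  eval_point <- function(theta) {
    mats <- ram_fill(ram, theta)
    IA <- diag(m) - mats$A
    E <- tryCatch(solve(IA), error = function(e) NULL)
    if (is.null(E)) return(NULL)
    C <- E %*% mats$S %*% t(E)          # full implied covariance (latents too)
    Sigma <- Fm %*% C %*% t(Fm)
    Sigma <- (Sigma + t(Sigma)) / 2
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Sig_inv <- chol2inv(R)
    list(E = E, C = C, Sigma = Sigma, Sig_inv = Sig_inv,
         logdet = 2 * sum(log(diag(R))))
  }

  objective <- function(theta) {
    pt <- eval_point(theta)
    if (is.null(pt)) return(1e12)
    pt$logdet + sum(S_obs * pt$Sig_inv) - ld_S - p
  }

  gradient <- function(theta) {
    pt <- eval_point(theta)
    if (is.null(pt)) return(rep(0, length(theta)))
    # dF = tr(W dSigma), W = Sigma^-1 (Sigma - S) Sigma^-1
    W <- pt$Sig_inv %*% (pt$Sigma - S_obs) %*% pt$Sig_inv
    G <- t(Fm) %*% W %*% Fm              # m x m
    GE <- G %*% pt$E
    CGE <- pt$C %*% GE                   # for A cells
    EtGE <- t(pt$E) %*% GE               # for S cells
    g <- numeric(length(theta))
    if (any(isA)) g[isA] <- 2 * CGE[cbind(fi$col[isA], fi$row[isA])]
    offS <- !isA & !isDiag
    if (any(offS)) g[offS] <- 2 * EtGE[cbind(fi$row[offS], fi$col[offS])]
    if (any(isDiag)) g[isDiag] <- EtGE[cbind(fi$row[isDiag], fi$col[isDiag])]
    g
  }

  list(objective = objective, gradient = gradient, eval_point = eval_point)
}

# deterministic start values: loadings 1, regressions 0, covariances 0,
# variances from sample variances (half for endogenous residuals)
start_values <- function(ram, S_obs) {
  fi <- ram$free_index
  obs <- ram$observed_vars
  endo <- unique(c(names(ram$spec$regressions),
                   unlist(ram$spec$latent_defs, use.names = FALSE)))
  theta <- numeric(nrow(fi))
  for (i in seq_len(nrow(fi))) {
    lab <- fi$label[i]
    if (fi$matrix[i] == "A") {
      theta[i] <- if (grepl("=~", lab, fixed = TRUE)) 1 else 0
    } else if (fi$row[i] == fi$col[i]) {
      v <- ram$var_names[fi$row[i]]
      if (v %in% obs) {
        s2 <- S_obs[v, v]
        theta[i] <- if (v %in% endo) s2 / 2 else s2
      } else {
        # latent: half the marker indicator's variance
        marker <- ram$spec$latent_defs[[v]][1]
        theta[i] <- S_obs[marker, marker] / 2
      }
    } else {
      theta[i] <- 0
    }
  }
  theta
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy [ml_discrepancy()] between the
#' sample covariance matrix and the RAM-implied covariance with
#' [stats::nlminb()], using an analytic gradient. Rows with missing values
#' on any model variable are removed listwise before computing moments.
#' Standard errors come from the observed information of the
#' covariance-structure log-likelihood (`scale/2` times the Hessian of
#' `F_ML`, `scale = n - 1` under the default Wishart convention).
#'
#' Negative variance estimates (Heywood cases) are reported with a warning
#' recorded in the result rather than bounded away, so the diagnostics stay
#' visible; set `bound_variances = TRUE` to constrain variances to be
#' non-negative.
#'
#' @param data A data.frame of observed variables, or a `sem_moments`
#'   object.
#' @param spec A `sem_spec` or a model-syntax string.
#' @param chi_convention `"n-1"` (Wishart, default) or `"n"`: the factor
#'   scaling `F_ML` into the chi-square and the information matrix.
#' @param bound_variances If `TRUE`, variance parameters get a lower bound
#'   of 0 during optimization.
#' @param start Optional numeric start vector (free-parameter order);
#'   defaults to deterministic starts (loadings 1, regressions and
#'   covariances 0, variances from the sample).
#' @param control Control list passed to [stats::nlminb()]; defaults set
#'   tight tolerances (`rel.tol = 1e-12`, up to 2000 iterations).
#' @return An object of class `sem_fit`: `theta`, `se`, `param_table`
#'   (data.frame with lhs/op/rhs, estimate, se, z, p-value, standardized
#'   estimate, free flag), `loglik`, `n_free`, `converged`, `discrepancy`,
#'   `chi_scale`, `vcov` (free-parameter covariance), `ram`, `moments`,
#'   `warnings`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(200))
#' d$y <- 0.5 * d$x + rnorm(200)
#' fit <- fit_sem(d, "y ~ x")
#' coef(fit)
#' @export
fit_sem <- function(data, spec, chi_convention = c("n-1", "n"),
                    bound_variances = FALSE, start = NULL, control = list()) {
  chi_convention <- match.arg(chi_convention)
  if (is.character(spec)) spec <- parse_model(spec)
  validate_spec(spec)
  ram <- to_ram(spec)
  id <- check_identification(ram)
  if (!id$ok)
    stop(sprintf("model not identified: %d free parameters > %d observed moments",
                 id$n_free, id$moments))

  moments <- if (inherits(data, "sem_moments")) data
             else sample_moments(data, ram$observed_vars)
  ord <- match(ram$observed_vars, moments$var_names)
  if (anyNA(ord))
    stop("moments do not cover model variables: ",
         paste(ram$observed_vars[is.na(ord)], collapse = ", "))
  S_obs <- moments$S_obs[ord, ord, drop = FALSE]
  n <- moments$n
  p <- ram$p

  obj <- make_objective(ram, S_obs)
  theta0 <- if (is.null(start)) start_values(ram, S_obs) else start
  fi <- ram$free_index
  lower <- rep(-Inf, nrow(fi))
  if (bound_variances) lower[fi$matrix == "S" & fi$row == fi$col] <- 0
  ctrl <- utils::modifyList(list(eval.max = 5000, iter.max = 2000,
                                 rel.tol = 1e-12), control)
  opt <- stats::nlminb(theta0, obj$objective, gradient = obj$gradient,
                       lower = lower, control = ctrl)
  theta <- opt$par
  grad <- obj$gradient(theta)
  # converged when the gradient max-norm is small; nlminb's own code is
  # accepted too (its "singular convergence" merely means rel.tol was
  # unreachable in finite precision)
  max_grad <- max(abs(grad))
  converged <- is.finite(opt$objective) && opt$objective < 1e11 &&
    (max_grad < 1e-6 || (opt$convergence == 0 && max_grad < 1e-4))

  warnings <- character(0)
  var_rows <- which(fi$matrix == "S" & fi$row == fi$col)
  heywood <- var_rows[theta[var_rows] < 0]
  if (length(heywood))
    warnings <- c(warnings,
                  paste0("Heywood case: negative variance estimate for ",
                         paste(fi$label[heywood], collapse = ", ")))

  scale <- if (chi_convention == "n-1") n - 1 else n
  F_min <- obj$objective(theta)
  # observed information = (scale/2) * Hessian of F_ML
  H <- jacobian_cd(obj$gradient, theta)
  H <- (H + t(H)) / 2
  info <- (scale / 2) * H
  vcov <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(vcov)) rep(NA_real_, length(theta)) else {
    d <- diag(vcov)
    ifelse(d >= 0, sqrt(d), NA_real_)
  }
  if (is.null(vcov))
    warnings <- c(warnings, "singular information matrix: standard errors undefined")

  pt <- eval_sigma <- obj$eval_point(theta)
  loglik <- -(scale / 2) * (p * log(2 * pi) + eval_sigma$logdet +
                              sum(S_obs * eval_sigma$Sig_inv))

  fit <- structure(
    list(theta = theta, se = se, loglik = loglik, n_free = length(theta),
         converged = converged, discrepancy = F_min, chi_scale = scale,
         chi_convention = chi_convention, vcov = vcov, ram = ram,
         moments = list(S_obs = S_obs, n = n, n_input = moments$n_input,
                        var_names = ram$observed_vars),
         optimizer = list(convergence = opt$convergence,
                          message = opt$message, iterations = opt$iterations,
                          max_abs_gradient = max(abs(grad))),
         warnings = warnings),
    class = "sem_fit")
  fit$param_table <- build_param_table(fit)
  fit
}

# central-difference Jacobian of a vector-valued function (used on the
# analytic gradient, giving the Hessian of the objective)
jacobian_cd <- function(f, x, eps = 1e-5) {
  k <- length(x)
  J <- matrix(0, k, k)
  for (i in seq_len(k)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# full parameter table (free + fixed rows), with standardized estimates
build_param_table <- function(fit) {
  ram <- fit$ram
  fi <- ram$free_index
  split_label <- function(lab) {
    for (op in c("=~", "~~", "~")) {
      if (grepl(op, lab, fixed = TRUE)) {
        bits <- strsplit(lab, op, fixed = TRUE)[[1]]
        return(c(bits[1], op, bits[2]))
      }
    }
    c(lab, "", "")
  }
  free_rows <- t(vapply(fi$label, split_label, character(3)))
  tab <- data.frame(lhs = free_rows[, 1], op = free_rows[, 2],
                    rhs = free_rows[, 3], estimate = fit$theta,
                    se = fit$se, free = TRUE, stringsAsFactors = FALSE)
  if (length(ram$fixed)) {
    fx_rows <- t(vapply(names(ram$fixed), split_label, character(3)))
    tab <- rbind(tab, data.frame(lhs = fx_rows[, 1], op = fx_rows[, 2],
                                 rhs = fx_rows[, 3],
                                 estimate = unname(unlist(ram$fixed)),
                                 se = 0, free = FALSE,
                                 stringsAsFactors = FALSE))
  }
  tab$z <- ifelse(tab$free & tab$se > 0, tab$estimate / tab$se, NA_real_)
  tab$p_value <- ifelse(is.na(tab$z), NA_real_, 2 * stats::pnorm(-abs(tab$z)))
  std <- standardize(fit, .param_table = tab)
  tab$std_estimate <- std$std_estimate[match(paste(tab$lhs, tab$op, tab$rhs),
                                             paste(std$lhs, std$op, std$rhs))]
  rownames(tab) <- NULL
  tab
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat(sprintf("SEM fit by maximum likelihood (%s): %s\n",
              x$chi_convention,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  n = %d (of %d input rows), free parameters = %d, F_ML = %.6f\n",
              x$moments$n, x$moments$n_input, x$n_free, x$discrepancy))
  tab <- x$param_table
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$z <- round(tab$z, digits)
  tab$p_value <- signif(tab$p_value, 3)
  tab$std_estimate <- round(tab$std_estimate, digits)
  print(tab[, c("lhs", "op", "rhs", "estimate", "se", "z", "p_value",
                "std_estimate")], row.names = FALSE)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.sem_fit <- function(object, ...) {
  stats::setNames(object$theta, object$ram$free_index$label)
}

#' @export
logLik.sem_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free,
            nobs = object$moments$n, class = "logLik")
}

#' @export
vcov.sem_fit <- function(object, ...) {
  v <- object$vcov
  if (!is.null(v)) dimnames(v) <- list(object$ram$free_index$label,
                                       object$ram$free_index$label)
  v
}

#' Standard errors of the free parameters
#'
#' @param fit A `sem_fit`.
#' @return Named numeric vector (free-parameter order); `NA` where the
#'   information matrix was singular.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  stats::setNames(fit$se, fit$ram$free_index$label)
}

#' Write a fitted parameter table to CSV
#'
#' Columns: lhs, op, rhs, estimate, se, z, p_value, std_estimate — the shape
#' of a published SEM coefficient table.
#'
#' @param fit A `sem_fit`.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_param_table <- function(fit, path) {
  tab <- fit$param_table[, c("lhs", "op", "rhs", "estimate", "se", "z",
                             "p_value", "std_estimate")]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
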