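#' Translate a model specification into RAM matrices
#'
#' The reticular-action-model (RAM) form represents the model over the
#' joint variable vector (observed then latent) with three matrices:
#' `A` holds directed-path coefficients (loadings and regressions; `A[i, j]`
#' is the path from variable `j` to variable `i`), `S` holds variances and
#' covariances (residual for endogenous variables, full for exogenous), and
#' the filter `F` selects the observed rows. The model-implied covariance of
#' the observed variables is `F (I - A)^-1 S (I - A)^-T F^T`.
#'
#' Every variable receives a variance cell in `S`. Declared covariances get
#' off-diagonal cells; in addition, pairs of exogenous variables (observed
#' variables never appearing as an outcome, and latents never regressed on
#' anything) are freed by convention, matching the usual behaviour of
#' covariance-structure software. Free parameters are enumerated
#' deterministically: loadings, then regressions, then covariances, then
#' variances, each block alphabetical by label, so all downstream output is
#' reproducible.
#'
#' @param spec A `sem_spec` from [parse_model()].
#' @return An object of class `sem_ram`: matrices `A`, `S`, `F`, the
#'   data.frame `free_index` (columns `label`, `matrix`, `row`, `col`),
#'   named numeric `fixed` (label -> value for fixed non-zero cells),
#'   `var_names` (observed then latent), `observed_vars`, `p` (number of
#'   observed variables).
#' @export
to_ram <- function(spec) {
  validate_spec(spec)
  obs <- spec$observed_vars
  lat <- spec$latent_vars
  vars <- c(obs, lat)
  m <- length(vars)
  p <- length(obs)
  idx <- stats::setNames(seq_len(m), vars)

  A <- matrix(0, m, m, dimnames = list(vars, vars))
  S <- matrix(0, m, m, dimnames = list(vars, vars))
  Fm <- matrix(0, p, m, dimnames = list(obs, vars))
  Fm[cbind(seq_len(p), seq_len(p))] <- 1

  fixed <- spec$fixed_params
  free <- list(loading = list(), regression = list(),
               covariance = list(), variance = list())
  fixed_used <- character(0)

  add_cell <- function(kind, label, mat, i, j) {
    if (label %in% names(fixed)) {
      fixed_used <<- c(fixed_used, label)
      if (mat == "A") A[i, j] <<- fixed[[label]]
      else { S[i, j] <<- fixed[[label]]; S[j, i] <<- fixed[[label]] }
    } else {
      free[[kind]][[label]] <<- data.frame(label = label, matrix = mat,
                                           row = i, col = j,
                                           stringsAsFactors = FALSE)
    }
  }

  for (l in lat)
    for (ind in spec$latent_defs[[l]])
      add_cell("loading", param_label(l, "=~", ind), "A", idx[[ind]], idx[[l]])
  for (y in names(spec$regressions))
    for (x in spec$regressions[[y]])
      add_cell("regression", param_label(y, "~", x), "A", idx[[y]], idx[[x]])

  # covariances: declared, plus exogenous-pair convention
  endo <- unique(c(names(spec$regressions),
                   unlist(spec$latent_defs, use.names = FALSE)))
  exo <- setdiff(vars, endo)
  pairs <- spec$covariances
  if (length(exo) > 1L) {
    extra <- t(utils::combn(sort(exo), 2))
    have <- if (nrow(pairs)) apply(pairs, 1, function(r) paste(sort(r), collapse = "|")) else character(0)
    keep <- !(paste(extra[, 1], extra[, 2], sep = "|") %in% have)
    pairs <- rbind(pairs, extra[keep, , drop = FALSE])
  }
  if (nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      pr <- sort(pairs[r, ])
      add_cell("covariance", param_label(pr[1], "~~", pr[2]), "S",
               idx[[pr[1]]], idx[[pr[2]]])
    }

  for (v in vars)
    add_cell("variance", param_label(v, "~~", v), "S", idx[[v]], idx[[v]])

  free_index <- do.call(rbind, lapply(free, function(block) {
    if (!length(block)) return(NULL)
    do.call(rbind, block[order(names(block))])
  }))
  rownames(free_index) <- NULL

  unknown_fixed <- setdiff(names(fixed), fixed_used)
  if (length(unknown_fixed))
    stop("fixed_params refer to paths absent from the model: ",
         paste(unknown_fixed, collapse = ", "))

  structure(list(A = A, S = S, F = Fm, free_index = free_index,
                 fixed = fixed, var_names = vars, observed_vars = obs,
                 latent_vars = lat, p = p, spec = spec),
            class = "sem_ram")
}

#' Number of free parameters of a RAM model
#' @param ram A `sem_ram`.
#' @return Integer count of free parameters.
#' @export
count_free_parameters <- function(ram) {
  stopifnot(inherits(ram, "sem_ram"))
  nrow(ram$free_index)
}

#' Order-condition identification check
#'
#' A covariance-structure model can be estimated only if the number of free
#' parameters does not exceed the number of distinct observed moments,
#' `p (p + 1) / 2` for `p` observed variables. This is the necessary order
#' condition only; it does not guarantee (local) identification.
#'
#' @param ram A `sem_ram`.
#' @return A list with `ok` (logical), `moments` (`p(p+1)/2`), `n_free`,
#'   `df` (`moments - n_free`), `p`.
#' @export
check_identification <- function(ram) {
  stopifnot(inherits(ram, "sem_ram"))
  p <- ram$p
  moments <- p * (p + 1) / 2
  n_free <- count_free_parameters(ram)
  list(ok = n_free <= moments, moments = moments, n_free = n_free,
       df = moments - n_free, p = p)
}

#' @export
print.sem_ram <- function(x, ...) {
  id <- check_identification(x)
  cat(sprintf("RAM model: %d observed + %d latent variables\n",
              x$p, length(x$latent_vars)))
  cat(sprintf("  free parameters: %d, observed moments: %d (df = %d) -> %s\n",
              id$n_free, id$moments, id$df,
              if (id$ok) "order condition satisfied" else "NOT identified (order condition)"))
  invisible(x)
}

# insert a free-parameter vector into copies of A and S
ram_fill <- function(ram, theta) {
  fi <- ram$free_index
  stopifnot(length(theta) == nrow(fi))
  A <- ram$A; S <- ram$S
  isA <- fi$matrix == "A"
  if (any(isA)) A[cbind(fi$row[isA], fi$col[isA])] <- theta[isA]
  if (any(!isA)) {
    rs <- fi$row[!isA]; cs <- fi$col[!isA]; th <- theta[!isA]
    S[cbind(rs, cs)] <- th
    S[cbind(cs, rs)] <- th
  }
  list(A = A, S = S)
}

#' Serialize RAM matrices to JSON
#'
#' Matrices are written as nested arrays and the free-parameter index as a
#' map from parameter label to `[row, col]` (1-based) with its matrix.
#'
#' @param ram A `sem_ram`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
ram_to_json <- function(ram, path = NULL) {
  fi <- ram$free_index
  obj <- list(
    var_names = ram$var_names, observed_vars = ram$observed_vars, p = ram$p,
    A = unname(apply(ram$A, 1, as.list)),
    S = unname(apply(ram$S, 1, as.list)),
    F = unname(apply(ram$F, 1, as.list)),
    free_index = stats::setNames(
      lapply(seq_len(nrow(fi)),
             function(i) list(matrix = fi$matrix[i], cell = c(fi$row[i], fi$col[i]))),
      fi$label))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
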