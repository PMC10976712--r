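#' Parse model syntax into a structural equation model specification
#'
#' The syntax uses one relation per line (or `;`-separated), in the style
#' common to covariance-structure software:
#'
#' * `F =~ y1 + y2 + y3` declares a latent variable `F` measured by the
#'   listed indicators. The first indicator is the marker variable: its
#'   loading is fixed to 1 to give the latent a scale, unless an explicit
#'   `k*` prefix overrides the fixed value.
#' * `y ~ x1 + x2` declares regressions of `y` on each predictor.
#' * `x ~~ z` frees the (residual) covariance between `x` and `z`.
#' * A numeric prefix `k*var` on a right-hand-side term fixes that
#'   parameter at `k` instead of estimating it.
#' * `#` starts a comment; blank lines are ignored.
#'
#' Variables never appearing on the left of `=~` are observed. Every
#' variable used in a regression or covariance must be observed or a
#' declared latent. Self-loops (`y ~ y`) and duplicate parameter paths are
#' errors.
#'
#' @param text Model syntax: a single string (possibly multi-line) or a
#'   character vector of lines.
#' @return An object of class `sem_spec` with components `latent_defs`
#'   (named list: latent -> ordered indicator names), `regressions` (named
#'   list: outcome -> predictor names), `covariances` (two-column character
#'   matrix of unordered pairs), `fixed_params` (named numeric vector keyed
#'   by parameter label), `observed_vars` and `latent_vars` (ordered name
#'   vectors).
#' @examples
#' spec <- parse_model("
#'   HRQoL =~ MSQ_EF + MSQ_RP + MSQ_RR
#'   HRQoL ~ MMDs + Treatment
#'   MMDs  ~ Treatment
#' ")
#' spec
#' @seealso [to_ram()], [fit_sem()]
#' @export
parse_model <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "[\n;]"))
  lines <- sub("#.*$", "", lines)
  latent_defs <- list()
  regressions <- list()
  cov_pairs <- character(0)  # "a|b" normalized keys
  cov_mat <- matrix(character(0), ncol = 2)
  fixed <- numeric(0)

  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    op <- if (grepl("=~", ln, fixed = TRUE)) "=~"
          else if (grepl("~~", ln, fixed = TRUE)) "~~"
          else if (grepl("~", ln, fixed = TRUE)) "~"
          else stop(sprintf("line %d: no relation operator (=~, ~, ~~) in '%s'", i, ln))
    parts <- strsplit(ln, op, fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(trimws(parts[1])) || !nzchar(trimws(parts[2])))
      stop(sprintf("line %d: malformed relation '%s'", i, ln))
    lhs <- trimws(parts[1])
    if (!is_valid_name(lhs))
      stop(sprintf("line %d: invalid variable name '%s'", i, lhs))
    rhs_terms <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    if (any(!nzchar(rhs_terms)))
      stop(sprintf("line %d: empty term on right-hand side", i))

    for (term in rhs_terms) {
      fx <- parse_term(term, i)
      v <- fx$var
      if (op == "=~") {
        if (v == lhs) stop(sprintf("line %d: latent '%s' cannot indicate itself", i, lhs))
        cur <- latent_defs[[lhs]]
        if (v %in% cur) stop(sprintf("line %d: duplicate indicator '%s' for '%s'", i, v, lhs))
        latent_defs[[lhs]] <- c(cur, v)
        if (!is.na(fx$fixed)) fixed[[param_label(lhs, "=~", v)]] <- fx$fixed
      } else if (op == "~") {
        if (v == lhs) stop(sprintf("line %d: self-loop '%s ~ %s'", i, lhs, v))
        cur <- regressions[[lhs]]
        if (v %in% cur) stop(sprintf("line %d: duplicate regression path '%s ~ %s'", i, lhs, v))
        regressions[[lhs]] <- c(cur, v)
        if (!is.na(fx$fixed)) fixed[[param_label(lhs, "~", v)]] <- fx$fixed
      } else {
        pr <- sort(c(lhs, v))
        key <- paste(pr, collapse = "|")
        if (key %in% cov_pairs)
          stop(sprintf("line %d: duplicate covariance '%s ~~ %s'", i, lhs, v))
        cov_pairs <- c(cov_pairs, key)
        cov_mat <- rbind(cov_mat, pr)
        if (!is.na(fx$fixed)) fixed[[param_label(pr[1], "~~", pr[2])]] <- fx$fixed
      }
    }
  }

  latents <- names(latent_defs)
  used <- unique(c(
    unlist(latent_defs, use.names = FALSE),
    names(regressions), unlist(regressions, use.names = FALSE),
    as.vector(cov_mat)
  ))
  observed <- setdiff(used, latents)
  # keep first-appearance order for observed variables
  observed <- used[used %in% observed]

  for (l in latents) {
    ind <- latent_defs[[l]]
    bad <- intersect(ind, latents)
    if (length(bad))
      stop(sprintf("higher-order latent indicators are not supported: '%s' indicates '%s'", bad[1], l))
    # marker-variable scaling: first indicator fixed to 1 unless overridden
    lab <- param_label(l, "=~", ind[1])
    if (!(lab %in% names(fixed))) fixed[[lab]] <- 1
  }

  spec <- structure(
    list(latent_defs = latent_defs, regressions = regressions,
         covariances = unname(cov_mat), fixed_params = fixed,
         observed_vars = observed, latent_vars = latents),
    class = "sem_spec")
  validate_spec(spec)
  spec
}

is_valid_name <- function(x) grepl("^[A-Za-z._][A-Za-z0-9._]*$", x)

parse_term <- function(term, line_no) {
  if (grepl("*", term, fixed = TRUE)) {
    bits <- trimws(strsplit(term, "*", fixed = TRUE)[[1]])
    if (length(bits) != 2L) stop(sprintf("line %d: malformed term '%s'", line_no, term))
    val <- suppressWarnings(as.numeric(bits[1]))
    if (is.na(val)) stop(sprintf("line %d: non-numeric fixed value in '%s'", line_no, term))
    if (!is_valid_name(bits[2]))
      stop(sprintf("line %d: invalid variable name '%s'", line_no, bits[2]))
    list(var = bits[2], fixed = val)
  } else {
    if (!is_valid_name(term))
      stop(sprintf("line %d: invalid variable name '%s'", line_no, term))
    list(var = term, fixed = NA_real_)
  }
}

param_label <- function(lhs, op, rhs) paste0(lhs, op, rhs)

validate_spec <- function(spec) {
  stopifnot(inherits(spec, "sem_spec"))
  all_vars <- c(spec$observed_vars, spec$latent_vars)
  if (anyDuplicated(all_vars))
    stop("variable declared as both latent and observed: ",
         paste(all_vars[duplicated(all_vars)], collapse = ", "))
  for (l in spec$latent_vars)
    if (length(spec$latent_defs[[l]]) < 1L)
      stop(sprintf("latent '%s' has no indicators", l))
  refd <- unique(c(names(spec$regressions),
                   unlist(spec$regressions, use.names = FALSE),
                   as.vector(spec$covariances)))
  unknown <- setdiff(refd, all_vars)
  if (length(unknown))
    stop("undeclared variables: ", paste(unknown, collapse = ", "))
  invisible(spec)
}

#' Render a model specification back to model syntax
#'
#' Produces an order-normalized syntax string: latent definitions first,
#' then regressions, then covariances, each block with the specification's
#' stored ordering. `parse_model(spec_to_text(s))` is structurally identical
#' to `s`.
#'
#' @param spec A `sem_spec`.
#' @return A single character string of model syntax.
#' @export
spec_to_text <- function(spec) {
  validate_spec(spec)
  out <- character(0)
  fx <- spec$fixed_params
  dress <- function(lhs, op, rhs) {
    lab <- param_label(lhs, op, rhs)
    if (lab %in% names(fx)) paste0(format(fx[[lab]]), "*", rhs) else rhs
  }
  for (l in names(spec$latent_defs)) {
    ind <- spec$latent_defs[[l]]
    out <- c(out, paste(l, "=~", paste(vapply(ind, function(v) dress(l, "=~", v), ""),
                                       collapse = " + ")))
  }
  for (y in names(spec$regressions)) {
    xs <- spec$regressions[[y]]
    out <- c(out, paste(y, "~", paste(vapply(xs, function(v) dress(y, "~", v), ""),
                                      collapse = " + ")))
  }
  if (nrow(spec$covariances))
    for (r in seq_len(nrow(spec$covariances))) {
      pr <- spec$covariances[r, ]
      out <- c(out, paste(pr[1], "~~", dress(pr[1], "~~", pr[2])))
    }
  paste(out, collapse = "\n")
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("Structural equation model specification\n")
  cat("  latents: ", if (length(x$latent_vars)) paste(x$latent_vars, collapse = ", ") else "(none)", "\n")
  cat("  observed:", paste(x$observed_vars, collapse = ", "), "\n")
  n_load <- sum(lengths(x$latent_defs))
  cat(sprintf("  %d loadings, %d regression paths, %d covariances, %d fixed parameters\n",
              n_load, sum(lengths(x$regressions)), nrow(x$covariances),
              length(x$fixed_params)))
  invisible(x)
}

#' Serialize a model specification to JSON
#'
#' @param spec A `sem_spec`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
spec_to_json <- function(spec, path = NULL) {
  validate_spec(spec)
  obj <- list(
    latent_defs = spec$latent_defs,
    regressions = spec$regressions,
    covariances = apply(spec$covariances, 1, function(r) as.list(r)),
    fixed_params = as.list(spec$fixed_params),
    observed_vars = spec$observed_vars,
    latent_vars = spec$latent_vars)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
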