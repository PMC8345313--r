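# Declarative SEM model specification. Latent factors with indicator lists,
# directed regressions among latents (observed covariates enter as
# single-indicator latents), free/fixed covariances among exogenous factors,
# orthogonality groups, and the identification rule.

#' Specify a structural equation model
#'
#' @param latents named list; each element is the character vector of
#'   indicator columns of that factor. An indicator may appear under several
#'   factors (bifactor structure).
#' @param regressions named list; element \code{outcome = c(predictors)} adds
#'   directed paths from each predictor (latent or observed-exogenous name)
#'   to the outcome latent. Must be acyclic.
#' @param observed_exogenous observed covariate columns entering the
#'   structural model directly (internally single-indicator factors with
#'   loading 1 and zero residual).
#' @param orthogonal list of character vectors; factors within a group have
#'   their covariances (or disturbance covariances) fixed to zero. Used for
#'   the orthogonal bifactor constraint.
#' @param fixed_covariances optional list of \code{list(pair = c(a, b),
#'   value = v)} overriding the default free exogenous covariance.
#' @param std_lv identification rule: \code{TRUE} fixes factor variances to 1
#'   with all loadings free (the default, matching freed-loading reporting);
#'   \code{FALSE} fixes each factor's first loading to 1 and frees its
#'   variance.
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(latents, regressions = list(),
                       observed_exogenous = character(),
                       orthogonal = list(), fixed_covariances = list(),
                       std_lv = TRUE) {
  stopifnot(is.list(latents), length(latents) >= 1L,
            !is.null(names(latents)), all(nzchar(names(latents))))
  if (any(lengths(latents) == 0L)) stop("every factor needs >= 1 indicator",
                                        call. = FALSE)
  factor_names <- c(names(latents), observed_exogenous)
  if (anyDuplicated(factor_names)) {
    stop("factor / observed-exogenous names must be unique", call. = FALSE)
  }
  for (out in names(regressions)) {
    if (!(out %in% names(latents))) {
      stop("regression outcome must be a latent factor: ", out, call. = FALSE)
    }
    bad <- setdiff(regressions[[out]], factor_names)
    if (length(bad)) {
      stop("unknown predictor(s) in regression for ", out, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  # acyclicity via topological sort over the regression graph
  topo_order_factors(factor_names, regressions)

  indicators <- unique(c(unlist(latents, use.names = FALSE), observed_exogenous))
  structure(list(latents = latents, regressions = regressions,
                 observed_exogenous = observed_exogenous,
                 orthogonal = orthogonal,
                 fixed_covariances = fixed_covariances,
                 std_lv = std_lv, factor_names = factor_names,
                 indicators = indicators),
            class = "model_spec")
}

topo_order_factors <- function(factor_names, regressions) {
  deps <- stats::setNames(vector("list", length(factor_names)), factor_names)
  for (out in names(regressions)) deps[[out]] <- regressions[[out]]
  ordered <- character(0)
  remaining <- factor_names
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(f)
      all(deps[[f]] %in% ordered), TRUE)]
    if (!length(ready)) {
      stop("regression graph is cyclic (involving: ",
           paste(remaining, collapse = ", "), ")", call. = FALSE)
    }
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

#' @export
print.model_spec <- function(x, ...) {
  cat("SEM model specification\n")
  for (f in names(x$latents)) {
    cat(sprintf("  %s =~ %s\n", f, paste(x$latents[[f]], collapse = " + ")))
  }
  for (out in names(x$regressions)) {
    cat(sprintf("  %s ~ %s\n", out, paste(x$regressions[[out]], collapse = " + ")))
  }
  if (length(x$observed_exogenous)) {
    cat("  observed exogenous:", paste(x$observed_exogenous, collapse = ", "), "\n")
  }
  for (gp in x$orthogonal) {
    cat("  orthogonal:", paste(gp, collapse = " | "), "\n")
  }
  cat("  identification:",
      if (x$std_lv) "unit factor variances" else "first loading fixed", "\n")
  invisible(x)
}

#' Serialize a model spec to a structured text file (YAML-like JSON)
#' @param spec a \code{model_spec}; @param path output path.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a model spec written by \code{write_model_spec}
#' @param path file path.
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(latents = as.list(x$latents),
             regressions = as.list(x$regressions),
             observed_exogenous = unlist(x$observed_exogenous) %||% character(),
             orthogonal = x$orthogonal %||% list(),
             std_lv = x$std_lv %||% TRUE)
}

# ---- parameter table -------------------------------------------------------

#' Parameter table of a model specification
#'
#' One row per model parameter (loadings, structural paths, factor
#' variances/disturbances, exogenous covariances) with explicit free/fixed
#' status, current values, and human-readable labels ("y1 =~ F", "g ~ SVD",
#' "A ~~ B"). The table round-trips losslessly with the flat vector of free
#' values used by the optimizer. Disturbance variances under the default
#' unit-variance identification are computed (value NA, fixed).
#'
#' @param spec a \code{model_spec}.
#' @return a \code{parameter_vector} data.frame.
#' @export
parameter_template <- function(spec) {
  rows <- list()
  add <- function(type, lhs, rhs, free, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, lhs = lhs, rhs = rhs, free = free, value = value,
      stringsAsFactors = FALSE)
  }
  for (f in names(spec$latents)) {
    ind <- spec$latents[[f]]
    for (k in seq_along(ind)) {
      if (!spec$std_lv && k == 1L) add("loading", ind[k], f, FALSE, 1)
      else add("loading", ind[k], f, TRUE, 0.4)
    }
  }
  for (ov in spec$observed_exogenous) add("loading", ov, ov, FALSE, 1)

  endo <- names(spec$regressions)
  for (out in endo) {
    for (pr in spec$regressions[[out]]) add("path", out, pr, TRUE, 0)
  }
  exo <- setdiff(spec$factor_names, endo)
  # factor variances
  for (f in spec$factor_names) {
    if (f %in% spec$observed_exogenous) add("variance", f, f, FALSE, 1)
    else if (f %in% endo) {
      # disturbance variance: computed under unit-variance identification
      if (spec$std_lv) add("variance", f, f, FALSE, NA_real_)
      else add("variance", f, f, TRUE, 0.5)
    } else {
      if (spec$std_lv) add("variance", f, f, FALSE, 1)
      else add("variance", f, f, TRUE, 1)
    }
  }
  # exogenous covariances: free unless an orthogonality group or fixed pair
  fixed_pairs <- lapply(spec$fixed_covariances, `[[`, "pair")
  fixed_vals <- vapply(spec$fixed_covariances, `[[`, numeric(1), "value")
  if (length(exo) > 1L) {
    for (a_i in seq_len(length(exo) - 1L)) for (b_i in (a_i + 1L):length(exo)) {
      a <- exo[a_i]; b <- exo[b_i]
      orth <- any(vapply(spec$orthogonal, function(gp) all(c(a, b) %in% gp), TRUE))
      fixed_at <- NA_real_
      for (kk in seq_along(fixed_pairs)) {
        if (setequal(fixed_pairs[[kk]], c(a, b))) fixed_at <- fixed_vals[kk]
      }
      if (orth) add("covariance", a, b, FALSE, 0)
      else if (!is.na(fixed_at)) add("covariance", a, b, FALSE, fixed_at)
      else add("covariance", a, b, TRUE, 0)
    }
  }
  out <- do.call(rbind, rows)
  out$label <- paste(out$lhs,
                     c(loading = "=~", path = "~", variance = "~~",
                       covariance = "~~")[out$type],
                     out$rhs)
  class(out) <- c("parameter_vector", "data.frame")
  out
}

free_values <- function(params) params$value[params$free]

set_free_values <- function(params, theta) {
  stopifnot(length(theta) == sum(params$free))
  params$value[params$free] <- theta
  params
}

#' Set named parameter values in a parameter table
#'
#' @param params a \code{parameter_vector} (from \code{parameter_template}).
#' @param ... named values (or named numeric vectors/lists, concatenated);
#'   names are parameter labels like \code{"g ~ SVD"} or
#'   \code{"wmh_tiv =~ SVD"}.
#' @return updated table.
#' @export
set_parameters <- function(params, ...) {
  vals <- unlist(list(...))
  for (nm in names(vals)) {
    i <- match(nm, params$label)
    if (is.na(i)) stop("no such parameter: ", nm, call. = FALSE)
    params$value[i] <- vals[[nm]]
  }
  params
}
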