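# Pairwise mixed correlation structure: Pearson for continuous pairs,
# polyserial for continuous-categorical, polychoric for categorical pairs,
# all on pairwise-complete observations. The per-estimate asymptotic
# variances serve as the diagonal DWLS weights; the full asymptotic
# covariance Gamma of the stacked estimates is assembled from per-observation
# influence functions.

#' Build a variable schema
#'
#' @param name,type,role character vectors of equal length; types are
#'   \code{continuous}, \code{binary}, or \code{ordinal(k)}.
#' @return schema data.frame.
#' @export
variable_schema <- function(name, type, role = "indicator") {
  stopifnot(!anyDuplicated(name))
  data.frame(name = name, type = type,
             role = rep_len(role, length(name)), stringsAsFactors = FALSE)
}

schema_type <- function(schema, var) {
  i <- match(var, schema$name)
  if (anyNA(i)) {
    stop("variable(s) missing from schema: ",
         paste(var[is.na(i)], collapse = ", "), call. = FALSE)
  }
  schema$type[i]
}

#' Mixed correlation matrix of a cohort
#'
#' Dispatches per pair on measurement type (pearson / polyserial /
#' polychoric), uses pairwise-complete observations, and records per-pair
#' sample sizes, asymptotic variances and (optionally) the full asymptotic
#' covariance of the stacked estimates from influence functions.
#'
#' @param table a \code{cohort_table} or data.frame.
#' @param schema variable schema (defaults to the table's own).
#' @param variables character vector of variables to include, in order.
#' @param min_pair_n floor on pairwise-complete counts (default 10).
#' @param gamma compute the full asymptotic covariance matrix (default TRUE).
#' @return object of class \code{mixed_cor} with fields \code{variables},
#'   \code{R} (estimates), \code{pair_type}, \code{thresholds},
#'   \code{pair_n}, \code{acov} (per-estimate variance), \code{Gamma}
#'   (covariance of the stacked lower-triangle estimates), \code{n_rows},
#'   \code{boundary}.
#' @export
mixed_matrix <- function(table, schema = NULL, variables = NULL,
                         min_pair_n = 10L, gamma = TRUE) {
  schema <- schema %||% schema_of(table)
  variables <- variables %||% schema$name[schema$role == "indicator"]
  df <- as.data.frame(table)
  missing_vars <- setdiff(variables, names(df))
  if (length(missing_vars)) {
    stop("variable(s) not in table: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  types <- schema_type(schema, variables)
  p <- length(variables)
  n <- nrow(df)

  # Per-variable thresholds from full observed margins (two-stage, stage one).
  thresholds <- stats::setNames(vector("list", p), variables)
  levels_of <- stats::setNames(vector("list", p), variables)
  for (i in seq_len(p)) {
    if (is_categorical_type(types[i])) {
      v <- df[[variables[i]]]
      levels_of[[i]] <- sort(unique(v[!is.na(v)]))
      thresholds[[i]] <- tryCatch(estimate_thresholds(v), error = function(e) {
        stop("column ", variables[i], ": ", conditionMessage(e), call. = FALSE)
      })
    }
  }

  R <- diag(1, p); dimnames(R) <- list(variables, variables)
  pair_type <- matrix(NA_character_, p, p, dimnames = dimnames(R))
  pair_n <- matrix(n, p, p, dimnames = dimnames(R))
  acov <- matrix(NA_real_, p, p, dimnames = dimnames(R))
  boundary <- matrix(FALSE, p, p, dimnames = dimnames(R))

  npairs <- p * (p - 1L) / 2L
  infl <- if (gamma && npairs > 0L) matrix(0, n, npairs) else NULL
  pair_index <- matrix(0L, p, p)
  pair_labels <- character(npairs)

  q <- 0L
  for (j in seq_len(p)) for (i in seq_len(p)) {
    if (i >= j) next
    q <- q + 1L
    pair_index[i, j] <- pair_index[j, i] <- q
    pair_labels[q] <- paste0(variables[i], "~", variables[j])
    xi <- df[[variables[i]]]; xj <- df[[variables[j]]]
    cat_i <- is_categorical_type(types[i]); cat_j <- is_categorical_type(types[j])
    est <- if (!cat_i && !cat_j) {
      c(list(kind = "pearson"), pearson_corr(xi, xj, min_n = min_pair_n))
    } else if (cat_i && cat_j) {
      c(list(kind = "polychoric"),
        polychoric_corr(xi, xj, levels_x = levels_of[[i]], levels_y = levels_of[[j]],
                        thresholds_x = thresholds[[variables[i]]],
                        thresholds_y = thresholds[[variables[j]]],
                        min_n = min_pair_n))
    } else if (!cat_i && cat_j) {
      c(list(kind = "polyserial"),
        polyserial_corr(xi, xj, levels_y = levels_of[[j]],
                        thresholds_y = thresholds[[variables[j]]],
                        min_n = min_pair_n))
    } else {
      c(list(kind = "polyserial"),
        polyserial_corr(xj, xi, levels_y = levels_of[[i]],
                        thresholds_y = thresholds[[variables[i]]],
                        min_n = min_pair_n))
    }
    R[i, j] <- R[j, i] <- est$rho
    pair_type[i, j] <- pair_type[j, i] <- est$kind
    pair_n[i, j] <- pair_n[j, i] <- est$n
    acov[i, j] <- acov[j, i] <- est$var
    boundary[i, j] <- boundary[j, i] <- est$boundary
    if (!is.null(infl)) {
      ok <- !is.na(xi) & !is.na(xj)
      # scale so that r_hat - rho ~ mean over ALL n rows of the stored column
      infl[ok, q] <- est$influence * (n / est$n)
    }
  }

  Gamma <- NULL
  if (!is.null(infl)) {
    Gamma <- crossprod(scale(infl, center = TRUE, scale = FALSE)) /
      (as.numeric(n) * (n - 1))
    dimnames(Gamma) <- list(pair_labels, pair_labels)
  }

  structure(list(variables = variables, types = types, R = R,
                 pair_type = pair_type, thresholds = thresholds,
                 pair_n = pair_n, acov = acov, Gamma = Gamma,
                 pair_index = pair_index, pair_labels = pair_labels,
                 boundary = boundary, n_rows = n),
            class = "mixed_cor")
}

#' @export
print.mixed_cor <- function(x, ...) {
  cat(sprintf("Mixed correlation matrix: %d variables, n = %d rows\n",
              length(x$variables), x$n_rows))
  counts <- table(x$pair_type[upper.tri(x$pair_type)])
  cat("  pair types:", paste(names(counts), counts, sep = "=", collapse = ", "),
      "\n")
  print(round(x$R, 3))
  invisible(x)
}

# Subset a mixed_cor object to a variable subset (order preserved as given).
subset_mixed_cor <- function(m, variables) {
  idx <- match(variables, m$variables)
  if (anyNA(idx)) {
    stop("variables absent from correlation object: ",
         paste(variables[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  p <- length(idx)
  keep_pairs <- integer(0)
  new_index <- matrix(0L, p, p)
  labels <- character(0)
  q <- 0L
  for (j in seq_len(p)) for (i in seq_len(p)) {
    if (i >= j) next
    q <- q + 1L
    keep_pairs[q] <- m$pair_index[idx[i], idx[j]]
    new_index[i, j] <- new_index[j, i] <- q
    labels[q] <- paste0(variables[i], "~", variables[j])
  }
  structure(list(variables = variables, types = m$types[idx],
                 R = m$R[idx, idx, drop = FALSE],
                 pair_type = m$pair_type[idx, idx, drop = FALSE],
                 thresholds = m$thresholds[variables],
                 pair_n = m$pair_n[idx, idx, drop = FALSE],
                 acov = m$acov[idx, idx, drop = FALSE],
                 Gamma = if (!is.null(m$Gamma))
                   m$Gamma[keep_pairs, keep_pairs, drop = FALSE],
                 pair_index = new_index, pair_labels = labels,
                 boundary = m$boundary[idx, idx, drop = FALSE],
                 n_rows = m$n_rows),
            class = "mixed_cor")
}

#' Serialize a mixed correlation matrix
#'
#' Writes the estimates as a labeled CSV and a JSON sidecar holding pair
#' types, pairwise sample sizes, thresholds and asymptotic weights.
#'
#' @param m a \code{mixed_cor} object.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_mixed_cor <- function(m, prefix) {
  csv <- paste0(prefix, ".csv")
  sidecar <- paste0(prefix, ".meta.json")
  utils::write.csv(data.frame(variable = m$variables, m$R, check.names = FALSE),
                   csv, row.names = FALSE)
  jsonlite::write_json(
    list(variables = m$variables, types = m$types,
         pair_type = m$pair_type, pair_n = m$pair_n,
         thresholds = m$thresholds[!vapply(m$thresholds, is.null, TRUE)],
         asymptotic_variances = m$acov, n_rows = m$n_rows),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
    matrix = "rowmajor")
  invisible(c(csv, sidecar))
}
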