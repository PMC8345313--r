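# Auxiliary inference: Williams' test for two dependent overlapping
# correlations, Benjamini-Hochberg FDR control, and pre-model
# residualization of cognitive scores for the scan-test interval.

#' Williams test for two dependent overlapping correlations
#'
#' Williams' (1959) modification of Hotelling's test comparing r12 and r13,
#' which share variable 1, given r23, with t on n - 3 degrees of freedom:
#' \deqn{t = (r_{12} - r_{13}) \sqrt{\frac{(n - 1)(1 + r_{23})}
#'   {2 \frac{n - 1}{n - 3} |R| + \bar r^2 (1 - r_{23})^3}}}
#' where \eqn{|R|} is the determinant of the 3x3 correlation matrix and
#' \eqn{\bar r = (r_{12} + r_{13}) / 2}. The one-sided p-value is taken in
#' the direction of the observed difference; both sides are returned.
#'
#' @param r12,r13 the two correlations being compared (share variable 1).
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size (>= 4).
#' @return object of class \code{williams_result}: \code{t_value}, \code{df},
#'   \code{p_one_sided}, \code{p_two_sided}, and the echoed inputs.
#' @export
williams_test <- function(r12, r13, r23, n) {
  stopifnot(n >= 4, abs(r12) < 1, abs(r13) < 1, abs(r23) < 1)
  R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
  detR <- det(R)
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    stop("the correlation triple does not form a positive definite matrix",
         call. = FALSE)
  }
  rbar <- (r12 + r13) / 2
  t_val <- (r12 - r13) *
    sqrt(((n - 1) * (1 + r23)) /
           (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3))
  df <- n - 3
  p_two <- 2 * stats::pt(-abs(t_val), df)
  structure(list(t_value = t_val, df = df,
                 p_one_sided = stats::pt(-abs(t_val), df),
                 p_two_sided = p_two,
                 r12 = r12, r13 = r13, r23 = r23, n = n),
            class = "williams_result")
}

#' @export
print.williams_result <- function(x, ...) {
  cat(sprintf("Williams test: t(%d) = %.3f, one-sided p = %.4g (r12 = %.3f, r13 = %.3f, r23 = %.3f)\n",
              x$df, x$t_value, x$p_one_sided, x$r12, x$r13, x$r23))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via \code{stats::p.adjust(method = "BH")},
#' returned in input order with the family recorded.
#'
#' @param pvals numeric p-values in [0, 1].
#' @param family_label which analysis family the correction spans.
#' @return object of class \code{adjusted_pvalues}: \code{raw},
#'   \code{adjusted}, \code{family_label}.
#' @export
bh_adjust <- function(pvals, family_label = "unspecified") {
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  structure(list(raw = pvals,
                 adjusted = stats::p.adjust(pvals, method = "BH"),
                 family_label = family_label),
            class = "adjusted_pvalues")
}

#' Residualize cognitive columns for the scan-test interval
#'
#' Each cognitive column is replaced by the residuals of its simple linear
#' regression on the interval (days between imaging and cognitive testing),
#' computed on complete pairs; missing values stay missing. If the interval
#' is constant the regression is undefined and columns are mean-centered
#' with a note.
#'
#' @param table a \code{cohort_table} or data.frame.
#' @param cognitive_columns columns to residualize (default: the ten test
#'   scores present in the table).
#' @param interval_column name of the interval column (days).
#' @return the table with residualized cognitive columns.
#' @export
residualize_for_interval <- function(table,
                                     cognitive_columns =
                                       intersect(COGNITIVE_TESTS, names(table)),
                                     interval_column = "interval_days") {
  df <- as.data.frame(table)
  if (!(interval_column %in% names(df))) {
    stop("interval column not found: ", interval_column, call. = FALSE)
  }
  iv <- df[[interval_column]]
  constant <- stats::sd(iv, na.rm = TRUE) == 0
  if (constant) {
    message("interval column is constant; cognitive columns mean-centered only")
  }
  for (cc in cognitive_columns) {
    y <- df[[cc]]
    ok <- !is.na(y) & !is.na(iv)
    if (sum(ok) < 3L) {
      stop("fewer than 3 complete pairs for column ", cc, call. = FALSE)
    }
    if (constant) {
      df[[cc]][ok] <- y[ok] - mean(y[ok])
    } else {
      fit <- stats::lm.fit(cbind(1, iv[ok]), y[ok])
      df[[cc]][ok] <- fit$residuals
    }
  }
  if (inherits(table, "cohort_table")) {
    new_cohort_table(df, attr(table, "schema"), attr(table, "provenance"))
  } else {
    df
  }
}
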