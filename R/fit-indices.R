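# Absolute fit indices (RMSEA, CFI, TLI, SRMR) with the conventional
# acceptability thresholds, computed from the mean-and-variance adjusted
# chi-square as is standard for WLSMV reporting.

#' Independence (baseline) model
#'
#' Fits the model with all correlations fixed to zero and thresholds free
#' (thresholds are saturated in the two-stage approach, so the baseline has
#' no free parameters and its statistic is the weighted sum of squared
#' observed correlations, adjusted the same way as the target model).
#'
#' @param moments a \code{mixed_cor} object.
#' @param variables optional variable subset.
#' @return a lightweight \code{sem_fit}-like object with the chi-square
#'   fields needed by \code{\link{fit_indices}}.
#' @export
baseline_model <- function(moments, variables = NULL) {
  mom <- if (is.null(variables)) moments else subset_mixed_cor(moments, variables)
  r <- lower_vec(mom$R)
  v <- lower_vec(mom$acov)
  if (length(r) == 0L) {
    return(structure(list(chisq_unadjusted = 0, chisq_adjusted = 0,
                          df = 0L, df_adjusted = 0, residuals = numeric(0),
                          n_effective = mom$n_rows, saturated = TRUE),
                     class = "sem_fit"))
  }
  if (any(!is.finite(v) | v <= 0)) {
    v[!is.finite(v) | v <= 0] <- max(v[is.finite(v) & v > 0], 1e-6)
  }
  w <- 1 / v
  T_unadj <- sum(w * r^2)
  Gamma <- mom$Gamma %||% diag(v, length(v))
  M <- diag(w, length(v)) %*% Gamma
  tr1 <- sum(diag(M))
  tr2 <- sum(M * t(M))
  structure(list(chisq_unadjusted = T_unadj,
                 chisq_adjusted = if (tr2 > 0) T_unadj * tr1 / tr2 else 0,
                 df = length(r),
                 df_adjusted = if (tr2 > 0) tr1^2 / tr2 else 0,
                 residuals = r, n_effective = mom$n_rows,
                 convergence = list(converged = TRUE, iterations = 0L,
                                    gradient_norm = 0)),
            class = "sem_fit")
}

#' Absolute fit indices
#'
#' RMSEA \eqn{= \sqrt{\max(0, (\chi^2 - df) / (df (n - 1)))}} (denominator
#' configurable to \eqn{n}); CFI \eqn{= 1 - \max(\chi^2 - df, 0) /
#' \max(\chi^2_b - df_b, \chi^2 - df, 0)}; TLI \eqn{= ((\chi^2_b / df_b) -
#' (\chi^2 / df)) / ((\chi^2_b / df_b) - 1)}, deliberately not clamped (values
#' slightly above 1 indicate better-than-exact fit and are reported as such);
#' SRMR = root mean square residual correlation. Verdicts use the
#' conventional thresholds: RMSEA < 0.06, CFI > 0.95, TLI > 0.95,
#' SRMR < 0.08. Chi-squares are the mean-and-variance adjusted statistics.
#'
#' @param model fitted \code{sem_fit}.
#' @param baseline independence-model fit from \code{\link{baseline_model}}.
#' @param n sample size (default: the model's effective n).
#' @param rmsea_denominator \code{"n-1"} (default) or \code{"n"}.
#' @return object of class \code{fit_indices} with fields \code{rmsea},
#'   \code{cfi}, \code{tli}, \code{srmr}, \code{verdicts}, \code{baseline},
#'   \code{saturated}.
#' @export
fit_indices <- function(model, baseline, n = model$n_effective,
                        rmsea_denominator = c("n-1", "n")) {
  rmsea_denominator <- match.arg(rmsea_denominator)
  stopifnot(n > 1)
  chisq <- model$chisq_adjusted
  df <- model$df_adjusted
  chisq_b <- baseline$chisq_adjusted
  df_b <- baseline$df_adjusted
  denom_n <- if (rmsea_denominator == "n-1") n - 1 else n
  saturated <- model$df == 0
  if (saturated) {
    rmsea <- 0; cfi <- 1; tli <- 1
  } else {
    rmsea <- sqrt(max(0, (chisq - df) / (df * denom_n)))
    cfi <- 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0)
    tli <- ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1)
  }
  srmr <- if (length(model$residuals)) sqrt(mean(model$residuals^2)) else 0
  verdicts <- c(rmsea = rmsea < 0.06, cfi = cfi > 0.95, tli = tli > 0.95,
                srmr = srmr < 0.08)
  structure(list(rmsea = rmsea, cfi = max(min(cfi, 1), 0), tli = tli,
                 srmr = srmr, verdicts = verdicts, saturated = saturated,
                 baseline = list(chisq = chisq_b, df = df_b)),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("RMSEA = %.3f [%s]  CFI = %.3f [%s]  TLI = %.3f [%s]  SRMR = %.3f [%s]%s\n",
              x$rmsea, ifelse(x$verdicts["rmsea"], "ok", "poor"),
              x$cfi, ifelse(x$verdicts["cfi"], "ok", "poor"),
              x$tli, ifelse(x$verdicts["tli"], "ok", "poor"),
              x$srmr, ifelse(x$verdicts["srmr"], "ok", "poor"),
              if (x$saturated) "  (saturated model)" else ""))
  invisible(x)
}
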