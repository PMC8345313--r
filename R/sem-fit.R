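# Implied moments and the DWLS (WLSMV-style) fitting engine.
#
# The model is fitted in the correlation metric: observed variables (and the
# latent response continua behind categorical indicators, delta
# parameterization) have unit variance, so indicator residual variances are
# implied, theta_ii = 1 - communality, rather than free. Under the default
# unit-factor-variance identification every free parameter is already a
# standardized quantity.

# Precompute index maps from a spec + parameter template so that the implied
# matrix can be evaluated thousands of times (optimizer, numeric Jacobians)
# without repeated table scans. Returns function(values) -> list(sigma, Phi,
# psi, theta).
make_implied_evaluator <- function(spec, params) {
  fac <- spec$factor_names
  m <- length(fac)
  p <- length(spec$indicators)
  endo <- names(spec$regressions)
  order <- topo_order_factors(fac, spec$regressions)
  order_i <- match(order, fac)

  load_rows <- which(params$type == "loading")
  load_pos <- cbind(match(params$lhs[load_rows], spec$indicators),
                    match(params$rhs[load_rows], spec$factor_names))

  var_row <- vapply(fac, function(f)
    which(params$type == "variance" & params$lhs == f)[1], integer(1))
  cov_row <- matrix(0L, m, m)
  for (i in which(params$type == "covariance")) {
    a <- match(params$lhs[i], fac); b <- match(params$rhs[i], fac)
    cov_row[a, b] <- cov_row[b, a] <- i
  }
  path_info <- lapply(fac, function(f) {
    if (!(f %in% endo)) return(NULL)
    pred <- spec$regressions[[f]]
    rows <- vapply(pred, function(pr)
      which(params$type == "path" & params$lhs == f & params$rhs == pr)[1],
      integer(1))
    list(pred_i = match(pred, fac), rows = rows)
  })
  is_endo <- fac %in% endo

  function(values) {
    Phi <- matrix(0, m, m)
    psi <- numeric(m)
    for (oi in seq_along(order_i)) {
      fi <- order_i[oi]
      earlier <- order_i[seq_len(oi - 1L)]
      if (!is_endo[fi]) {
        Phi[fi, fi] <- values[var_row[fi]]
        for (gi in earlier) {
          cr <- cov_row[fi, gi]
          if (cr > 0L) Phi[fi, gi] <- Phi[gi, fi] <- values[cr]
        }
        psi[fi] <- Phi[fi, fi]
      } else {
        pi_ <- path_info[[fi]]
        b <- values[pi_$rows]
        for (gi in earlier) {
          Phi[fi, gi] <- Phi[gi, fi] <- sum(b * Phi[pi_$pred_i, gi])
        }
        explained <- sum(b * (Phi[pi_$pred_i, pi_$pred_i, drop = FALSE] %*% b))
        d <- values[var_row[fi]]
        if (is.na(d)) d <- 1 - explained   # computed disturbance (std_lv)
        psi[fi] <- d
        Phi[fi, fi] <- explained + d
      }
    }
    L <- matrix(0, p, m)
    L[load_pos] <- values[load_rows]
    common <- L %*% Phi %*% t(L)
    theta <- 1 - diag(common)
    sigma <- common
    diag(sigma) <- 1
    dimnames(sigma) <- list(spec$indicators, spec$indicators)
    dimnames(Phi) <- list(fac, fac)
    list(sigma = sigma, Phi = Phi, psi = stats::setNames(psi, fac),
         theta = stats::setNames(theta, spec$indicators))
  }
}

#' Model-implied correlation matrix
#'
#' Standard linear-structural algebra: the latent covariance implied by
#' regressions and free covariances, mapped through the loadings, with
#' indicator residual variances implied by the unit-diagonal (correlation
#' metric / delta parameterization for categorical indicators).
#'
#' @param spec a \code{model_spec}.
#' @param params a \code{parameter_vector} conforming to \code{spec}.
#' @return list with \code{sigma} (implied correlation matrix), \code{Phi}
#'   (latent covariance), \code{theta} (implied residual variances),
#'   \code{heywood} (indicators with negative residual variance),
#'   \code{heywood_latent}.
#' @export
implied_moments <- function(spec, params) {
  ev <- make_implied_evaluator(spec, params)
  out <- ev(params$value)
  out$heywood <- spec$indicators[out$theta < -1e-10]
  out$heywood_latent <- names(out$psi)[out$psi < -1e-10]
  out
}

# unique-pair vector of a symmetric matrix (i < j in column-major order),
# matching mixed_cor pair ordering.
lower_vec <- function(S) S[upper.tri(S)]

#' Fit a model by diagonally weighted least squares
#'
#' Minimizes \eqn{F(\theta) = \sum_{i<j} (r_{ij} - \sigma_{ij}(\theta))^2 /
#' v_{ij}} with \eqn{v_{ij}} the estimated asymptotic variance of each
#' correlation. Standard errors are sandwich-type using the influence-function
#' estimate of the full asymptotic covariance of the correlations; the test
#' statistic is reported unadjusted and with the Satterthwaite
#' mean-and-variance adjustment (adjusted statistic and fractional adjusted
#' degrees of freedom whose expectation matches under correct specification).
#'
#' @param spec a \code{model_spec} whose indicators are all present in
#'   \code{moments}.
#' @param moments a \code{mixed_cor} object.
#' @param start optional named start values (label = value).
#' @param max_restarts jittered restarts on non-convergence (default 5).
#' @param maxit BFGS iteration cap per start (default 500).
#' @return object of class \code{sem_fit}.
#' @export
fit_dwls <- function(spec, moments, start = NULL, max_restarts = 5L,
                     maxit = 500L) {
  mom <- subset_mixed_cor(moments, spec$indicators)
  params <- parameter_template(spec)
  r <- lower_vec(mom$R)
  v <- lower_vec(mom$acov)
  if (any(!is.finite(v) | v <= 0)) {
    v[!is.finite(v) | v <= 0] <- max(v[is.finite(v) & v > 0], 1e-6)
  }
  w <- 1 / v
  nfree <- sum(params$free)
  npairs <- length(r)
  if (nfree > npairs) {
    stop(sprintf("model not identified: %d free parameters > %d moments",
                 nfree, npairs), call. = FALSE)
  }

  # data-informed starts: observed correlation for covariances between
  # observed-exogenous singletons
  for (i in which(params$type == "covariance" & params$free)) {
    a <- params$lhs[i]; b <- params$rhs[i]
    if (a %in% spec$observed_exogenous && b %in% spec$observed_exogenous) {
      params$value[i] <- mom$R[a, b]
    }
  }
  if (!is.null(start)) params <- do.call(set_parameters, c(list(params), start))

  ev <- make_implied_evaluator(spec, params)
  values_base <- params$value
  free_idx <- which(params$free)
  ut <- upper.tri(diag(length(spec$indicators)))
  sigma_of <- function(theta) {
    vals <- values_base
    vals[free_idx] <- theta
    ev(vals)$sigma[ut]
  }
  objective <- function(theta) sum(w * (r - sigma_of(theta))^2)

  theta0 <- free_values(params)
  best <- NULL
  grad_norm <- Inf
  iter_total <- 0L
  num_grad <- function(f, x, h = 1e-6) {
    vapply(seq_along(x), function(i) {
      e <- numeric(length(x)); e[i] <- h
      (f(x + e) - f(x - e)) / (2 * h)
    }, numeric(1))
  }
  # gradient tolerance relative to the weight scale: the discrepancy carries
  # weights of order n, so the raw gradient norm scales with mean(w)
  grad_tol <- 1e-6 * max(1, mean(w))
  for (attempt in seq_len(max_restarts + 1L)) {
    init <- if (attempt == 1L) theta0 else
      with_rng_seed(7000L + attempt,   # deterministic restart jitter
                    theta0 + stats::rnorm(length(theta0), 0, 0.1 * attempt))
    opt <- stats::optim(init, objective, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-14))
    iter_total <- iter_total + opt$counts[["function"]]
    g <- num_grad(objective, opt$par)
    gn <- sqrt(sum(g^2))
    if (is.null(best) || opt$value < best$value) {
      best <- opt; grad_norm <- gn
    }
    if (gn < grad_tol) { best <- opt; grad_norm <- gn; break }
  }
  converged <- grad_norm < max(grad_tol, 1e-3)
  if (!converged) {
    warning(sprintf(
      "fit_dwls did not reach gradient tolerance (|g| = %.3g) after %d starts",
      grad_norm, max_restarts + 1L), call. = FALSE)
  }

  params <- set_free_values(params, best$par)
  imp <- implied_moments(spec, params)
  sigma_vec <- lower_vec(imp$sigma)
  resid <- r - sigma_vec

  # numeric Jacobian of the implied moments in the free parameters
  Delta <- matrix(0, npairs, nfree)
  h <- 1e-6
  for (k in seq_len(nfree)) {
    tp <- best$par; tm <- best$par
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    Delta[, k] <- (sigma_of(tp) - sigma_of(tm)) / (2 * h)
  }
  Gamma <- mom$Gamma %||% diag(v, npairs)
  WD <- Delta * w
  A <- crossprod(Delta, WD)
  Ainv <- tryCatch(solve(A), error = function(e) MASS_ginv(A))
  vc <- Ainv %*% crossprod(WD, Gamma %*% WD) %*% Ainv
  se <- sqrt(pmax(diag(vc), 0))

  # test statistic: unadjusted F-hat, then Satterthwaite mean-variance
  # adjustment via the residual-weighting operator U
  T_unadj <- best$value
  U <- diag(w, npairs) - WD %*% Ainv %*% t(WD)
  M <- U %*% Gamma
  tr1 <- sum(diag(M))
  tr2 <- sum(M * t(M))
  df <- npairs - nfree
  if (df > 0 && tr2 > 0) {
    df_adj <- tr1^2 / tr2
    T_adj <- T_unadj * tr1 / tr2
  } else {
    df_adj <- 0
    T_adj <- 0
  }

  params$se <- NA_real_
  params$se[params$free] <- se

  structure(list(spec = spec, params = params, estimates = params,
                 free_labels = params$label[params$free],
                 theta = best$par, se = se, vcov = vc,
                 discrepancy = T_unadj,
                 chisq_unadjusted = T_unadj, chisq_adjusted = T_adj,
                 df = df, df_adjusted = df_adj,
                 p_value = if (df > 0) stats::pchisq(T_adj, df_adj,
                                                     lower.tail = FALSE) else NA_real_,
                 n_effective = mom$n_rows,
                 implied = imp$sigma, Phi = imp$Phi, theta_res = imp$theta,
                 residuals = resid, moments = mom,
                 heywood = imp$heywood, heywood_latent = imp$heywood_latent,
                 convergence = list(converged = converged,
                                    iterations = iter_total,
                                    gradient_norm = grad_norm)),
            class = "sem_fit")
}

# minimal Moore-Penrose fallback for near-singular information
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("DWLS structural equation model fit\n")
  cat(sprintf("  n = %d, free parameters = %d, df = %d (adjusted %.2f)\n",
              x$n_effective, length(x$theta), x$df, x$df_adjusted))
  cat(sprintf("  discrepancy = %.4f, adjusted chi-square = %.3f (p = %s)\n",
              x$discrepancy, x$chisq_adjusted,
              format.pval(x$p_value, digits = 3)))
  cat(sprintf("  converged: %s (|grad| = %.2g, %d evaluations)\n",
              x$convergence$converged, x$convergence$gradient_norm,
              x$convergence$iterations))
  if (length(x$heywood)) {
    cat("  Heywood-flagged indicators:", paste(x$heywood, collapse = ", "), "\n")
  }
  est <- x$params[x$params$free, c("label", "value", "se")]
  est$value <- round(est$value, 4); est$se <- round(est$se, 4)
  print(est, row.names = FALSE)
  invisible(x)
}

#' Write fit results to structured text
#'
#' Flat CSV parameter table plus a JSON summary (test statistic, convergence).
#' @param fit a \code{sem_fit}; @param prefix output path prefix.
#' @export
write_fit_result <- function(fit, prefix) {
  utils::write.csv(as.data.frame(fit$params), paste0(prefix, "_parameters.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(discrepancy = fit$discrepancy, chisq_unadjusted = fit$chisq_unadjusted,
         chisq_adjusted = fit$chisq_adjusted, df = fit$df,
         df_adjusted = fit$df_adjusted, p_value = fit$p_value,
         n_effective = fit$n_effective, convergence = fit$convergence,
         heywood = fit$heywood),
    paste0(prefix, "_fit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}
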