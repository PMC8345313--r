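# Standardized solutions and regression-method factor scores.

# standardized parameter vector (one entry per loading/path/covariance row
# plus variance rows as standardized residuals) as a function of all values
std_vector <- function(spec, params, evaluator, values) {
  out <- evaluator(values)
  sdl <- sqrt(pmax(diag(out$Phi), 1e-12))
  names(sdl) <- spec$factor_names
  z <- numeric(nrow(params))
  for (i in seq_len(nrow(params))) {
    ty <- params$type[i]
    if (ty == "loading") {
      z[i] <- values[i] * sdl[params$rhs[i]]
    } else if (ty == "path") {
      z[i] <- values[i] * sdl[params$rhs[i]] / sdl[params$lhs[i]]
    } else if (ty == "covariance") {
      z[i] <- values[i] / (sdl[params$lhs[i]] * sdl[params$rhs[i]])
    } else {
      f <- params$lhs[i]
      z[i] <- out$psi[f] / max(out$Phi[f, f], 1e-12)
    }
  }
  z
}

#' Standardized solution of a fitted model
#'
#' Rescales estimates so all latents (and indicators, already on the
#' correlation metric) have unit variance; standard errors propagate by the
#' delta method, confidence intervals are Wald-type (estimate +/- 1.96 SE).
#' Under the default unit-variance identification the solution equals the raw
#' estimates (idempotence); under marker identification it is the rescaled
#' solution. R-squared of an endogenous latent is 1 minus its standardized
#' disturbance variance; an indicator's R-squared is its communality.
#'
#' @param fit a converged \code{sem_fit}.
#' @return object of class \code{std_solution} with a parameter table
#'   (\code{est_std}, \code{se}, \code{ci_lower}, \code{ci_upper},
#'   \code{p_value}), \code{r_squared} per endogenous latent,
#'   \code{communalities} per indicator, and the implied correlation matrix.
#' @export
standardize <- function(fit) {
  spec <- fit$spec
  params <- fit$params
  evaluator <- make_implied_evaluator(spec, params)
  free_idx <- which(params$free)
  vals <- params$value
  zfun <- function(theta) {
    v <- vals; v[free_idx] <- theta
    std_vector(spec, params, evaluator, v)
  }
  z <- zfun(fit$theta)

  J <- matrix(0, length(z), length(fit$theta))
  h <- 1e-6
  for (k in seq_along(fit$theta)) {
    tp <- fit$theta; tm <- fit$theta
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    J[, k] <- (zfun(tp) - zfun(tm)) / (2 * h)
  }
  se <- sqrt(pmax(diag(J %*% fit$vcov %*% t(J)), 0))
  se[!(params$free | params$type == "variance")] <- NA_real_

  imp <- implied_moments(spec, params)
  tab <- data.frame(label = params$label, type = params$type,
                    lhs = params$lhs, rhs = params$rhs,
                    est_std = z, se = se,
                    ci_lower = z - 1.96 * se, ci_upper = z + 1.96 * se,
                    stringsAsFactors = FALSE)
  tab$p_value <- 2 * stats::pnorm(-abs(tab$est_std / tab$se))
  tab$flag <- ""
  tab$flag[tab$type == "loading" & tab$lhs %in% imp$heywood] <- "heywood"
  tab$flag[tab$type == "variance" & tab$lhs %in% imp$heywood_latent] <- "heywood"

  endo <- names(spec$regressions)
  r2_lat <- stats::setNames(
    vapply(endo, function(f) 1 - imp$psi[f] / max(imp$Phi[f, f], 1e-12),
           numeric(1)), endo)
  comm <- 1 - imp$theta

  structure(list(table = tab, r_squared = r2_lat, communalities = comm,
                 implied = imp$sigma, std_lv = spec$std_lv,
                 heywood = imp$heywood, heywood_latent = imp$heywood_latent),
            class = "std_solution")
}

#' @export
print.std_solution <- function(x, ...) {
  cat("Standardized solution\n")
  tab <- x$table[x$table$type != "variance", ]
  tab$est_std <- round(tab$est_std, 3); tab$se <- round(tab$se, 3)
  tab$ci_lower <- round(tab$ci_lower, 3); tab$ci_upper <- round(tab$ci_upper, 3)
  print(tab[, c("label", "est_std", "se", "ci_lower", "ci_upper", "flag")],
        row.names = FALSE)
  if (length(x$r_squared)) {
    cat("R-squared (latent):",
        paste(sprintf("%s=%.3f", names(x$r_squared), x$r_squared),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Regression-method factor scores
#'
#' Computes per-participant scores for one latent from the fitted moment
#' structure: weights are \eqn{R^{-1} \Lambda \Phi} on the standardized
#' observed indicators, where \eqn{R} is the observed-scale indicator
#' correlation matrix and categorical indicators' latent-scale loadings are
#' attenuated to the observed scale through their thresholds
#' (\eqn{\lambda \sum_j \phi(\tau_j) / sd(y)}). Participants missing some
#' indicators are scored from the available-indicator submatrix; participants
#' missing all indicators get a missing score (count reported via a message).
#' Scores are standardized to mean 0, SD 1 over scored participants.
#'
#' @param fit a converged \code{sem_fit}.
#' @param table the cohort containing the model's indicator columns.
#' @param latent which latent to score (default: the first factor).
#' @return numeric vector of length \code{nrow(table)}.
#' @export
factor_scores <- function(fit, table, latent = names(fit$spec$latents)[1]) {
  spec <- fit$spec
  stopifnot(latent %in% spec$factor_names)
  # use all model indicators loading on any factor correlated with `latent`
  ind <- unique(unlist(spec$latents[vapply(names(spec$latents), function(f)
    abs(fit$Phi[latent, f]) > 1e-10, TRUE)]))
  df <- as.data.frame(table)
  miss_cols <- setdiff(ind, names(df))
  if (length(miss_cols)) {
    stop("table lacks indicator column(s): ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  }
  types <- fit$moments$types[match(ind, fit$moments$variables)]
  thresholds <- fit$moments$thresholds[ind]

  # observed-scale standardized data and attenuated loadings
  Z <- matrix(NA_real_, nrow(df), length(ind), dimnames = list(NULL, ind))
  atten <- stats::setNames(rep(1, length(ind)), ind)
  for (k in seq_along(ind)) {
    y <- df[[ind[k]]]
    mu <- mean(y, na.rm = TRUE); sdv <- stats::sd(y, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) {
      stop("indicator has zero variance: ", ind[k], call. = FALSE)
    }
    Z[, k] <- (y - mu) / sdv
    if (!is.na(types[k]) && is_categorical_type(types[k])) {
      tau <- thresholds[[ind[k]]]
      if (!is.null(tau)) atten[k] <- sum(stats::dnorm(tau)) / sdv
    }
  }

  L <- matrix(0, length(ind), length(spec$factor_names),
              dimnames = list(ind, spec$factor_names))
  lr <- which(fit$params$type == "loading" & fit$params$lhs %in% ind)
  L[cbind(match(fit$params$lhs[lr], ind),
          match(fit$params$rhs[lr], spec$factor_names))] <- fit$params$value[lr]
  L_obs <- L * atten
  cov_lat <- as.vector(L_obs %*% fit$Phi[, latent])   # cov(y_obs*, latent)

  R_obs <- stats::cor(Z, use = "pairwise.complete.obs")
  scores <- rep(NA_real_, nrow(df))
  patterns <- apply(!is.na(Z), 1L, function(r) paste(as.integer(r), collapse = ""))
  for (pat in unique(patterns)) {
    rows <- which(patterns == pat)
    avail <- which(strsplit(pat, "")[[1]] == "1")
    if (!length(avail)) next
    w <- solve(R_obs[avail, avail, drop = FALSE], cov_lat[avail])
    scores[rows] <- Z[rows, avail, drop = FALSE] %*% w
  }
  n_unscored <- sum(is.na(scores))
  if (n_unscored > 0) {
    message(n_unscored, " participant(s) had no observed indicators; score set missing")
  }
  ok <- !is.na(scores)
  scores[ok] <- (scores[ok] - mean(scores[ok])) / stats::sd(scores[ok])
  scores
}
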