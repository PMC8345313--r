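# Independent oracles, deliberately implemented by different routes than the
# package code paths they validate.

# Bivariate normal CDF via the conditional-probability identity and adaptive
# quadrature (stats::integrate): P(X<=h, Y<=k) = int_-inf^h phi(t) *
# Phi((k - rho t)/sqrt(1-rho^2)) dt. Independent of the package's
# Plackett/Gauss-Legendre route.
oracle_pbvnorm <- function(h, k, rho) {
  if (!is.finite(h) && h > 0) return(pnorm(k))
  if (!is.finite(k) && k > 0) return(pnorm(h))
  if (!is.finite(h) || !is.finite(k)) return(0)
  s <- sqrt(1 - rho^2)
  stats::integrate(function(t) dnorm(t) * pnorm((k - rho * t) / s),
                   -Inf, h, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Grid-search tetrachoric oracle for a 2x2 table: coarse grid over rho then a
# fine local grid, maximizing the orthant-probability likelihood with
# thresholds fixed at the margins. Accuracy ~1e-4 in rho.
oracle_tetrachoric <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  n <- sum(tab)
  tx <- qnorm(sum(tab[1, ]) / n)
  ty <- qnorm(sum(tab[, 1]) / n)
  ll <- function(r) {
    p11 <- oracle_pbvnorm(tx, ty, r)
    p12 <- pnorm(tx) - p11
    p21 <- pnorm(ty) - p11
    p22 <- 1 - p11 - p12 - p21
    p <- c(p11, p21, p12, p22)
    if (any(p <= 1e-300)) return(-Inf)
    sum(c(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2]) * log(p))
  }
  coarse <- seq(-0.995, 0.995, by = 0.005)
  v <- vapply(coarse, ll, numeric(1))
  r0 <- coarse[which.max(v)]
  fine <- seq(max(-0.9989, r0 - 0.005), min(0.9989, r0 + 0.005), by = 1e-4)
  vf <- vapply(fine, ll, numeric(1))
  fine[which.max(vf)]
}

# Independent transcription of Williams' (1959) t for comparing dependent
# overlapping correlations r12 vs r13 (shared variable 1), df = n - 3.
oracle_williams_t <- function(r12, r13, r23, n) {
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  rb <- (r12 + r13) / 2
  (r12 - r13) * sqrt((n - 1) * (1 + r23) /
                       (2 * detR * (n - 1) / (n - 3) + rb^2 * (1 - r23)^3))
}

# expand a 2x2 count table into two binary columns
table_to_columns <- function(tab) {
  x <- rep(c(0L, 0L, 1L, 1L), times = c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  y <- rep(c(0L, 1L, 0L, 1L), times = c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  list(x = x, y = y)
}

# mixed_cor stub with given correlation matrix and constant weights, for
# closed-form fitting checks against population moments
stub_moments <- function(R, n = 1000, acov_scale = 1 / n) {
  p <- ncol(R)
  vars <- colnames(R) %||% paste0("v", seq_len(p))
  dimnames(R) <- list(vars, vars)
  acov <- matrix(acov_scale, p, p, dimnames = dimnames(R))
  pair_index <- matrix(0L, p, p)
  labels <- character(p * (p - 1L) / 2L)
  q <- 0L
  for (j in seq_len(p)) for (i in seq_len(p)) {
    if (i >= j) next
    q <- q + 1L
    pair_index[i, j] <- pair_index[j, i] <- q
    labels[q] <- paste0(vars[i], "~", vars[j])
  }
  structure(list(variables = vars, types = rep("continuous", p), R = R,
                 pair_type = matrix("pearson", p, p, dimnames = dimnames(R)),
                 thresholds = stats::setNames(vector("list", p), vars),
                 pair_n = matrix(n, p, p, dimnames = dimnames(R)),
                 acov = acov, Gamma = NULL, pair_index = pair_index,
                 pair_labels = labels,
                 boundary = matrix(FALSE, p, p, dimnames = dimnames(R)),
                 n_rows = n),
            class = "mixed_cor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sem_fit stub carrying only the chi-square fields fit_indices() needs
stub_fit <- function(chisq, df, n = 540, residuals = numeric(0)) {
  structure(list(chisq_adjusted = chisq, df_adjusted = df, df = df,
                 chisq_unadjusted = chisq, residuals = residuals,
                 n_effective = n),
            class = "sem_fit")
}
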