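# Two-stage latent correlation estimators for mixed measurement types.
#
# Stage one fixes thresholds at inverse-normal transforms of the observed
# cumulative category proportions; stage two maximizes the bivariate-normal
# likelihood over the single correlation parameter. This mirrors standard
# categorical-SEM practice (Olsson-type estimators) and keeps the weight
# matrix of the downstream DWLS fit diagonal-compatible.

RHO_BOUND <- 1 - 1e-6

#' Estimate probit thresholds of a categorical column
#'
#' Thresholds are \eqn{\tau_j = \Phi^{-1}} of the cumulative proportion through
#' category \eqn{j}, over observed (non-missing) values. Categories are the
#' sorted unique observed values unless \code{levels} supplies the full coding.
#'
#' @param column integer-coded categorical values (0-based or any ordered
#'   coding); may contain \code{NA}.
#' @param levels optional full vector of category codes (so empty top/bottom
#'   categories can be detected and reported).
#' @return numeric vector of k-1 strictly increasing thresholds.
#' @export
estimate_thresholds <- function(column, levels = NULL) {
  x <- column[!is.na(column)]
  if (length(x) == 0L) stop("no observed values in column", call. = FALSE)
  lev <- levels %||% sort(unique(x))
  if (length(lev) < 2L) {
    stop("degenerate category structure: fewer than 2 observed categories",
         call. = FALSE)
  }
  counts <- tabulate(match(x, lev), nbins = length(lev))
  if (any(counts == 0L)) {
    stop(sprintf("degenerate category: level(s) %s have zero observed mass",
                 paste(lev[counts == 0L], collapse = ", ")), call. = FALSE)
  }
  cum <- cumsum(counts) / sum(counts)
  stats::qnorm(cum[-length(cum)])
}

# Cell probabilities of the contingency table implied by thresholds and rho.
polychoric_cell_probs <- function(tau_x, tau_y, rho) {
  ax <- c(-Inf, tau_x, Inf)
  ay <- c(-Inf, tau_y, Inf)
  kx <- length(ax) - 1L; ky <- length(ay) - 1L
  ix <- rep(seq_len(kx), times = ky)
  iy <- rep(seq_len(ky), each = kx)
  p <- bvn_rect(ax[ix], ax[ix + 1L], ay[iy], ay[iy + 1L], rho)
  matrix(pmax(p, 1e-300), kx, ky)
}

polychoric_loglik <- function(rho, tab, tau_x, tau_y) {
  sum(tab * log(polychoric_cell_probs(tau_x, tau_y, rho)))
}

# Maximize the table likelihood over rho with fixed thresholds. Ties on flat
# likelihoods break toward lower |rho| via a microscopic ridge penalty.
polychoric_rho_mle <- function(tab, tau_x, tau_y, bound = RHO_BOUND) {
  obj <- function(r) -polychoric_loglik(r, tab, tau_x, tau_y) + 1e-10 * r^2
  opt <- stats::optimize(obj, lower = -bound, upper = bound, tol = 1e-9)
  opt$minimum
}

#' Polychoric correlation of two categorical columns
#'
#' Two-stage maximum likelihood: thresholds fixed from the marginals, then the
#' latent correlation maximizing the bivariate-normal cell-probability
#' likelihood of the pairwise-complete contingency table. The binary-by-binary
#' case is the tetrachoric special case.
#'
#' @param x,y integer-coded categorical columns (NA allowed).
#' @param levels_x,levels_y optional full category codings.
#' @param thresholds_x,thresholds_y optional pre-estimated thresholds (e.g.
#'   from the full sample when the pair is estimated on pairwise-complete
#'   rows).
#' @param min_n minimum pairwise-complete count (default 10).
#' @return list with \code{rho}, \code{var} (asymptotic variance of the
#'   estimate), \code{n}, \code{thresholds_x}, \code{thresholds_y},
#'   \code{boundary} flag, and \code{influence} (per-complete-observation
#'   influence values, in row order of the complete cases).
#' @export
polychoric_corr <- function(x, y, levels_x = NULL, levels_y = NULL,
                            thresholds_x = NULL, thresholds_y = NULL,
                            min_n = 10L) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_n) {
    stop(sprintf("insufficient pairwise-complete data (n = %d < %d)", n, min_n),
         call. = FALSE)
  }
  lx <- levels_x %||% sort(unique(x[ok]))
  ly <- levels_y %||% sort(unique(y[ok]))
  if (length(lx) < 2L || length(ly) < 2L) {
    stop("degenerate category structure: a column has a single observed category",
         call. = FALSE)
  }
  xi <- match(x[ok], lx); yi <- match(y[ok], ly)
  tab <- table(factor(xi, levels = seq_along(lx)),
               factor(yi, levels = seq_along(ly)))
  tab <- matrix(as.numeric(tab), length(lx), length(ly))
  tau_x <- thresholds_x %||% estimate_thresholds(x[ok], levels = lx)
  tau_y <- thresholds_y %||% estimate_thresholds(y[ok], levels = ly)
  if (is.unsorted(tau_x, strictly = TRUE) || is.unsorted(tau_y, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }

  boundary <- FALSE
  # A zero row/column margin cannot happen (thresholds demand mass), but a
  # structurally perfect association drives rho to the boundary.
  rho <- polychoric_rho_mle(tab, tau_x, tau_y)
  if (abs(rho) >= RHO_BOUND - 1e-9) {
    boundary <- TRUE
    rho <- sign(rho) * RHO_BOUND
    warning("polychoric estimate at boundary; clamped to +/-(1 - 1e-6)",
            call. = FALSE)
  }

  # Observed information at the optimum (numeric second difference).
  h <- 1e-4
  l0 <- polychoric_loglik(rho, tab, tau_x, tau_y)
  lp <- polychoric_loglik(min(rho + h, RHO_BOUND), tab, tau_x, tau_y)
  lm <- polychoric_loglik(max(rho - h, -RHO_BOUND), tab, tau_x, tau_y)
  info <- -(lp - 2 * l0 + lm) / h^2
  var_rho <- if (is.finite(info) && info > 0) 1 / info else NA_real_

  # Empirical influence through BOTH stages: directional derivative of the
  # two-stage estimator at the observed cell-proportion vector toward each
  # cell's point mass. Exact for the delta-method Gamma construction.
  p_hat <- tab / n
  eps <- 1e-3
  psi_cell <- matrix(0, nrow(tab), ncol(tab))
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      p_pert <- (1 - eps) * p_hat
      p_pert[i, j] <- p_pert[i, j] + eps
      cx <- pmin(cumsum(rowSums(p_pert)), 1 - 1e-12)
      cy <- pmin(cumsum(colSums(p_pert)), 1 - 1e-12)
      rx <- stats::qnorm(cx[-nrow(tab)])
      ry <- stats::qnorm(cy[-ncol(tab)])
      rho_p <- polychoric_rho_mle(p_pert * n, rx, ry)
      psi_cell[i, j] <- (rho_p - rho) / eps
    }
  }
  influence <- psi_cell[cbind(xi, yi)]

  list(rho = rho, var = var_rho, n = n,
       thresholds_x = tau_x, thresholds_y = tau_y,
       boundary = boundary, influence = influence)
}

polyserial_loglik_terms <- function(rho, z, yi, tau) {
  s <- sqrt(max(1 - rho^2, 1e-12))
  a <- c(-Inf, tau, Inf)
  upper <- stats::pnorm((a[yi + 1L] - rho * z) / s)
  lower <- stats::pnorm((a[yi] - rho * z) / s)
  log(pmax(upper - lower, 1e-300))
}

#' Polyserial correlation of a continuous and a categorical column
#'
#' Two-stage ML: the continuous column is standardized, thresholds of the
#' categorical column fixed from its marginals, then the latent correlation
#' maximizes the conditional-probit likelihood.
#'
#' @inheritParams polychoric_corr
#' @param x continuous column; @param y integer-coded categorical column.
#' @return list as in \code{\link{polychoric_corr}}.
#' @export
polyserial_corr <- function(x, y, levels_y = NULL, thresholds_y = NULL,
                            min_n = 10L) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_n) {
    stop(sprintf("insufficient pairwise-complete data (n = %d < %d)", n, min_n),
         call. = FALSE)
  }
  xs <- x[ok]
  if (stats::sd(xs) == 0) {
    stop("degenerate input: continuous column has zero variance", call. = FALSE)
  }
  z <- (xs - mean(xs)) / stats::sd(xs)
  ly <- levels_y %||% sort(unique(y[ok]))
  if (length(ly) < 2L) {
    stop("degenerate category structure: a column has a single observed category",
         call. = FALSE)
  }
  yi <- match(y[ok], ly)
  tau <- thresholds_y %||% estimate_thresholds(y[ok], levels = ly)

  obj <- function(r) -sum(polyserial_loglik_terms(r, z, yi, tau)) + 1e-10 * r^2
  opt <- stats::optimize(obj, lower = -RHO_BOUND, upper = RHO_BOUND, tol = 1e-9)
  rho <- opt$minimum
  boundary <- FALSE
  if (abs(rho) >= RHO_BOUND - 1e-9) {
    boundary <- TRUE
    rho <- sign(rho) * RHO_BOUND
    warning("polyserial estimate at boundary; clamped to +/-(1 - 1e-6)",
            call. = FALSE)
  }

  h <- 1e-4
  lp <- polyserial_loglik_terms(min(rho + h, RHO_BOUND), z, yi, tau)
  lm <- polyserial_loglik_terms(max(rho - h, -RHO_BOUND), z, yi, tau)
  l0 <- polyserial_loglik_terms(rho, z, yi, tau)
  info <- -sum(lp - 2 * l0 + lm) / h^2
  var_rho <- if (is.finite(info) && info > 0) 1 / info else NA_real_

  score <- (lp - lm) / (2 * h)       # per-observation score at the optimum
  influence <- score / (info / n)    # IF = score / mean information

  list(rho = rho, var = var_rho, n = n,
       thresholds_y = tau, boundary = boundary, influence = influence)
}

# Pearson correlation with analytic influence function; asymptotic variance
# uses the normal-theory default (1 - r^2)^2 / n on pairwise-complete rows.
pearson_corr <- function(x, y, min_n = 10L) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_n) {
    stop(sprintf("insufficient pairwise-complete data (n = %d < %d)", n, min_n),
         call. = FALSE)
  }
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("degenerate input: column has zero variance", call. = FALSE)
  }
  r <- stats::cor(xs, ys)
  zx <- (xs - mean(xs)) / stats::sd(xs)
  zy <- (ys - mean(ys)) / stats::sd(ys)
  influence <- zx * zy - (r / 2) * (zx^2 + zy^2)
  list(rho = r, var = (1 - r^2)^2 / n, n = n, boundary = FALSE,
       influence = influence)
}
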