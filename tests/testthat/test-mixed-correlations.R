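# Threshold estimation, latent correlation estimators, and the mixed matrix.

test_that("thresholds are inverse-normal cumulative proportions", {
  expect_equal(estimate_thresholds(rep(c(0, 1), each = 50)), 0)
  x <- rep(c(0, 1), times = c(949, 51))  # 5.1% present
  expect_equal(estimate_thresholds(x), 1.635234, tolerance = 1e-6)
  y <- rep(c(0, 1, 2), each = 30)
  expect_equal(estimate_thresholds(y), c(-0.4307273, 0.4307273),
               tolerance = 1e-6)
  expect_error(estimate_thresholds(c(1, 1, 1)), "fewer than 2")
  expect_error(estimate_thresholds(c(0, 0, 2, 2), levels = 0:2),
               "zero observed mass")
  # estimated thresholds reproduce observed proportions through Phi
  z <- c(rep(0, 13), rep(1, 55), rep(2, 9), rep(3, 23))
  tau <- estimate_thresholds(z)
  expect_equal(pnorm(tau), cumsum(c(13, 55, 9) / 100), tolerance = 1e-12)
})

test_that("bivariate normal CDF matches an independent quadrature oracle", {
  set.seed(42)
  for (i in 1:25) {
    h <- runif(1, -3, 3); k <- runif(1, -3, 3); r <- runif(1, -0.99, 0.99)
    expect_lt(abs(pbvnorm(h, k, r) - oracle_pbvnorm(h, k, r)), 1e-10)
  }
  expect_equal(pbvnorm(0, 0, 0.5), 1 / 4 + asin(0.5) / (2 * pi),
               tolerance = 1e-12)
  expect_equal(pbvnorm(Inf, 1.3, 0.6), pnorm(1.3), tolerance = 1e-12)
  expect_equal(pbvnorm(-Inf, 1.3, 0.6), 0)
})

test_that("polychoric estimate is zero for a balanced independent 2x2 table", {
  cols <- table_to_columns(matrix(c(25, 25, 25, 25), 2))
  est <- polychoric_corr(cols$x, cols$y)
  expect_lt(abs(est$rho), 1e-4)
})

test_that("tetrachoric estimates agree with the grid-search oracle", {
  cols <- table_to_columns(matrix(c(40, 10, 10, 40), 2))
  est <- polychoric_corr(cols$x, cols$y)
  expect_equal(est$rho, oracle_tetrachoric(matrix(c(40, 10, 10, 40), 2,
                                                  byrow = TRUE)),
               tolerance = 1e-3)

  # exhaustive sweep of all 2x2 tables with every cell >= 5 and n <= 24,
  # plus a seeded sample of larger tables up to n = 200
  tables <- list()
  for (n in 20:24) {
    extra <- n - 20
    for (a in 0:extra) for (b in 0:(extra - a)) for (cc in 0:(extra - a - b)) {
      d <- extra - a - b - cc
      tables[[length(tables) + 1L]] <- matrix(c(5 + a, 5 + b, 5 + cc, 5 + d),
                                              2, byrow = TRUE)
    }
  }
  set.seed(7)
  for (i in 1:25) {
    repeat {
      cells <- rmultinom(1, sample(40:200, 1), prob = runif(4, 0.1, 1))[, 1]
      if (all(cells >= 5)) break
    }
    tables[[length(tables) + 1L]] <- matrix(cells, 2)
  }
  for (tab in tables) {
    cols <- table_to_columns(tab)
    est <- suppressWarnings(polychoric_corr(cols$x, cols$y))
    expect_lt(abs(est$rho - oracle_tetrachoric(tab)), 1e-3)
  }
})

test_that("polychoric recovers a known latent correlation within 3 SEs", {
  set.seed(31)
  n <- 100000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  x <- findInterval(z1, qnorm(c(0.3, 0.8)))
  y <- findInterval(z2, qnorm(c(0.5, 0.9)))
  est <- polychoric_corr(x, y)
  expect_lt(abs(est$rho - 0.5), 3 * sqrt(est$var))
  # influence-function variance agrees with the observed-information variance
  expect_equal(var(est$influence) / est$n, est$var, tolerance = 0.15)
})

test_that("polyserial behaves at independence, degeneracy, and known rho", {
  set.seed(13)
  n <- 20000
  x <- rnorm(n); y <- rbinom(n, 1, 0.3)
  est0 <- polyserial_corr(x, y)
  expect_lt(abs(est0$rho), 3 * sqrt(est0$var))

  ydet <- as.integer(x > median(x))  # deterministic dichotomization of x
  estd <- suppressWarnings(polyserial_corr(x, ydet))
  expect_gt(estd$rho, 0.99)

  expect_error(polyserial_corr(rep(1, 100), rbinom(100, 1, 0.5)),
               "zero variance")

  lat <- 0.4 * scale(x)[, 1] + sqrt(1 - 0.16) * rnorm(n)
  y2 <- as.integer(lat > qnorm(0.9))
  est2 <- polyserial_corr(x, y2)
  expect_lt(abs(est2$rho - 0.4), 3 * sqrt(est2$var))
})

test_that("estimators are symmetric and sign-equivariant", {
  set.seed(5)
  n <- 4000
  z1 <- rnorm(n); z2 <- 0.4 * z1 + sqrt(0.84) * rnorm(n)
  x <- findInterval(z1, qnorm(c(0.4, 0.7)))
  y <- findInterval(z2, c(0))
  a <- polychoric_corr(x, y)
  b <- polychoric_corr(y, x)
  expect_equal(a$rho, b$rho, tolerance = 1e-7)
  flipped <- polychoric_corr(x, max(y) - y)
  expect_equal(flipped$rho, -a$rho, tolerance = 1e-7)
  xc <- rnorm(n) + z1
  ps <- polyserial_corr(xc, y)
  ps_f <- polyserial_corr(xc, max(y) - y)
  expect_equal(ps_f$rho, -ps$rho, tolerance = 1e-7)
  ps_neg <- polyserial_corr(-xc, y)
  expect_equal(ps_neg$rho, -ps$rho, tolerance = 1e-7)
})

test_that("mixed_matrix dispatches, handles degenerate sizes, and counts pairs", {
  df <- data.frame(a = rnorm(50))
  sc <- variable_schema("a", "continuous")
  m1 <- mixed_matrix(df, sc, "a")
  expect_equal(unname(m1$R), matrix(1, 1, 1))

  set.seed(8)
  n <- 300
  f <- rnorm(n)
  df2 <- data.frame(c1 = f + rnorm(n), c2 = f + rnorm(n),
                    b1 = as.integer(f + rnorm(n) > 0.5),
                    o1 = findInterval(f + rnorm(n), c(-0.5, 0.8)))
  sc2 <- variable_schema(names(df2), c("continuous", "continuous", "binary",
                                       "ordinal(3)"))
  df2$c1[5] <- NA
  m <- mixed_matrix(df2, sc2, names(df2))
  expect_equal(m$pair_type["c1", "c2"], "pearson")
  expect_equal(m$pair_type["c1", "b1"], "polyserial")
  expect_equal(m$pair_type["b1", "o1"], "polychoric")
  expect_true(isSymmetric(m$R))
  expect_equal(diag(m$R), setNames(rep(1, 4), names(df2)))
  expect_true(all(abs(m$R) <= 1))
  # pairwise deletion accounting: pairs touching c1 lose exactly one row
  expect_equal(m$pair_n["c1", "c2"], n - 1L)
  expect_equal(m$pair_n["c1", "b1"], n - 1L)
  expect_equal(m$pair_n["c2", "b1"], n)
  expect_error(mixed_matrix(df2[1:5, ], sc2, names(df2)),
               "insufficient pairwise-complete")
})

test_that("mixed matrix round-trips the generator's implied structure", {
  params <- default_generating_parameters()
  co <- generate_cohort(params, n = 100000, seed = 12)
  m <- mixed_matrix(co, variables = c("wmh_tiv", "pvs_count", "lacunes",
                                      "microbleeds"))
  lam <- params$svd_loadings
  implied <- tcrossprod(lam)
  diag(implied) <- 1
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(abs(m$R[i, j] - implied[i, j]), 3 * sqrt(m$acov[i, j]))
  }
  # serialization round-trip of estimates
  pre <- file.path(tempdir(), "mixedcor")
  write_mixed_cor(m, pre)
  back <- utils::read.csv(paste0(pre, ".csv"), check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), unname(m$R), ignore_attr = TRUE,
               tolerance = 1e-12)
})
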