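# Implied moments, DWLS estimation, standardization, factor scores.

test_that("implied moments follow the one-factor loading products", {
  spec <- model_spec(latents = list(F = c("y1", "y2", "y3")))
  pt <- parameter_template(spec)
  pt0 <- set_parameters(pt, "y1 =~ F" = 0, "y2 =~ F" = 0, "y3 =~ F" = 0)
  expect_equal(unname(implied_moments(spec, pt0)$sigma), diag(3))
  pt1 <- set_parameters(pt, "y1 =~ F" = 0.5, "y2 =~ F" = 0.6, "y3 =~ F" = 0.7)
  sg <- implied_moments(spec, pt1)$sigma
  expect_equal(sg["y1", "y2"], 0.30)
  expect_equal(sg["y1", "y3"], 0.35)
  expect_equal(sg["y2", "y3"], 0.42)
  expect_equal(diag(sg), setNames(rep(1, 3), c("y1", "y2", "y3")))
})

test_that("implied moments reproduce the generator's population matrix", {
  params <- default_generating_parameters()
  spec <- model_spec(
    latents = list(SVD = c("wmh_tiv", "pvs_count", "lacunes", "microbleeds"),
                   g = svdburden:::COGNITIVE_TESTS,
                   speed = svdburden:::COGNITIVE_DOMAINS$speed),
    regressions = list(g = "SVD", speed = "SVD"))
  pt <- parameter_template(spec)
  pt <- set_parameters(pt, setNames(params$svd_loadings,
                                    paste(names(params$svd_loadings), "=~ SVD")))
  pt <- set_parameters(pt, setNames(params$cognitive_loadings_g,
                                    paste(svdburden:::COGNITIVE_TESTS, "=~ g")))
  sp <- svdburden:::COGNITIVE_DOMAINS$speed
  pt <- set_parameters(pt, setNames(params$cognitive_loadings_domain[sp],
                                    paste(sp, "=~ speed")))
  pt <- set_parameters(pt, "g ~ SVD" = params$structural_paths$svd_to[["g"]],
                       "speed ~ SVD" = params$structural_paths$svd_to[["speed"]])
  sg <- implied_moments(spec, pt)$sigma
  # population correlations assembled directly from the generating algebra
  lam_g <- params$cognitive_loadings_g; lam_d <- params$cognitive_loadings_domain
  b_g <- params$structural_paths$svd_to[["g"]]
  b_s <- params$structural_paths$svd_to[["speed"]]
  expect_equal(sg["wmh_tiv", "pvs_count"],
               prod(params$svd_loadings[c("wmh_tiv", "pvs_count")]))
  expect_equal(sg["wmh_tiv", "digit_symbol"],
               params$svd_loadings[["wmh_tiv"]] *
                 (lam_g[["digit_symbol"]] * b_g + lam_d[["digit_symbol"]] * b_s))
  expect_equal(sg["digit_symbol", "symbol_search"],
               lam_g[["digit_symbol"]] * lam_g[["symbol_search"]] *
                 (b_g^2 + 1 - b_g^2) +      # unit g variance
                 lam_d[["digit_symbol"]] * lam_d[["symbol_search"]] +
                 (lam_g[["digit_symbol"]] * lam_d[["symbol_search"]] +
                    lam_d[["digit_symbol"]] * lam_g[["symbol_search"]]) *
                 b_g * b_s)                 # cov(g, speed) through shared SVD
  expect_equal(sg["digit_symbol", "verbal_paired_associates"],
               lam_g[["digit_symbol"]] * lam_g[["verbal_paired_associates"]] +
                 lam_d[["digit_symbol"]] * b_s * b_g *
                 lam_g[["verbal_paired_associates"]])
})

test_that("cyclic regression graphs are rejected", {
  expect_error(model_spec(latents = list(A = "a1", B = "b1"),
                          regressions = list(A = "B", B = "A")),
               "cyclic")
})

test_that("just-identified CFA matches the closed-form tetrad solution", {
  R <- matrix(c(1, .5, .4, .5, 1, .32, .4, .32, 1), 3)
  colnames(R) <- rownames(R) <- c("y1", "y2", "y3")
  fit <- fit_dwls(model_spec(latents = list(F = c("y1", "y2", "y3"))),
                  stub_moments(R))
  lam <- setNames(fit$params$value[fit$params$free],
                  fit$params$label[fit$params$free])
  expect_equal(unname(lam["y1 =~ F"]), sqrt(.5 * .4 / .32), tolerance = 1e-6)
  expect_equal(unname(lam["y2 =~ F"]), sqrt(.5 * .32 / .4), tolerance = 1e-6)
  expect_equal(unname(lam["y3 =~ F"]), sqrt(.4 * .32 / .5), tolerance = 1e-6)
  expect_equal(fit$df, 0L)
  expect_lt(fit$discrepancy, 1e-10)
})

test_that("population moments are recovered exactly (oracle equivalence)", {
  spec <- model_spec(latents = list(F = paste0("y", 1:4)))
  pt <- parameter_template(spec)
  truth <- c(0.7, -0.55, 0.62, 0.48)
  pt <- set_parameters(pt, setNames(truth, paste0("y", 1:4, " =~ F")))
  sg <- implied_moments(spec, pt)$sigma
  fit <- fit_dwls(spec, stub_moments(sg))
  est <- fit$params$value[fit$params$free]
  # sign indeterminacy of the factor: compare up to a global flip
  if (sum(est * truth) < 0) est <- -est
  expect_equal(est, truth, tolerance = 1e-5)
  expect_lt(fit$discrepancy, 1e-10)
})

test_that("structural path and disturbance recover from population moments", {
  spec <- model_spec(latents = list(X = paste0("x", 1:3), Y = paste0("y", 1:3)),
                     regressions = list(Y = "X"))
  pt <- parameter_template(spec)
  pt <- set_parameters(pt, setNames(c(0.6, 0.7, 0.8), paste0("x", 1:3, " =~ X")),
                       setNames(c(0.5, 0.65, 0.75), paste0("y", 1:3, " =~ Y")))
  pt <- set_parameters(pt, "Y ~ X" = -0.438)
  fit <- fit_dwls(spec, stub_moments(implied_moments(spec, pt)$sigma))
  std <- standardize(fit)
  path <- std$table[std$table$label == "Y ~ X", ]
  expect_equal(abs(path$est_std), 0.438, tolerance = 1e-5)
  expect_equal(unname(std$r_squared["Y"]), 0.438^2, tolerance = 1e-5)
})

test_that("standardization is idempotent and identification-invariant", {
  R <- matrix(c(1, .42, .48, .3,
                .42, 1, .56, .35,
                .48, .56, 1, .4,
                .3, .35, .4, 1), 4)
  colnames(R) <- rownames(R) <- paste0("y", 1:4)
  spec1 <- model_spec(latents = list(F = paste0("y", 1:4)), std_lv = TRUE)
  spec2 <- model_spec(latents = list(F = paste0("y", 1:4)), std_lv = FALSE)
  fit1 <- fit_dwls(spec1, stub_moments(R))
  fit2 <- fit_dwls(spec2, stub_moments(R))
  std1 <- standardize(fit1)
  std2 <- standardize(fit2)
  # idempotence: unit-variance identification is already standardized
  free1 <- fit1$params$free
  expect_equal(std1$table$est_std[free1], fit1$params$value[free1],
               tolerance = 1e-10)
  # invariance: both identifications give the same standardized loadings
  l1 <- std1$table$est_std[std1$table$type == "loading"]
  l2 <- std2$table$est_std[std2$table$type == "loading"]
  if (sum(l1 * l2) < 0) l2 <- -l2
  expect_equal(l1, l2, tolerance = 1e-4)
  expect_equal(std1$communalities, std2$communalities, tolerance = 1e-4)
})

test_that("hand rescaling: unstandardized loading 2 with factor variance 1", {
  # indicator with total variance 4 <=> correlation-metric loading 1, so the
  # standardized loading and communality are exactly 1 (boundary case)
  spec <- model_spec(latents = list(F = c("y1", "y2")), std_lv = FALSE)
  pt <- parameter_template(spec)   # y1 loading fixed at 1, F variance free
  pt <- set_parameters(pt, "y2 =~ F" = 0.5, "F ~~ F" = 1)
  # scale back: loading 2 on sd-2 indicator is loading 1 in correlation metric
  sg <- implied_moments(spec, pt)$sigma
  expect_equal(sg["y1", "y2"], 0.5)
  expect_equal(implied_moments(spec, pt)$theta[["y1"]], 0)
})

test_that("Heywood indicators are flagged, not silently dropped", {
  R <- matrix(c(1, .9, .9, .9, 1, .5, .9, .5, 1), 3)
  colnames(R) <- rownames(R) <- paste0("y", 1:3)
  fit <- fit_dwls(model_spec(latents = list(F = paste0("y", 1:3))),
                  stub_moments(R))
  expect_true("y1" %in% fit$heywood)
  std <- standardize(fit)
  expect_true(any(std$table$flag == "heywood"))
  expect_gt(std$communalities[["y1"]], 1)
})

test_that("single-path standardized beta of -0.363 reports 13% variance", {
  spec <- model_spec(latents = list(X = paste0("x", 1:3), Y = paste0("y", 1:3)),
                     regressions = list(Y = "X"))
  pt <- parameter_template(spec)
  pt <- set_parameters(pt, setNames(rep(0.7, 6), c(paste0("x", 1:3, " =~ X"),
                                                   paste0("y", 1:3, " =~ Y"))))
  pt <- set_parameters(pt, "Y ~ X" = -0.363)
  fit <- fit_dwls(spec, stub_moments(implied_moments(spec, pt)$sigma))
  std <- standardize(fit)
  expect_equal(unname(std$r_squared["Y"]), 0.131769, tolerance = 1e-4)
  expect_equal(round(100 * unname(std$r_squared["Y"])), 13)
})

test_that("SVD mixed CFA recovers the generating communalities", {
  params <- default_generating_parameters()
  co <- generate_cohort(params, n = 30000, seed = 4)
  mm <- build_svd_measurement_model(co)
  lam_hat <- mm$std$table[mm$std$table$type == "loading", ]
  truth <- c(0.25, 0.10, 0.32, 0.18)
  for (k in seq_len(4)) {
    comm <- lam_hat$est_std[k]^2
    se_comm <- 2 * abs(lam_hat$est_std[k]) * lam_hat$se[k]
    expect_lt(abs(comm - truth[k]), 3 * se_comm)
  }
})

test_that("factor scores behave for perfect, equal, and mixed indicators", {
  # perfect single indicator (loading 1, zero residual): the score equals the
  # standardized indicator; constructed fit since a one-indicator model is
  # saturated
  set.seed(3)
  df <- data.frame(y1 = rnorm(400))
  spec <- model_spec(latents = list(F = "y1"))
  pt <- set_parameters(parameter_template(spec), "y1 =~ F" = 1)
  fit1 <- structure(list(spec = spec, params = pt,
                         Phi = matrix(1, 1, 1, dimnames = list("F", "F")),
                         moments = list(types = "continuous",
                                        variables = "y1",
                                        thresholds = list(y1 = NULL))),
                    class = "sem_fit")
  s <- factor_scores(fit1, df, "F")
  expect_equal(s, scale(df$y1)[, 1], tolerance = 1e-10)

  # equal loadings on exchangeable indicators: score proportional to row mean
  set.seed(4)
  f <- rnorm(2000)
  df2 <- data.frame(y1 = 0.6 * f + 0.8 * rnorm(2000),
                    y2 = 0.6 * f + 0.8 * rnorm(2000),
                    y3 = 0.6 * f + 0.8 * rnorm(2000))
  sc2 <- variable_schema(names(df2), rep("continuous", 3))
  fit2 <- fit_dwls(model_spec(latents = list(F = names(df2))),
                   mixed_matrix(df2, sc2, names(df2)))
  fit2$params$value[fit2$params$type == "loading"] <- 0.6
  s2 <- factor_scores(fit2, df2, "F")
  rm2 <- rowMeans(scale(df2))
  expect_gt(abs(cor(s2, rm2)), 0.999)

  # missing-indicator handling: available-indicator submatrix, no NA leak
  df3 <- df2
  df3$y1[1:50] <- NA
  df3[1, ] <- NA
  s3 <- suppressMessages(factor_scores(fit2, df3, "F"))
  expect_true(is.na(s3[1]))
  expect_false(anyNA(s3[-1]))

  # mixed-type vascular CFA: correlation between the score and the
  # generating latent matches the population score reliability computed
  # independently from the generating parameters
  params <- default_generating_parameters()
  co <- generate_cohort(params, n = 30000, seed = 14)
  vr <- build_vascular_risk_factor(co)
  r_obs <- cor(vr$scores, co$.vascular_latent)
  lam <- params$vascular_loadings
  prev <- params$binary_prevalences[c("hypertension", "diabetes", "smoking_ever")]
  vars <- svdburden:::VASCULAR_INDICATORS
  is_bin <- vars %in% names(prev)
  tau <- qnorm(1 - prev)
  # observed-scale cross-correlations with the latent
  c_obs <- ifelse(is_bin,
                  lam[vars] * dnorm(qnorm(1 - prev[vars])) /
                    sqrt(prev[vars] * (1 - prev[vars])),
                  lam[vars])
  # observed-scale population correlation matrix of the indicators
  Rp <- diag(length(vars))
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (i >= j) next
    rho <- lam[vars[i]] * lam[vars[j]]
    if (is_bin[i] && is_bin[j]) {
      pi_ <- prev[vars[i]]; pj_ <- prev[vars[j]]
      p11 <- oracle_pbvnorm(qnorm(pi_), qnorm(pj_), rho)  # P(both present)
      Rp[i, j] <- Rp[j, i] <- (p11 - pi_ * pj_) /
        sqrt(pi_ * (1 - pi_) * pj_ * (1 - pj_))
    } else if (is_bin[i] || is_bin[j]) {
      pb <- prev[vars[if (is_bin[i]) i else j]]
      Rp[i, j] <- Rp[j, i] <- rho * dnorm(qnorm(pb)) / sqrt(pb * (1 - pb))
    } else {
      Rp[i, j] <- Rp[j, i] <- rho
    }
  }
  rel <- sqrt(drop(t(c_obs) %*% solve(Rp, c_obs)))
  expect_lt(abs(abs(r_obs) - rel), 0.02)
  # scored column standardized over scored participants
  expect_equal(mean(vr$scores), 0, tolerance = 1e-10)
  expect_equal(sd(vr$scores), 1, tolerance = 1e-10)
})

test_that("model specs and fit results serialize to structured text", {
  spec <- model_spec(latents = list(F = c("a", "b", "c"), G = c("d", "e")),
                     regressions = list(G = "F"))
  p <- tempfile(fileext = ".json")
  write_model_spec(spec, p)
  back <- read_model_spec(p)
  expect_identical(back$latents, spec$latents)
  expect_identical(back$regressions$G, "F")
  expect_identical(back$std_lv, TRUE)

  R <- matrix(c(1, .5, .4, .5, 1, .32, .4, .32, 1), 3)
  colnames(R) <- rownames(R) <- c("a", "b", "c")
  fit <- fit_dwls(model_spec(latents = list(F = c("a", "b", "c"))),
                  stub_moments(R))
  pre <- tempfile()
  write_fit_result(fit, pre)
  tab <- utils::read.csv(paste0(pre, "_parameters.csv"))
  expect_equal(tab$value[tab$free], fit$params$value[fit$params$free])
  meta <- jsonlite::read_json(paste0(pre, "_fit.json"), simplifyVector = TRUE)
  expect_equal(meta$df, 0L)
})

test_that("non-identified models are rejected up front", {
  R <- diag(2); colnames(R) <- rownames(R) <- c("y1", "y2")
  expect_error(fit_dwls(model_spec(latents = list(F = c("y1", "y2"))),
                        stub_moments(R)),
               "not identified")
})
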