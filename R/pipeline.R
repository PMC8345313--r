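# Orchestration of the full analysis: measurement models, stepwise covariate
# regressions for three predictors by four cognitive outcomes, the orthogonal
# bifactor model, predictor comparisons via the Williams test, and FDR
# control per results table.

COVARIATE_STEPS <- list(
  "none" = character(0),
  "+ age" = "age",
  "+ age + sex" = c("age", "sex_female"),
  "+ age + sex + vascular risk" = c("age", "sex_female", "vascular_risk"),
  "+ age + sex + vascular risk + depression" =
    c("age", "sex_female", "vascular_risk", "hads_depression"),
  "+ age + sex + vascular risk + depression + age-11 IQ" =
    c("age", "sex_female", "vascular_risk", "hads_depression", "iq_age11")
)

ALL_COVARIATES <- c("age", "sex_female", "vascular_risk", "hads_depression",
                    "iq_age11")

outcome_indicators <- function(outcome) {
  switch(outcome,
         g = COGNITIVE_TESTS,
         speed = COGNITIVE_DOMAINS$speed,
         memory = COGNITIVE_DOMAINS$memory,
         visuospatial = COGNITIVE_DOMAINS$visuospatial,
         stop("unknown outcome: ", outcome, call. = FALSE))
}

analysis_schema <- function(table) {
  sc <- schema_of(table)
  if (!("vascular_risk" %in% sc$name) && "vascular_risk" %in% names(table)) {
    sc <- rbind(sc, data.frame(name = "vascular_risk", type = "continuous",
                               role = "covariate"))
  }
  sc
}

#' One-factor measurement model of total SVD burden (computational markers)
#'
#' CFA of WMH/TIV and PVS count (continuous, linear loadings) and lacunes and
#' microbleeds (binary, probit loadings on the latent-response scale) as
#' indicators of a single latent SVD burden factor.
#'
#' @param table cohort with the four marker columns.
#' @param schema variable schema (default: the table's).
#' @param moments optional precomputed \code{mixed_cor} containing the
#'   markers.
#' @return list: \code{fit} (\code{sem_fit}), \code{std}
#'   (\code{std_solution}), \code{indices} (\code{fit_indices}),
#'   \code{communalities}.
#' @export
build_svd_measurement_model <- function(table, schema = NULL, moments = NULL) {
  schema <- schema %||% analysis_schema(table)
  mom <- moments %||% mixed_matrix(table, schema, SVD_MARKERS)
  spec <- model_spec(latents = list(SVD = SVD_MARKERS))
  fit <- fit_dwls(spec, mom)
  std <- standardize(fit)
  idx <- fit_indices(fit, baseline_model(mom, SVD_MARKERS))
  list(fit = fit, std = std, indices = idx,
       communalities = std$communalities[SVD_MARKERS])
}

#' One-factor measurement model of SVD burden from visual ratings
#'
#' Ordinal reconstruction: deep and periventricular Fazekas scores (0-3), the
#' basal-ganglia PVS rating (0-4) and binary lacunes/microbleeds as
#' indicators of a single latent, estimated through polychoric correlations.
#'
#' @inheritParams build_svd_measurement_model
#' @export
build_staals_measurement_model <- function(table, schema = NULL, moments = NULL) {
  schema <- schema %||% analysis_schema(table)
  vars <- c(RATING_COLUMNS, "lacunes", "microbleeds")
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("visual-rating column(s) absent (run derive_visual_ratings): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  mom <- moments %||% mixed_matrix(table, schema, vars)
  spec <- model_spec(latents = list(SVD_ratings = vars))
  fit <- fit_dwls(spec, mom)
  std <- standardize(fit)
  idx <- fit_indices(fit, baseline_model(mom, vars))
  list(fit = fit, std = std, indices = idx,
       communalities = std$communalities[vars])
}

#' Vascular-risk factor score
#'
#' One-factor mixed CFA of the seven vascular-risk indicators (hypertension,
#' diabetes, smoking ever/never binary; HbA1c, total cholesterol, systolic
#' and diastolic blood pressure continuous), with regression-method factor
#' scores appended to the table as column \code{vascular_risk}.
#'
#' @inheritParams build_svd_measurement_model
#' @return list: \code{table} (with the score column), \code{fit},
#'   \code{std}, \code{scores}.
#' @export
build_vascular_risk_factor <- function(table, schema = NULL, moments = NULL) {
  schema <- schema %||% schema_of(table)
  mom <- moments %||% mixed_matrix(table, schema, VASCULAR_INDICATORS)
  spec <- model_spec(latents = list(vascular_risk = VASCULAR_INDICATORS))
  fit <- fit_dwls(spec, mom)
  std <- standardize(fit)
  scores <- factor_scores(fit, table, "vascular_risk")
  df <- as.data.frame(table)
  df$vascular_risk <- scores
  sc <- rbind(schema, data.frame(name = "vascular_risk", type = "continuous",
                                 role = "covariate"))
  out <- new_cohort_table(df, sc, attr(table, "provenance"))
  list(table = out, fit = fit, std = std, scores = scores)
}

stepwise_model_spec <- function(predictor, outcome, covariates) {
  out_ind <- outcome_indicators(outcome)
  latents <- stats::setNames(list(out_ind), outcome)
  obs_exo <- covariates
  if (predictor == "svd_latent") {
    latents$SVD <- SVD_MARKERS
    pred_name <- "SVD"
  } else if (predictor == "staals_latent") {
    latents$SVD_ratings <- c(RATING_COLUMNS, "lacunes", "microbleeds")
    pred_name <- "SVD_ratings"
  } else if (predictor == "wmh_tiv") {
    obs_exo <- c("wmh_tiv", covariates)
    pred_name <- "wmh_tiv"
  } else {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  regressions <- stats::setNames(list(c(pred_name, covariates)), outcome)
  list(spec = model_spec(latents = latents, regressions = regressions,
                         observed_exogenous = obs_exo),
       pred_name = pred_name)
}

fit_one_structural <- function(moments, predictor, outcome, covariates,
                               step_label) {
  sm <- stepwise_model_spec(predictor, outcome, covariates)
  vars <- sm$spec$indicators
  row_na <- data.frame(outcome = outcome, predictor = predictor,
                       step = step_label, beta = NA_real_, se = NA_real_,
                       ci_lower = NA_real_, ci_upper = NA_real_,
                       p_raw = NA_real_, p_fdr = NA_real_,
                       rmsea = NA_real_, cfi = NA_real_, tli = NA_real_,
                       srmr = NA_real_, variance_explained = NA_real_,
                       converged = FALSE, flags = "not_converged",
                       stringsAsFactors = FALSE)
  fit <- tryCatch(fit_dwls(sm$spec, moments), error = function(e) NULL)
  if (is.null(fit)) return(list(row = row_na, fit = NULL, std = NULL))
  std <- standardize(fit)
  idx <- fit_indices(fit, baseline_model(moments, vars))
  prow <- std$table[std$table$type == "path" & std$table$lhs == outcome &
                      std$table$rhs == sm$pred_name, ]
  flags <- character(0)
  if (!fit$convergence$converged) flags <- c(flags, "not_converged")
  if (length(fit$heywood)) flags <- c(flags, paste0("heywood:", fit$heywood))
  row <- data.frame(outcome = outcome, predictor = predictor,
                    step = step_label,
                    beta = prow$est_std, se = prow$se,
                    ci_lower = prow$ci_lower, ci_upper = prow$ci_upper,
                    p_raw = prow$p_value, p_fdr = NA_real_,
                    rmsea = idx$rmsea, cfi = idx$cfi, tli = idx$tli,
                    srmr = idx$srmr,
                    variance_explained = prow$est_std^2,
                    converged = fit$convergence$converged,
                    flags = paste(flags, collapse = ";"),
                    stringsAsFactors = FALSE)
  list(row = row, fit = fit, std = std)
}

#' Stepwise covariate regressions for one predictor-outcome pair
#'
#' Fits the covariate-free latent regression and the five nested covariate
#' additions (age; sex; vascular risk; depression; age-11 IQ) in the
#' canonical order. Covariates correlate freely with one another and with the
#' predictor, and regress onto the cognitive factor. Cognitive columns are
#' expected to be interval-residualized beforehand.
#'
#' @param table cohort (after \code{residualize_for_interval} and
#'   \code{build_vascular_risk_factor}).
#' @param predictor \code{"svd_latent"}, \code{"wmh_tiv"} or
#'   \code{"staals_latent"}.
#' @param outcome \code{"g"}, \code{"speed"}, \code{"memory"} or
#'   \code{"visuospatial"}.
#' @param moments optional precomputed \code{mixed_cor} covering all needed
#'   variables.
#' @param steps covariate steps (named list; default the canonical six).
#' @return data.frame of one report row per step.
#' @export
run_stepwise_models <- function(table, predictor, outcome, moments = NULL,
                                steps = COVARIATE_STEPS) {
  schema <- analysis_schema(table)
  need <- unique(unlist(lapply(steps, function(cv)
    stepwise_model_spec(predictor, outcome, cv)$spec$indicators)))
  moments <- moments %||% mixed_matrix(table, schema, need)
  rows <- lapply(names(steps), function(lbl) {
    fit_one_structural(moments, predictor, outcome, steps[[lbl]], lbl)$row
  })
  do.call(rbind, rows)
}

#' Orthogonal bifactor model of cognitive ability with SVD and covariates
#'
#' Every test loads on the general factor g and on its orthogonal domain
#' factor (speed, memory, visuospatial); latent SVD burden (four
#' computational markers) regresses onto g and each domain factor; the five
#' covariates enter simultaneously, free to correlate with one another and
#' with SVD. FDR is applied across the four SVD paths. A near-zero domain
#' residual variance is tolerated with a flag rather than an error.
#'
#' @param table cohort after residualization and vascular scoring.
#' @param moments optional precomputed \code{mixed_cor}.
#' @param covariates covariate set entered simultaneously (default all five;
#'   use \code{character(0)} for the measurement-plus-SVD model only).
#' @param covariates_on \code{"all"} regresses covariates on g and the three
#'   domain factors; \code{"g_only"} on g alone.
#' @return list: \code{block} (four-row data.frame of standardized SVD paths
#'   with CIs, raw and FDR p), \code{fit}, \code{std}, \code{indices}.
#' @export
run_bifactor_model <- function(table, moments = NULL,
                               covariates = ALL_COVARIATES,
                               covariates_on = c("all", "g_only")) {
  covariates_on <- match.arg(covariates_on)
  schema <- analysis_schema(table)
  latents <- c(list(SVD = SVD_MARKERS, g = COGNITIVE_TESTS), COGNITIVE_DOMAINS)
  facs <- c("g", names(COGNITIVE_DOMAINS))
  regressions <- stats::setNames(lapply(facs, function(f) {
    covs <- if (covariates_on == "all" || f == "g") covariates else character(0)
    c("SVD", covs)
  }), facs)
  spec <- model_spec(latents = latents, regressions = regressions,
                     observed_exogenous = covariates,
                     orthogonal = list(facs))
  vars <- spec$indicators
  moments <- moments %||% mixed_matrix(table, schema, vars)
  fit <- fit_dwls(spec, moments)
  std <- standardize(fit)
  idx <- fit_indices(fit, baseline_model(moments, vars))
  rows <- std$table[std$table$type == "path" & std$table$rhs == "SVD", ]
  block <- data.frame(factor = rows$lhs, beta = rows$est_std, se = rows$se,
                      ci_lower = rows$ci_lower, ci_upper = rows$ci_upper,
                      p_raw = rows$p_value,
                      p_fdr = bh_adjust(rows$p_value, "bifactor SVD paths")$adjusted,
                      flags = rows$flag, stringsAsFactors = FALSE)
  if (length(fit$heywood_latent)) {
    block$flags <- ifelse(block$factor %in% fit$heywood_latent,
                          paste0(block$flags, ";heywood_latent"), block$flags)
  }
  list(block = block, fit = fit, std = std, indices = idx)
}

#' Williams comparisons of two predictors across outcomes
#'
#' For each outcome score, computes the correlation of the outcome with each
#' predictor score and between the predictors, then Williams' one-sided t for
#' the difference of the dependent overlapping correlations. Comparisons of
#' negative associations are orientation-normalized so that t is negative
#' when predictor A's association magnitude is the larger.
#'
#' @param scores_a,scores_b per-participant predictor scores (factor scores
#'   for latent predictors; the observed standardized column for WMH/TIV).
#' @param outcome_scores named list (or data.frame) of per-participant
#'   outcome scores.
#' @param label_a,label_b predictor labels for the output.
#' @return data.frame with one row per outcome: the three correlations,
#'   complete-case n, t, df, and one- and two-sided p.
#' @export
compare_predictors <- function(scores_a, scores_b, outcome_scores,
                               label_a = "A", label_b = "B") {
  rows <- lapply(names(outcome_scores), function(oc) {
    y <- outcome_scores[[oc]]
    ok <- !is.na(y) & !is.na(scores_a) & !is.na(scores_b)
    n <- sum(ok)
    r12 <- stats::cor(y[ok], scores_a[ok])
    r13 <- stats::cor(y[ok], scores_b[ok])
    r23 <- stats::cor(scores_a[ok], scores_b[ok])
    # compare magnitudes: orient so both associations are positive, then
    # t < 0 means predictor A carries the larger magnitude (the
    # weaker-minus-stronger difference is reported as negative)
    s <- if (stats::median(c(r12, r13)) < 0) -1 else 1
    wt <- williams_test(s * r13, s * r12, r23, n)
    data.frame(outcome = oc, r_a = r12, r_b = r13, r_ab = r23, n = n,
               t_value = wt$t_value, df = wt$df,
               p_one_sided = wt$p_one_sided, p_two_sided = wt$p_two_sided,
               stronger = ifelse(abs(r12) > abs(r13), label_a, label_b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "predictors") <- c(label_a, label_b)
  out
}

#' Run the full study pipeline
#'
#' Residualizes cognitive scores for the scan-test interval, extracts the
#' vascular-risk factor score, fits both SVD measurement models, runs the
#' stepwise grid (three predictors by four outcomes by six covariate steps),
#' the orthogonal bifactor model with simultaneous covariates, applies FDR
#' within each results table, and computes Williams comparisons between
#' predictors.
#'
#' @param table a cohort including the visual-rating columns (see
#'   \code{\link{derive_visual_ratings}}).
#' @param predictors subset of \code{c("svd_latent", "wmh_tiv",
#'   "staals_latent")}.
#' @param outcomes subset of \code{c("g", "speed", "memory",
#'   "visuospatial")}.
#' @param fdr_family \code{"per_table"} (one BH family per predictor grid,
#'   default) or \code{"global"} (one family across all stepwise rows).
#' @return object of class \code{analysis_report}.
#' @export
run_study <- function(table,
                      predictors = c("svd_latent", "wmh_tiv", "staals_latent"),
                      outcomes = c("g", "speed", "memory", "visuospatial"),
                      fdr_family = c("per_table", "global")) {
  fdr_family <- match.arg(fdr_family)
  table <- residualize_for_interval(table)
  vr <- build_vascular_risk_factor(table)
  table <- vr$table
  schema <- analysis_schema(table)

  all_vars <- unique(c(SVD_MARKERS,
                       if ("staals_latent" %in% predictors) RATING_COLUMNS,
                       COGNITIVE_TESTS, ALL_COVARIATES))
  moments <- mixed_matrix(table, schema, all_vars)

  svd_mm <- build_svd_measurement_model(table, schema, moments)
  staals_mm <- if ("staals_latent" %in% predictors) {
    build_staals_measurement_model(table, schema, moments)
  }

  stepwise <- list()
  for (pr in predictors) {
    rows_pr <- list()
    for (oc in outcomes) {
      rows_pr[[oc]] <- run_stepwise_models(table, pr, oc, moments = moments)
    }
    grid <- do.call(rbind, rows_pr)
    if (fdr_family == "per_table") {
      grid$p_fdr <- bh_adjust(grid$p_raw, paste0("stepwise:", pr))$adjusted
    }
    stepwise[[pr]] <- grid
  }
  stepwise <- do.call(rbind, stepwise)
  rownames(stepwise) <- NULL
  if (fdr_family == "global") {
    stepwise$p_fdr <- bh_adjust(stepwise$p_raw, "stepwise:global")$adjusted
  }

  bifactor <- run_bifactor_model(table, moments = moments)

  # predictor scores for the Williams comparisons (factor scores for the
  # latents, standardized observed column for WMH/TIV)
  scores <- list(
    svd_latent = factor_scores(svd_mm$fit, table, "SVD"),
    wmh_tiv = as.vector(scale(table$wmh_tiv))
  )
  if (!is.null(staals_mm)) {
    scores$staals_latent <- factor_scores(staals_mm$fit, table, "SVD_ratings")
  }
  outcome_scores <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
    om <- model_spec(latents = stats::setNames(list(outcome_indicators(oc)), oc))
    factor_scores(fit_dwls(om, moments), table, oc)
  })
  comparisons <- list()
  if (all(c("svd_latent", "wmh_tiv") %in% predictors)) {
    comparisons$svd_vs_wmh <- compare_predictors(
      scores$svd_latent, scores$wmh_tiv, outcome_scores,
      "svd_latent", "wmh_tiv")
  }
  if (all(c("svd_latent", "staals_latent") %in% predictors)) {
    comparisons$svd_vs_staals <- compare_predictors(
      scores$svd_latent, scores$staals_latent, outcome_scores,
      "svd_latent", "staals_latent")
  }

  measurement <- data.frame(
    model = c("svd_computational",
              if (!is.null(staals_mm)) "svd_ratings"),
    rmsea = c(svd_mm$indices$rmsea,
              if (!is.null(staals_mm)) staals_mm$indices$rmsea),
    cfi = c(svd_mm$indices$cfi, if (!is.null(staals_mm)) staals_mm$indices$cfi),
    tli = c(svd_mm$indices$tli, if (!is.null(staals_mm)) staals_mm$indices$tli),
    srmr = c(svd_mm$indices$srmr,
             if (!is.null(staals_mm)) staals_mm$indices$srmr),
    stringsAsFactors = FALSE)

  structure(list(stepwise = stepwise, measurement = measurement,
                 bifactor_block = bifactor$block,
                 bifactor_indices = bifactor$indices,
                 comparisons = comparisons,
                 svd_measurement = svd_mm, staals_measurement = staals_mm,
                 vascular = vr, n = nrow(table),
                 fdr_family = fdr_family),
            class = "analysis_report")
}
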