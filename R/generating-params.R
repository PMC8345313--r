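# The generative truth for synthetic cohorts: standardized loadings,
# probit thresholds, structural paths and marginal calibrations. Defaults are
# calibrated to the published cohort descriptives (n = 540 community-dwelling
# older adults) and to the reported standardized estimates of the SVD
# measurement model and the bifactor structural model.

COGNITIVE_TESTS <- c("digit_symbol", "symbol_search", "four_choice_rt",
                     "inspection_time", "verbal_paired_associates",
                     "logical_memory", "digit_span", "block_design",
                     "matrix_reasoning", "spatial_span")

COGNITIVE_DOMAINS <- list(
  speed = c("digit_symbol", "symbol_search", "four_choice_rt", "inspection_time"),
  memory = c("verbal_paired_associates", "logical_memory", "digit_span"),
  visuospatial = c("block_design", "matrix_reasoning", "spatial_span")
)

SVD_MARKERS <- c("wmh_tiv", "pvs_count", "lacunes", "microbleeds")

VASCULAR_INDICATORS <- c("hypertension", "diabetes", "smoking_ever",
                         "hba1c", "cholesterol", "systolic_bp", "diastolic_bp")

RATING_COLUMNS <- c("fazekas_deep", "fazekas_periventricular", "bg_pvs_rating")

#' Default generating parameters for the synthetic cohort
#'
#' SVD marker loadings are the square roots of the published communalities
#' (25/10/32/18 percent of variance in WMH/TIV, PVS count, lacunes and
#' microbleeds); binary prevalences, means and SDs match the published cohort
#' table; structural SVD-to-cognition paths default to the bifactor estimates
#' (g -0.224, speed -0.325, memory -0.133, visuospatial 0.075).
#'
#' @return object of class \code{generating_parameters}.
#' @export
default_generating_parameters <- function() {
  p <- list(
    svd_loadings = c(wmh_tiv = sqrt(0.25), pvs_count = sqrt(0.10),
                     lacunes = sqrt(0.32), microbleeds = sqrt(0.18)),
    binary_prevalences = c(lacunes = 0.051, microbleeds = 0.120,
                           sex_female = 0.467, hypertension = 0.480,
                           diabetes = 0.100, smoking_ever = 0.507),
    cognitive_loadings_g = c(digit_symbol = 0.70, symbol_search = 0.65,
                             four_choice_rt = 0.55, inspection_time = 0.50,
                             verbal_paired_associates = 0.55,
                             logical_memory = 0.60, digit_span = 0.50,
                             block_design = 0.75, matrix_reasoning = 0.70,
                             spatial_span = 0.65),
    cognitive_loadings_domain = c(digit_symbol = 0.45, symbol_search = 0.45,
                                  four_choice_rt = 0.50, inspection_time = 0.40,
                                  verbal_paired_associates = 0.55,
                                  logical_memory = 0.60, digit_span = 0.40,
                                  block_design = 0.30, matrix_reasoning = 0.30,
                                  spatial_span = 0.35),
    structural_paths = list(
      svd_to = c(g = -0.224, speed = -0.325, memory = -0.133,
                 visuospatial = 0.075),
      covariate_to_g = c(age = -0.05, sex_female = 0.03, vascular_risk = -0.10,
                         hads_depression = -0.10, iq_age11 = 0.55)
    ),
    vascular_loadings = c(hypertension = 0.60, diabetes = 0.40,
                          smoking_ever = 0.30, hba1c = 0.45, cholesterol = 0.20,
                          systolic_bp = 0.65, diastolic_bp = 0.55),
    rating_loadings = c(fazekas_deep = 0.65, fazekas_periventricular = 0.65,
                        bg_pvs_rating = 0.45),
    ordinal_thresholds = list(
      fazekas_deep = stats::qnorm(c(0.35, 0.80, 0.95)),
      fazekas_periventricular = stats::qnorm(c(0.25, 0.70, 0.92)),
      bg_pvs_rating = stats::qnorm(c(0.10, 0.55, 0.85, 0.97))
    ),
    continuous_marginals = rbind(
      wmh_tiv = c(mean = 0.008, sd = 0.009),
      pvs_count = c(mean = 258.7, sd = 94.6),
      age = c(mean = 72.6, sd = 0.7),
      systolic_bp = c(mean = 146.5, sd = 18.0),
      diastolic_bp = c(mean = 79.7, sd = 18.0),
      hba1c = c(mean = 5.7, sd = 0.6),
      cholesterol = c(mean = 5.2, sd = 1.1),
      hads_depression = c(mean = 2.5, sd = 2.1),
      iq_age11 = c(mean = 50.2, sd = 11.9),
      interval_days = c(mean = 65, sd = 38)
    ),
    # Correlations among the exogenous latents of the structural model:
    # latent SVD, latent vascular risk, and the (latent continua of the)
    # covariates. Age is uncorrelated with SVD by default (very narrow age
    # range, SD 0.7 y); vascular risk has a modest positive correlation with
    # SVD; childhood IQ a small negative one.
    covariate_correlations = {
      v <- c("svd", "vascular_risk", "age", "sex_female", "hads_depression",
             "iq_age11")
      R <- diag(length(v)); dimnames(R) <- list(v, v)
      R["svd", "vascular_risk"] <- R["vascular_risk", "svd"] <- 0.20
      R["svd", "iq_age11"] <- R["iq_age11", "svd"] <- -0.10
      R["vascular_risk", "hads_depression"] <-
        R["hads_depression", "vascular_risk"] <- 0.10
      R
    },
    interval_effect = -0.002,  # SD units of manifest score per day
    missing_rate = 0.01,       # MCAR rate per cognitive column
    wmh_distribution = "normal"
  )
  class(p) <- "generating_parameters"
  validate_generating_parameters(p)
  p
}

#' Validate generating parameters
#'
#' Checks loading/path ranges, prevalences, threshold monotonicity,
#' orthogonal-bifactor communalities, and positive semi-definiteness of the
#' exogenous correlation matrix.
#'
#' @param params a \code{generating_parameters} object.
#' @return the validated object, invisibly on success.
#' @export
validate_generating_parameters <- function(params) {
  stopifnot(inherits(params, "generating_parameters"))
  ld <- c(params$svd_loadings, params$cognitive_loadings_g,
          params$cognitive_loadings_domain, params$vascular_loadings,
          params$rating_loadings, unlist(params$structural_paths))
  if (any(abs(ld) > 1)) {
    stop("all loadings and structural paths must lie in [-1, 1]", call. = FALSE)
  }
  comm <- params$cognitive_loadings_g^2 + params$cognitive_loadings_domain^2
  if (any(comm > 1)) {
    stop("bifactor communality exceeds 1 for: ",
         paste(names(comm)[comm > 1], collapse = ", "), call. = FALSE)
  }
  pv <- params$binary_prevalences
  if (any(pv <= 0 | pv >= 1)) {
    stop("binary prevalences must lie strictly in (0, 1)", call. = FALSE)
  }
  for (nm in names(params$ordinal_thresholds)) {
    tau <- params$ordinal_thresholds[[nm]]
    if (is.unsorted(tau, strictly = TRUE)) {
      stop("ordinal thresholds for ", nm, " are not strictly increasing",
           call. = FALSE)
    }
  }
  check_psd(params$covariate_correlations,
            "exogenous (covariate) correlation block")
  if (exogenous_r2(params, "g") >= 1) {
    stop("structural paths imply variance of g >= 1 (non-PSD latent block)",
         call. = FALSE)
  }
  invisible(params)
}

# Variance of an endogenous cognitive factor explained by its predictors
# under `params` (used both by the generator and by implied-moment checks).
exogenous_r2 <- function(params, factor) {
  R <- params$covariate_correlations
  if (factor == "g") {
    b <- c(svd = unname(params$structural_paths$svd_to["g"]),
           params$structural_paths$covariate_to_g)
    pred <- c("svd", names(params$structural_paths$covariate_to_g))
    as.numeric(t(b) %*% R[pred, pred] %*% b)
  } else {
    unname(params$structural_paths$svd_to[factor])^2
  }
}

#' @export
print.generating_parameters <- function(x, ...) {
  cat("Generating parameters for a synthetic SVD-cognition cohort\n")
  cat("  SVD marker loadings:   ",
      paste(sprintf("%s=%.3f", names(x$svd_loadings), x$svd_loadings),
            collapse = ", "), "\n")
  cat("  Structural SVD paths:  ",
      paste(sprintf("%s=%.3f", names(x$structural_paths$svd_to),
                    x$structural_paths$svd_to), collapse = ", "), "\n")
  cat("  Binary prevalences:    ",
      paste(sprintf("%s=%.3f", names(x$binary_prevalences),
                    x$binary_prevalences), collapse = ", "), "\n")
  cat("  Missing rate (cognitive columns):", x$missing_rate, "\n")
  invisible(x)
}
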