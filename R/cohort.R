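# Synthetic cohort generation. Latent factors (SVD burden, general cognitive
# ability g, orthogonal domain factors, vascular risk, covariate continua) are
# drawn from a multivariate normal with the structural correlation implied by
# the generating parameters; manifest variables are emitted as
# loading * latent + residual, affinely rescaled to the target marginals for
# continuous columns and probit-thresholded for binary/ordinal columns.

#' Variable schema of a generated cohort
#'
#' One row per column: \code{name}, measurement \code{type}
#' (\code{continuous}, \code{binary}, \code{ordinal(k)}, \code{identifier})
#' and \code{role} (\code{indicator}, \code{covariate}, \code{auxiliary},
#' \code{identifier}).
#'
#' @param include_ratings add the three visual-rating ordinal columns.
#' @return data.frame schema.
#' @export
cohort_schema <- function(include_ratings = FALSE) {
  rows <- list(
    c("participant_id", "identifier", "identifier"),
    c("wmh_tiv", "continuous", "indicator"),
    c("pvs_count", "continuous", "indicator"),
    c("lacunes", "binary", "indicator"),
    c("microbleeds", "binary", "indicator")
  )
  for (tst in COGNITIVE_TESTS) rows <- c(rows, list(c(tst, "continuous", "indicator")))
  rows <- c(rows, list(
    c("age", "continuous", "covariate"),
    c("sex_female", "binary", "covariate"),
    c("hypertension", "binary", "indicator"),
    c("diabetes", "binary", "indicator"),
    c("smoking_ever", "binary", "indicator"),
    c("hba1c", "continuous", "indicator"),
    c("cholesterol", "continuous", "indicator"),
    c("systolic_bp", "continuous", "indicator"),
    c("diastolic_bp", "continuous", "indicator"),
    c("hads_depression", "continuous", "covariate"),
    c("iq_age11", "continuous", "covariate"),
    c("interval_days", "continuous", "covariate"),
    c(".svd_latent", "continuous", "auxiliary"),
    c(".g_latent", "continuous", "auxiliary"),
    c(".vascular_latent", "continuous", "auxiliary")
  ))
  if (include_ratings) {
    rows <- c(rows, list(
      c("fazekas_deep", "ordinal(4)", "indicator"),
      c("fazekas_periventricular", "ordinal(4)", "indicator"),
      c("bg_pvs_rating", "ordinal(5)", "indicator")
    ))
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("name", "type", "role")
  out
}

new_cohort_table <- function(df, schema, provenance = NULL) {
  stopifnot(all(schema$name %in% names(df)))
  structure(df, schema = schema, provenance = provenance,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  pr <- attr(x, "provenance")
  cat(sprintf("Synthetic cohort table: %d participants, %d columns\n",
              nrow(x), ncol(x)))
  if (!is.null(pr)) {
    cat(sprintf("  provenance: seed = %s, parameter checksum = %s\n",
                pr$seed, pr$params_checksum))
  }
  utils::str(as.data.frame(utils::head(x, 3)), give.attr = FALSE)
  invisible(x)
}

#' Retrieve the schema of a cohort table
#' @param table a \code{cohort_table}.
#' @return the schema data.frame.
#' @export
schema_of <- function(table) {
  sc <- attr(table, "schema")
  if (is.null(sc)) stop("table carries no variable schema", call. = FALSE)
  sc
}

#' Generate a synthetic cohort
#'
#' Draws the latent factors from a multivariate normal with the correlation
#' structure implied by \code{params}, emits manifest indicators by linear
#' measurement (continuous) or probit thresholding at \eqn{\Phi^{-1}} of
#' cumulative prevalences (binary/ordinal), applies the scan-test interval
#' effect to cognitive scores, and finally imposes MCAR missingness on the
#' cognitive columns. Deterministic given \code{(params, n, seed)}.
#'
#' @param params a \code{generating_parameters} object.
#' @param n number of participants (n = 0 yields an empty table with the full
#'   column set).
#' @param seed integer RNG seed.
#' @return a \code{cohort_table}.
#' @export
generate_cohort <- function(params = default_generating_parameters(),
                            n = 540L, seed = 1L) {
  validate_generating_parameters(params)
  stopifnot(n >= 0)
  n <- as.integer(n)
  with_rng_seed(seed, {
    exo_names <- colnames(params$covariate_correlations)
    R <- params$covariate_correlations
    L <- tryCatch(chol(R), error = function(e) {
      stop("exogenous (covariate) correlation block is not positive definite",
           call. = FALSE)
    })
    exo <- matrix(stats::rnorm(n * length(exo_names)), nrow = n,
                  ncol = length(exo_names)) %*% L
    colnames(exo) <- exo_names

    # Endogenous cognitive factors, unit marginal variance by construction.
    b_cov <- params$structural_paths$covariate_to_g
    g_expl <- exogenous_r2(params, "g")
    g <- as.vector(exo[, "svd", drop = FALSE] * params$structural_paths$svd_to["g"] +
                     exo[, names(b_cov), drop = FALSE] %*% b_cov) +
      stats::rnorm(n) * sqrt(1 - g_expl)
    domains <- sapply(names(COGNITIVE_DOMAINS), function(d) {
      b <- params$structural_paths$svd_to[d]
      exo[, "svd"] * b + stats::rnorm(n) * sqrt(1 - b^2)
    })
    if (n == 0L) domains <- matrix(0, 0, length(COGNITIVE_DOMAINS),
                                   dimnames = list(NULL, names(COGNITIVE_DOMAINS)))

    cm <- params$continuous_marginals
    rescale <- function(z, var) cm[var, "mean"] + cm[var, "sd"] * z
    thr_binary <- function(latent, loading, prev) {
      ystar <- loading * latent + stats::rnorm(n) * sqrt(1 - loading^2)
      as.integer(ystar > stats::qnorm(1 - prev))
    }

    df <- data.frame(participant_id = seq_len(n))

    # SVD markers
    lam <- params$svd_loadings
    z_wmh <- lam["wmh_tiv"] * exo[, "svd"] +
      stats::rnorm(n) * sqrt(1 - lam["wmh_tiv"]^2)
    if (identical(params$wmh_distribution, "lognormal")) {
      # same latent correlation structure on the log scale, marginal matched
      # by moment-matching the lognormal to the target mean/SD
      mu <- cm["wmh_tiv", "mean"]; sdv <- cm["wmh_tiv", "sd"]
      s2 <- log(1 + (sdv / mu)^2)
      df$wmh_tiv <- exp(log(mu) - s2 / 2 + sqrt(s2) * z_wmh)
    } else {
      df$wmh_tiv <- rescale(z_wmh, "wmh_tiv")
    }
    df$pvs_count <- round(rescale(
      lam["pvs_count"] * exo[, "svd"] +
        stats::rnorm(n) * sqrt(1 - lam["pvs_count"]^2), "pvs_count"))
    df$lacunes <- thr_binary(exo[, "svd"], lam["lacunes"],
                             params$binary_prevalences["lacunes"])
    df$microbleeds <- thr_binary(exo[, "svd"], lam["microbleeds"],
                                 params$binary_prevalences["microbleeds"])

    # Cognitive tests (z-score scale), interval effect applied last.
    interval <- pmax(round(stats::rnorm(n, cm["interval_days", "mean"],
                                        cm["interval_days", "sd"])), 0)
    domain_of <- stats::setNames(
      rep(names(COGNITIVE_DOMAINS), lengths(COGNITIVE_DOMAINS)),
      unlist(COGNITIVE_DOMAINS))
    for (tst in COGNITIVE_TESTS) {
      lg <- params$cognitive_loadings_g[tst]
      ld <- params$cognitive_loadings_domain[tst]
      resid <- sqrt(1 - lg^2 - ld^2)
      sc <- lg * g + ld * domains[, domain_of[tst]] + stats::rnorm(n) * resid
      df[[tst]] <- sc + params$interval_effect *
        (interval - cm["interval_days", "mean"])
    }

    # Covariates
    df$age <- rescale(exo[, "age"], "age")
    df$sex_female <- thr_binary(exo[, "sex_female"], 1,
                                params$binary_prevalences["sex_female"])
    vl <- params$vascular_loadings
    for (v in c("hypertension", "diabetes", "smoking_ever")) {
      df[[v]] <- thr_binary(exo[, "vascular_risk"], vl[v],
                            params$binary_prevalences[v])
    }
    for (v in c("hba1c", "cholesterol", "systolic_bp", "diastolic_bp")) {
      df[[v]] <- rescale(vl[v] * exo[, "vascular_risk"] +
                           stats::rnorm(n) * sqrt(1 - vl[v]^2), v)
    }
    df$hads_depression <- rescale(exo[, "hads_depression"], "hads_depression")
    df$iq_age11 <- rescale(exo[, "iq_age11"], "iq_age11")
    df$interval_days <- interval

    # Auxiliary latent columns for validation and rating derivation.
    df$.svd_latent <- exo[, "svd"]
    df$.g_latent <- g
    df$.vascular_latent <- exo[, "vascular_risk"]

    # MCAR missingness on cognitive columns only.
    if (params$missing_rate > 0 && n > 0) {
      for (tst in COGNITIVE_TESTS) {
        drop <- stats::runif(n) < params$missing_rate
        df[[tst]][drop] <- NA_real_
      }
    }

    new_cohort_table(df, cohort_schema(),
                     provenance = list(seed = seed,
                                       params_checksum = param_checksum(params)))
  })
}

#' Add visual-rating ordinal columns to a cohort
#'
#' Generates the two Fazekas scales (0-3) and the basal-ganglia PVS rating
#' (0-4) from the same latent SVD continuum used for the computational
#' markers: each rating's continuum is loading * SVD + rating noise,
#' partitioned at the parameter thresholds. If the auxiliary latent column is
#' absent, the standardized continuous markers are ordinalized directly
#' (WMH/TIV for the Fazekas scales, PVS count for the basal-ganglia rating).
#'
#' @param table a \code{cohort_table}.
#' @param params a \code{generating_parameters} object.
#' @param seed integer RNG seed for the rating noise.
#' @return the cohort with three ordinal columns appended and schema updated.
#' @export
derive_visual_ratings <- function(table, params = default_generating_parameters(),
                                  seed = 1L) {
  validate_generating_parameters(params)
  n <- nrow(table)
  marker_proxy <- c(fazekas_deep = "wmh_tiv",
                    fazekas_periventricular = "wmh_tiv",
                    bg_pvs_rating = "pvs_count")
  with_rng_seed(seed, {
    df <- as.data.frame(table)
    for (rc in RATING_COLUMNS) {
      tau <- params$ordinal_thresholds[[rc]]
      if (is.unsorted(tau, strictly = TRUE)) {
        stop("ordinal thresholds for ", rc, " are not strictly increasing",
             call. = FALSE)
      }
      lam <- params$rating_loadings[rc]
      if (".svd_latent" %in% names(df)) {
        ystar <- lam * df$.svd_latent + stats::rnorm(n) * sqrt(1 - lam^2)
      } else {
        mk <- df[[marker_proxy[rc]]]
        ystar <- (mk - mean(mk, na.rm = TRUE)) / stats::sd(mk, na.rm = TRUE)
      }
      df[[rc]] <- findInterval(ystar, tau)
    }
    sc <- attr(table, "schema")
    extra <- cohort_schema(include_ratings = TRUE)
    sc <- rbind(sc, extra[extra$name %in% RATING_COLUMNS & !(extra$name %in% sc$name), ])
    new_cohort_table(df, sc, provenance = attr(table, "provenance"))
  })
}

#' Write a cohort to CSV with a JSON schema sidecar
#'
#' @param table a \code{cohort_table}.
#' @param prefix output path prefix; writes \code{<prefix>.csv} and
#'   \code{<prefix>.schema.json}.
#' @return the two paths, invisibly.
#' @export
write_cohort <- function(table, prefix) {
  csv <- paste0(prefix, ".csv")
  sidecar <- paste0(prefix, ".schema.json")
  utils::write.csv(as.data.frame(table), csv, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(schema = schema_of(table),
         provenance = attr(table, "provenance") %||% list()),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, sidecar))
}

#' Read a cohort written by \code{write_cohort}
#' @param prefix path prefix used at write time.
#' @return a \code{cohort_table}.
#' @export
read_cohort <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".schema.json"),
                              simplifyVector = TRUE)
  new_cohort_table(df, as.data.frame(meta$schema),
                   provenance = as.list(meta$provenance))
}
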