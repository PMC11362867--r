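#' Pearson chi-square test of independence on a contingency table
#'
#' Computes the Pearson statistic with expected counts from the margin
#' products. For 2x2 tables the Yates continuity correction is applied
#' (each |O - E| reduced by 0.5), matching the convention of standard R
#' output; larger tables are uncorrected. A zero row or column margin
#' makes expected counts degenerate and is rejected with the offending
#' level named.
#'
#' @param counts A matrix or data frame of non-negative cell counts;
#'   rows are attribute levels, columns exposure groups.
#' @return A one-row tibble: `statistic`, `df`, `p_value`,
#'   `continuity_corrected`.
#' @examples
#' pearson_chi2(rbind(c(20, 10), c(15, 30)))
#' @export
pearson_chi2 <- function(counts) {
  m <- as.matrix(counts)
  if (!is.numeric(m) || any(m < 0) || anyNA(m)) {
    abort("`counts` must be a matrix of non-negative counts.")
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("`counts` must be at least 2 x 2.")
  }
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0)) {
    lvl <- rownames(m)[which(rs == 0)[1]] %||% which(rs == 0)[1]
    abort(sprintf("Row margin is zero for level '%s'.", lvl))
  }
  if (any(cs == 0)) {
    lvl <- colnames(m)[which(cs == 0)[1]] %||% which(cs == 0)[1]
    abort(sprintf("Column margin is zero for level '%s'.", lvl))
  }
  correct <- nrow(m) == 2 && ncol(m) == 2
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    continuity_corrected = correct
  )
}

#' Bivariate association report, one chi-square per attribute
#'
#' Cross-tabulates each categorical attribute against a binary (or
#' multi-level) exposure column, reporting cell counts with column
#' percentages and the Pearson chi-square per attribute — the claims-table
#' style of descriptive reporting. Attributes with a single observed level
#' are skipped with a warning.
#'
#' @param rows Analysis-row tibble.
#' @param attributes Character vector of column names to cross-tabulate.
#' @param exposure Name of the exposure column.
#' @return Tibble with one row per attribute level and exposure group:
#'   `attribute`, `level`, `exposure_group`, `n`, `pct` (column percent),
#'   plus per-attribute `statistic`, `df`, `p_value`.
#' @export
bivariate_report <- function(rows, attributes, exposure) {
  stopifnot(is.data.frame(rows), exposure %in% names(rows))
  out <- purrr::map(attributes, function(a) {
    if (!a %in% names(rows)) abort(sprintf("No column `%s` in `rows`.", a))
    tab <- table(rows[[a]], rows[[exposure]])
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2) {
      warn(sprintf("Skipping attribute `%s`: fewer than 2 observed levels.",
                   a))
      return(NULL)
    }
    chi <- pearson_chi2(tab)
    as_tibble(as.data.frame(tab, stringsAsFactors = FALSE)) |>
      stats::setNames(c("level", "exposure_group", "n")) |>
      dplyr::group_by(.data$exposure_group) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::mutate(attribute = a, statistic = chi$statistic, df = chi$df,
                    p_value = chi$p_value) |>
      dplyr::relocate("attribute")
  })
  dplyr::bind_rows(out)
}

#' Hierarchical logistic regression with cross-classified random
#' intercepts
#'
#' Fits `delayed ~ exposures + covariates + (1 | surgeon) + (1 | HRR)` by
#' Laplace-approximate maximum likelihood: the two grouping factors are
#' crossed, not nested — a surgeon's patients span HRRs and an HRR holds
#' many surgeons — and each contributes an additive random intercept on
#' the log-odds scale. Reference levels are non-linchpin and low care
#' density, so exponentiated coefficients are the delay odds ratios for
#' linchpin exposure and for medium/high/sole-clinician care density
#' against low. Wald 95% intervals on the log-odds scale are
#' exponentiated.
#'
#' The outcome is re-derived from `interval_days` at the requested
#' `cutoff`, so the same rows serve the primary (60-day) and sensitivity
#' (90-day) analyses. Covariates with fewer than 2 observed levels are
#' dropped silently from the formula; a degenerate outcome (all delayed or
#' none) is an error. Non-convergence is reported in the result, never
#' hidden.
#'
#' @param rows Analysis-row tibble from [assemble_analysis_rows()] (one
#'   cohort), or any tibble with `interval_days`, `linchpin_exposed`,
#'   `care_density_level`, `surgeon_id`, `hrr` and the covariate columns.
#' @param cutoff Delay cutoff in days (60).
#' @param covariates Character vector of adjustment columns; default all
#'   standard study covariates present in `rows`. Use `character()` for an
#'   exposures-only model.
#' @param backend Estimation backend; `"glmer"` (lme4, Laplace) is the
#'   implemented strategy and is recorded in the result.
#' @return Object of class `psnet_fit`; see [tidy.psnet_fit()] and
#'   [glance.psnet_fit()].
#' @export
fit_delay_model <- function(rows, cutoff = 60, covariates = NULL,
                            backend = c("glmer")) {
  backend <- match.arg(backend)
  stopifnot(is.data.frame(rows))
  need <- c("interval_days", "linchpin_exposed", "care_density_level",
            "surgeon_id", "hrr")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0) {
    abort(sprintf("`rows` lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  std_covars <- c("age_group", "race_ethnicity", "comorbidity_bin",
                  "deprivation_bin", "patient_rurality",
                  "nci_affiliated_surgery", "encounter_count",
                  "surgeon_volume_bin", "surgeon_rurality", "supply_bin",
                  "within_hsa_bin", "between_hsa_bin", "surgeon_gender")
  covariates <- covariates %||% intersect(std_covars, names(rows))

  d <- rows
  d$delayed <- delay_flag(d$interval_days, cutoff)
  if (length(unique(d$delayed)) < 2) {
    abort(sprintf(
      "Degenerate outcome: every patient is on the same side of the %d-day cutoff.",
      cutoff
    ))
  }
  d$care_density_level <- droplevels(factor(d$care_density_level))
  if ("low" %in% levels(d$care_density_level)) {
    d$care_density_level <- stats::relevel(d$care_density_level, ref = "low")
  }
  d$surgeon_id <- factor(d$surgeon_id)
  d$hrr <- factor(d$hrr)
  if (nlevels(d$surgeon_id) < 2 || nlevels(d$hrr) < 2) {
    abort("Each random factor needs at least 2 levels.")
  }

  usable <- vapply(covariates, function(v) {
    x <- d[[v]]
    if (is.numeric(x)) stats::var(x, na.rm = TRUE) > 0
    else length(unique(x[!is.na(x)])) >= 2
  }, logical(1))
  covariates <- covariates[usable]

  fixed <- c("linchpin_exposed", "care_density_level", covariates)
  fml <- stats::as.formula(paste(
    "delayed ~", paste(fixed, collapse = " + "),
    "+ (1 | surgeon_id) + (1 | hrr)"
  ))
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::glmer(fml, data = d, family = binomial(),
                control = lme4::glmerControl(
                  optimizer = "bobyqa",
                  optCtrl = list(maxfun = 100000))),
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  singular <- lme4::isSingular(fit)
  opt_msgs <- fit@optinfo$conv$lme4$messages %||% character()
  # a boundary (singular) fit is a zero variance estimate, not a failure
  converged <- length(setdiff(opt_msgs, grep("singular", opt_msgs,
                                             value = TRUE))) == 0

  co <- summary(fit)$coefficients
  z <- qnorm(0.975)
  est <- unname(co[, "Estimate"])
  se <- unname(co[, "Std. Error"])
  tidy_tab <- tibble(
    term = rownames(co),
    estimate = est,
    std_error = se,
    statistic = unname(co[, "z value"]),
    p_value = unname(co[, "Pr(>|z|)"]),
    odds_ratio = exp(est),
    conf_low = exp(est - z * se),
    conf_high = exp(est + z * se)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_of <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v) == 0) 0 else v[1]
  }

  structure(
    list(
      model = fit,
      coefficients = tidy_tab,
      var_npi = var_of("surgeon_id"),
      var_hrr = var_of("hrr"),
      cutoff = cutoff,
      nobs = nrow(d),
      n_surgeons = nlevels(d$surgeon_id),
      n_hrr = nlevels(d$hrr),
      converged = converged,
      singular = singular,
      messages = unique(c(msgs, opt_msgs)),
      backend = "lme4::glmer (Laplace approximate ML)",
      formula = fml
    ),
    class = "psnet_fit"
  )
}

#' Refit the delay model at the sensitivity cutoff
#'
#' Identical model with the outcome re-derived at `cutoff` (default the
#' 90-day sensitivity definition); intended to be reported side by side
#' with the 60-day primary fit.
#'
#' @inheritParams fit_delay_model
#' @export
sensitivity_rerun <- function(rows, cutoff = 90, covariates = NULL) {
  fit_delay_model(rows, cutoff = cutoff, covariates = covariates)
}

#' @export
print.psnet_fit <- function(x, ...) {
  cat(sprintf(
    "<psnet_fit> %s; n = %d, cutoff > %g days%s\n",
    x$backend, x$nobs, x$cutoff,
    paste0(if (x$singular) " [singular fit: a variance component is 0]",
           if (!x$converged) " [DID NOT CONVERGE]")
  ))
  cat(sprintf("  random-intercept variances: surgeon %.4f, HRR %.4f\n",
              x$var_npi, x$var_hrr))
  main <- dplyr::filter(
    x$coefficients,
    grepl("^linchpin_exposed|^care_density_level", .data$term)
  )
  for (i in seq_len(nrow(main))) {
    cat(sprintf("  %-32s OR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
                main$term[i], main$odds_ratio[i], main$conf_low[i],
                main$conf_high[i], main$p_value[i]))
  }
  invisible(x)
}

#' Tidy the fitted delay model
#'
#' One row per fixed-effect term with log-odds estimate, Wald standard
#' error, p-value, and the exponentiated odds ratio with its 95% CI.
#'
#' @param x A `psnet_fit`.
#' @param ... Unused.
#' @method tidy psnet_fit
#' @export
tidy.psnet_fit <- function(x, ...) {
  x$coefficients
}

#' One-row model summary
#'
#' Sample size, cluster counts, random-intercept variance components,
#' log-likelihood, convergence flag and estimation backend.
#'
#' @param x A `psnet_fit`.
#' @param ... Unused.
#' @method glance psnet_fit
#' @export
glance.psnet_fit <- function(x, ...) {
  ll <- as.numeric(stats::logLik(x$model))
  tibble(
    nobs = x$nobs, n_surgeons = x$n_surgeons, n_hrr = x$n_hrr,
    cutoff = x$cutoff, var_npi = x$var_npi, var_hrr = x$var_hrr,
    log_lik = ll, aic = stats::AIC(x$model),
    converged = x$converged, singular = x$singular, backend = x$backend
  )
}

#' Write a machine-readable model report
#'
#' One row per coefficient (term, OR, CI bounds, p) as tab-separated
#' text, mirroring an adjusted-associations table.
#'
#' @param fit A `psnet_fit`.
#' @param path Output file.
#' @export
write_model_report <- function(fit, path) {
  stopifnot(inherits(fit, "psnet_fit"))
  utils::write.table(tidy(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
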