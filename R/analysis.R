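#' Center level-1 predictors within cluster
#'
#' Subtracts each participant's own mean from the listed columns, so every
#' cluster mean is exactly zero — the usual preparation of level-1
#' predictors for a random-intercept model.  Idempotent.
#'
#' @param table Long-format data frame.
#' @param columns Character vector of numeric columns to center.
#' @param cluster Name of the cluster id column (default
#'   `"participant_id"`).
#' @return The table with the listed columns centered.
#' @export
center_within_cluster <- function(table, columns,
                                  cluster = "participant_id") {
  stopifnot(cluster %in% names(table), all(columns %in% names(table)))
  for (cl in columns) {
    means <- stats::ave(table[[cl]], table[[cluster]],
                        FUN = function(x) mean(x, na.rm = TRUE))
    if (any(is.nan(means))) {
      stop("degenerate cluster: column '", cl,
           "' is all-missing within some cluster", call. = FALSE)
    }
    table[[cl]] <- table[[cl]] - means
  }
  table
}

# Nakagawa marginal/conditional R2 for a random-intercept lmer fit
r2_mixed <- function(fit) {
  vf <- stats::var(as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vr <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"])
  ve <- stats::sigma(fit)^2
  c(marginal = vf / (vf + vr + ve), conditional = (vf + vr) / (vf + vr + ve))
}

#' Fit the SV-prediction multilevel model
#'
#' Random-intercept linear mixed model of subjective value on
#' within-cluster-centered level-1 predictors, fitted by REML with
#' Satterthwaite degrees of freedom:
#' `sv ~ effort + arousal + utility + corrugator + levator + (1 | subject)`.
#' Optional level-2 covariates (e.g. self-control, NFC) are appended as
#' fixed effects.  The intraclass correlation is taken from the null
#' (intercept-only) model on the same rows.
#'
#' @param table Long-format study table (one row per trial or per
#'   strategy) with an `sv` column and the predictor columns.
#' @param predictors Character vector of level-1 predictor columns; they
#'   are centered within cluster before fitting.
#' @param level2_predictors Optional character vector of subject-level
#'   covariate columns (grand-mean centered before fitting).
#' @param cluster Cluster id column.
#' @param compute_f2 Compute per-predictor f2 effect sizes (one model refit
#'   per predictor); disable in large replicate loops.
#' @return An `mlm_result` list: `fixed_effects` (estimate, SE,
#'   Satterthwaite df, t, p per term), `random_intercept_sd`,
#'   `residual_sd`, `icc` (null model), `r2_marginal`, `r2_conditional`,
#'   `f2` (per predictor, from marginal R-squared), `singular` flag,
#'   `df_method`, and the underlying `fit`.
#' @export
fit_sv_mlm <- function(table, predictors = c("effort", "arousal", "utility",
                                             "corrugator", "levator"),
                       level2_predictors = character(0),
                       cluster = "participant_id", compute_f2 = TRUE) {
  stopifnot("sv" %in% names(table))
  tab <- center_within_cluster(table, predictors, cluster)
  for (l2 in level2_predictors) {
    tab[[l2]] <- tab[[l2]] - mean(tab[[l2]], na.rm = TRUE)
  }
  all_pred <- c(predictors, level2_predictors)
  form <- stats::as.formula(paste(
    "sv ~", paste(all_pred, collapse = " + "), "+ (1 |", cluster, ")"))
  fit <- lmerTest::lmer(form, data = tab, REML = TRUE)
  null_fit <- lme4::lmer(stats::as.formula(paste("sv ~ 1 + (1 |", cluster, ")")),
                         data = tab, REML = TRUE)
  vc0 <- as.data.frame(lme4::VarCorr(null_fit))
  icc <- vc0$vcov[1] / sum(vc0$vcov)
  coefs <- stats::coef(summary(fit))
  fixed <- data.frame(
    term = rownames(coefs), estimate = coefs[, "Estimate"],
    se = coefs[, "Std. Error"], df = coefs[, "df"],
    t = coefs[, "t value"], p = coefs[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  r2 <- r2_mixed(fit)
  f2 <- if (compute_f2) {
    stats::setNames(
      vapply(all_pred, function(p) effect_size_f2(fit, p, tab)["f2"], 0),
      all_pred)
  } else NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(fixed_effects = fixed,
         random_intercept_sd = sqrt(vc$vcov[vc$grp == cluster][1]),
         residual_sd = stats::sigma(fit),
         icc = icc, r2_marginal = unname(r2["marginal"]),
         r2_conditional = unname(r2["conditional"]),
         f2 = f2, singular = lme4::isSingular(fit),
         df_method = "Satterthwaite", fit = fit),
    class = "mlm_result"
  )
}

#' Local effect size f2 of one predictor in a mixed model
#'
#' Refits the model without the predictor and computes
#' `f2 = (R2_full - R2_reduced) / (1 - R2_full)` on the marginal
#' (fixed-effects) R-squared.  `f2` is zero exactly when the two
#' R-squared values coincide.
#'
#' @param fit A fitted `lmerMod`/`lmerModLmerTest`, or an `mlm_result`.
#' @param predictor Fixed-effect term to drop.
#' @param data Data used for the fit (defaults to the model frame).
#' @return Named numeric `c(f2 =, delta_r2 =)`.
#' @export
effect_size_f2 <- function(fit, predictor, data = NULL) {
  if (inherits(fit, "mlm_result")) fit <- fit$fit
  if (is.null(data)) data <- stats::model.frame(fit)
  reduced <- stats::update(fit, stats::as.formula(paste(". ~ . -", predictor)),
                           data = data, evaluate = TRUE)
  r2f <- r2_mixed(fit)["marginal"]
  r2r <- r2_mixed(reduced)["marginal"]
  if (r2f == r2r) return(c(f2 = 0, delta_r2 = 0))
  c(f2 = unname((r2f - r2r) / (1 - r2f)), delta_r2 = unname(r2f - r2r))
}

#' One-factor repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Complete within-subject design: the univariate repeated-measures F test
#' from the subject/condition/error sum-of-squares decomposition, Mauchly's
#' sphericity test, Greenhouse-Geisser epsilon applied to both degrees of
#' freedom, generalized and partial eta squared, and pairwise post-hoc
#' paired-t contrasts with Tukey or Bonferroni adjustment.  A flat outcome
#' (no condition or error variance) reports `F = 0`; degenerate covariance
#' leaves the sphericity p-value `NA`.
#'
#' @param table Long data frame.
#' @param dv Name of the outcome column.
#' @param within Name of the within-subject factor column.
#' @param id Name of the subject id column.
#' @param adjust `"tukey"` (default) or `"bonferroni"` for the post-hoc
#'   contrasts.
#' @return An `anova_result` list: `F`, `df_num`, `df_den` (uncorrected),
#'   `df_num_gg`, `df_den_gg`, `epsilon`, `p` (uncorrected), `p_gg`,
#'   `mauchly_p`, `eta2_generalized`, `eta2_partial`, and `contrasts`
#'   (pairwise t, raw and adjusted p).
#' @export
rm_anova <- function(table, dv, within, id = "participant_id",
                     adjust = c("tukey", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c(dv, within, id) %in% names(table)))
  wide <- stats::reshape(
    table[, c(id, within, dv)], direction = "wide",
    idvar = id, timevar = within, v.names = dv
  )
  y <- as.matrix(wide[, -1, drop = FALSE])
  colnames(y) <- sub(paste0("^", dv, "\\."), "", colnames(y))
  if (anyNA(y)) stop("unbalanced input: incomplete within-subject design",
                     call. = FALSE)
  k <- ncol(y); n <- nrow(y)
  grand <- mean(y)
  ss_eff <- n * sum((colMeans(y) - grand)^2)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_err <- sum((y - grand)^2) - ss_eff - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fval <- if (ss_eff == 0) 0 else (ss_eff / df1) / (ss_err / df2)
  p_unc <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  if (k > 2) {
    # Greenhouse-Geisser epsilon from the condition covariance matrix
    S <- stats::cov(y)
    sbar <- mean(diag(S)); mbar <- mean(S)
    rowm <- rowMeans(S)
    denom <- (k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * mbar^2)
    eps <- if (denom == 0) 1 else (k * (sbar - mbar))^2 / denom
    eps <- min(max(eps, 1 / (k - 1)), 1)
    p_gg <- stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE)
    # Mauchly's sphericity test on the within-subject contrasts
    mauchly_p <- tryCatch(
      stats::mauchly.test(stats::lm(y ~ 1), X = ~1)$p.value,
      error = function(e) NA_real_)
  } else {
    eps <- 1; p_gg <- p_unc; mauchly_p <- NA_real_
  }
  # post-hoc pairwise paired t contrasts
  combs <- utils::combn(colnames(y), 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
    a <- combs[1, j]; b <- combs[2, j]
    d <- y[, a] - y[, b]
    tt <- stats::t.test(d)
    data.frame(contrast = paste(a, "-", b), estimate = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  contrasts$p_adj <- if (adjust == "bonferroni") {
    stats::p.adjust(contrasts$p, "bonferroni")
  } else {
    stats::ptukey(abs(contrasts$t) * sqrt(2), nmeans = k, df = n - 1,
                  lower.tail = FALSE)
  }
  structure(
    list(F = unname(Fval), df_num = k - 1, df_den = (k - 1) * (n - 1),
         df_num_gg = unname((k - 1) * eps), df_den_gg = unname((k - 1) * (n - 1) * eps),
         epsilon = unname(eps), p = unname(p_unc), p_gg = unname(p_gg),
         mauchly_p = unname(mauchly_p),
         eta2_generalized = unname(ss_eff / (ss_eff + ss_subj + ss_err)),
         eta2_partial = unname(ss_eff / (ss_eff + ss_err)),
         adjust = adjust, contrasts = contrasts),
    class = "anova_result"
  )
}

#' Chi-square association between predicted and actual strategy choice
#'
#' Pearson chi-square on the 3 x 3 contingency table of the predicted
#' (highest-SV) against the actually chosen strategy.  Strategy levels
#' absent from both margins are kept as structural zeros (their cells
#' contribute 0), so the table stays 3 x 3 and df = 4.
#'
#' @param predicted,actual Character vectors of strategy labels.
#' @return List with `chi2`, `df`, `p` and the `contingency` table.
#' @export
predicted_vs_actual_chi2 <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), length(predicted) >= 1)
  assert_strategy(predicted); assert_strategy(actual)
  lv <- strategies()
  tab <- table(factor(predicted, levels = lv), factor(actual, levels = lv))
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  cells <- ifelse(expd > 0, (tab - expd)^2 / expd, 0)
  chi2 <- sum(cells)
  df <- (length(lv) - 1)^2
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       contingency = tab)
}

#' Ordinal (or multinomial) regression of strategy choice on SVs
#'
#' Proportional-odds model of the chosen strategy — ordered by the
#' canonical strategy order, since choice carries no intrinsic order — on
#' the three per-strategy SVs, with a multinomial alternative.
#' McFadden's pseudo R-squared is reported; quasi-separation or
#' collinearity (degenerate SVs, exploding coefficients, or an unsolvable
#' Hessian) raises a `separation` flag rather than an error.
#'
#' @param profile_table Data frame from [sv_profile_table()] (columns
#'   `sv_distancing`, `sv_distraction`, `sv_suppression`).
#' @param actual Character vector of actually chosen strategies.
#' @param mode `"ordinal"` (default) or `"multinomial"`.
#' @return List with `coefficients` (estimate, SE, odds ratio), `mode`,
#'   `pseudo_r2`, `separation` flag and the underlying `fit`.
#' @export
ordinal_choice_model <- function(profile_table, actual,
                                 mode = c("ordinal", "multinomial")) {
  mode <- match.arg(mode)
  assert_strategy(actual)
  dat <- data.frame(
    choice = factor(actual, levels = strategies(), ordered = mode == "ordinal"),
    sv_distancing = profile_table$sv_distancing,
    sv_distraction = profile_table$sv_distraction,
    sv_suppression = profile_table$sv_suppression
  )
  svs <- dat[, -1]
  degenerate <- any(vapply(svs, function(x) stats::var(x) == 0, TRUE))
  separation <- degenerate
  form <- choice ~ sv_distancing + sv_distraction + sv_suppression
  fit <- NULL; coefs <- NULL; pseudo_r2 <- NA_real_
  res <- withCallingHandlers(
    tryCatch({
      if (mode == "ordinal") {
        fit <- MASS::polr(form, data = dat, Hess = TRUE)
        est <- stats::coef(fit)
        se <- tryCatch(sqrt(diag(stats::vcov(fit)))[names(est)],
                       error = function(e) {
                         separation <<- TRUE
                         rep(NA_real_, length(est))
                       })
        ll <- stats::logLik(fit)
        null_fit <- MASS::polr(choice ~ 1, data = dat)
        pseudo_r2 <- 1 - as.numeric(ll) / as.numeric(stats::logLik(null_fit))
      } else {
        fit <- nnet::multinom(form, data = dat, trace = FALSE)
        est <- stats::coef(fit)
        se <- summary(fit)$standard.errors
        null_fit <- nnet::multinom(choice ~ 1, data = dat, trace = FALSE)
        pseudo_r2 <- 1 - as.numeric(stats::logLik(fit)) /
          as.numeric(stats::logLik(null_fit))
      }
      list(est = est, se = se)
    }, error = function(e) {
      separation <<- TRUE
      NULL
    }),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (!is.null(res)) {
    if (is.matrix(res$est)) {
      coefs <- data.frame(
        outcome = rep(rownames(res$est), ncol(res$est)),
        term = rep(colnames(res$est), each = nrow(res$est)),
        estimate = as.vector(res$est), se = as.vector(res$se),
        odds_ratio = exp(as.vector(res$est)), stringsAsFactors = FALSE
      )
    } else {
      coefs <- data.frame(
        term = names(res$est), estimate = unname(res$est),
        se = unname(res$se), odds_ratio = exp(unname(res$est)),
        stringsAsFactors = FALSE
      )
    }
    if (any(abs(coefs$estimate) > 20, na.rm = TRUE)) separation <- TRUE
  }
  if (separation) {
    warning("separation or degenerate predictors detected; ",
            "coefficients (if any) are unreliable", call. = FALSE)
  }
  list(coefficients = coefs, mode = mode, pseudo_r2 = pseudo_r2,
       separation = separation, fit = fit)
}

#' Regression of the FlexER score on ordered-SV intercept and slope
#'
#' Ordinary least squares of a participant-level flexibility score on the
#' intercept (overall strategy valuation) and slope (preference steepness)
#' of the ordered-SV fit, with coefficient confidence intervals.
#'
#' @param profile_table Data frame from [sv_profile_table()].
#' @param flexer Numeric score vector, one per participant.
#' @param conf_level Confidence level for the coefficient intervals.
#' @return List with `coefficients` (estimate, SE, t, p, CI bounds), `r2`,
#'   `F`, `df`, `p` and the underlying `fit`.
#' @export
flexer_regression <- function(profile_table, flexer, conf_level = 0.95) {
  n <- nrow(profile_table)
  stopifnot(length(flexer) == n)
  if (n <= 3) stop("insufficient data: need more than 3 participants",
                   call. = FALSE)
  dat <- data.frame(flexer = flexer,
                    intercept = profile_table$intercept,
                    slope = profile_table$slope)
  fit <- stats::lm(flexer ~ intercept + slope, data = dat)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  cf <- stats::coef(sm)
  coefs <- data.frame(
    term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
    t = cf[, 3], p = cf[, 4],
    ci_lower = ci[, 1], ci_upper = ci[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  fstat <- sm$fstatistic
  list(coefficients = coefs, r2 = sm$r.squared,
       F = unname(fstat[1]), df = unname(fstat[2:3]),
       p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       fit = fit)
}

#' Run the full analysis pipeline on a generated or loaded study
#'
#' Convenience wrapper: manipulation-check rmANOVAs on the block ratings,
#' the SV multilevel model (with and without level-2 covariates), the
#' predicted-versus-actual choice chi-square, the ordinal choice model and
#' the flexibility regression.  Bayes factors are not computed.
#'
#' @param study Output of [generate_study()], or a list with the same
#'   `study`, `ratings` and `profile_table` components.
#' @param adjust Post-hoc adjustment for the rmANOVAs.
#' @return An `analysis_bundle` list of the individual results.
#' @export
analyze_study <- function(study, adjust = c("tukey", "bonferroni")) {
  adjust <- match.arg(adjust)
  ptab <- study$profile_table
  reg <- study$ratings[study$ratings$condition %in%
                         c("view_neg", strategies()), ]
  mlm <- fit_sv_mlm(study$study)
  mlm_l2 <- fit_sv_mlm(study$study,
                       level2_predictors = c("self_control", "nfc"))
  per_p <- study$study[!duplicated(study$study$participant_id), ]
  list(
    anova_arousal = rm_anova(reg, "arousal", "condition", adjust = adjust),
    anova_effort = rm_anova(reg, "effort", "condition", adjust = adjust),
    anova_corrugator = rm_anova(reg, "corrugator", "condition", adjust = adjust),
    mlm = mlm, mlm_level2 = mlm_l2,
    choice_chi2 = predicted_vs_actual_chi2(ptab$predicted_choice,
                                           per_p$actual_choice),
    choice_model = ordinal_choice_model(ptab, per_p$actual_choice),
    flexer = flexer_regression(ptab, per_p$flexer),
    note = "Bayes factors are not computed by this pipeline"
  )
}
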