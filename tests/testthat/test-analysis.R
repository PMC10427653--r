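test_that("within-cluster centering zeroes every cluster mean and is idempotent", {
  tab <- data.frame(participant_id = c("a", "a", "a", "b", "b"),
                    x = c(1, 2, 3, 10, 20))
  c1 <- center_within_cluster(tab, "x")
  expect_equal(c1$x[1:3], c(-1, 0, 1))
  means <- tapply(c1$x, c1$participant_id, mean)
  expect_true(all(abs(means) < 1e-12))
  c2 <- center_within_cluster(c1, "x")
  expect_equal(c1, c2)
  tab$x[4:5] <- NA
  expect_error(center_within_cluster(tab, "x"), "degenerate cluster")
})

test_that("the mixed model reduces to OLS when subjects carry no variance", {
  withr::with_seed(10, {
    n <- 40
    tab <- data.frame(
      participant_id = rep(paste0("p", 1:n), each = 3),
      effort = rnorm(3 * n, 0, 1), arousal = rnorm(3 * n),
      utility = rnorm(3 * n), corrugator = rnorm(3 * n),
      levator = rnorm(3 * n)
    )
  })
  # build the outcome from the *within-cluster centered* predictors so no
  # between-subject signal (and hence no subject variance) exists
  cc <- center_within_cluster(tab, c("effort", "utility"))
  withr::with_seed(11, {
    tab$sv <- 0.8 - 0.1 * cc$effort + 0.2 * cc$utility + rnorm(3 * n, 0, 0.05)
  })
  suppressMessages({
    m <- fit_sv_mlm(tab, compute_f2 = FALSE)
  })
  ctab <- center_within_cluster(tab, c("effort", "arousal", "utility",
                                       "corrugator", "levator"))
  ols <- lm(sv ~ effort + arousal + utility + corrugator + levator,
            data = ctab)
  expect_equal(m$fixed_effects$estimate, unname(coef(ols)), tolerance = 1e-6)
  # essentially no subject variance is attributed
  expect_lt(m$random_intercept_sd, 0.02)
})

test_that("mixed-model recovery on generated studies finds the planted signs", {
  st <- generate_study(study_config(n = 60), seed = 77)
  m <- fit_sv_mlm(st$study)
  fe <- m$fixed_effects
  expect_lt(fe$estimate[fe$term == "effort"], 0)
  expect_gt(fe$estimate[fe$term == "utility"], 0)
  expect_lt(fe$p[fe$term == "utility"], 0.001)
  expect_gt(m$r2_conditional, m$r2_marginal)
  expect_true(m$icc >= 0 && m$icc <= 1)
  # f2 from marginal R2: utility planted strongest
  expect_gt(m$f2[["utility"]], m$f2[["arousal"]])
})

test_that("level-2 covariates join the model as fixed effects", {
  st <- generate_study(study_config(n = 50), seed = 14)
  m <- fit_sv_mlm(st$study, level2_predictors = c("self_control", "nfc"))
  expect_true(all(c("self_control", "nfc") %in% m$fixed_effects$term))
  # the generator links self-control to the subject intercept positively
  expect_gt(m$fixed_effects$estimate[m$fixed_effects$term == "self_control"], 0)
})

test_that("f2 is zero exactly when full and reduced R2 coincide", {
  st <- generate_study(study_config(n = 20), seed = 6)
  m <- fit_sv_mlm(st$study, predictors = c("effort", "utility"),
                  compute_f2 = FALSE)
  f2 <- effect_size_f2(m, "effort")
  expect_gte(f2[["f2"]], 0)
  r2f <- m$r2_marginal
  red <- fit_sv_mlm(st$study, predictors = "utility", compute_f2 = FALSE)
  expect_equal(f2[["f2"]], (r2f - red$r2_marginal) / (1 - r2f),
               tolerance = 1e-6)
})

test_that("rmANOVA matches the hand-computed oracle to six decimals", {
  res <- rm_anova(rm_fixture(), "value", "condition")
  expect_equal(res$F, 25.7142857143, tolerance = 1e-6)
  expect_equal(res$epsilon, 0.6966824645, tolerance = 1e-6)
  expect_equal(res$df_num_gg, 1.3933649289, tolerance = 1e-6)
  expect_equal(res$df_den_gg, 5.5734597156, tolerance = 1e-6)
  expect_equal(res$p, 0.000328381578026, tolerance = 1e-6)
  expect_equal(res$p_gg, 0.00209297462454, tolerance = 1e-6)
  expect_equal(res$eta2_generalized, 0.4253308129, tolerance = 1e-6)
  expect_equal(res$eta2_partial, 0.8653846154, tolerance = 1e-6)
})

test_that("a two-level within factor reduces to the squared paired t-test", {
  tab <- rm_fixture()
  tab <- tab[tab$condition != "c3", ]
  res <- rm_anova(tab, "value", "condition")
  wide <- reshape(tab, direction = "wide", idvar = "participant_id",
                  timevar = "condition")
  tt <- t.test(wide$value.c1, wide$value.c2, paired = TRUE)
  expect_equal(res$epsilon, 1)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("a flat outcome yields F = 0 and incomplete designs are rejected", {
  tab <- rm_fixture()
  tab$value <- rep(c(3, 5, 9, 2, 4), each = 3)  # constant within subject
  res <- rm_anova(tab, "value", "condition")
  expect_equal(res$F, 0)
  expect_error(rm_anova(rm_fixture()[-1, ], "value", "condition"),
               "unbalanced")
})

test_that("post-hoc contrasts support Tukey and Bonferroni adjustment", {
  res_t <- rm_anova(rm_fixture(), "value", "condition", adjust = "tukey")
  res_b <- rm_anova(rm_fixture(), "value", "condition", adjust = "bonferroni")
  expect_equal(nrow(res_t$contrasts), 3)
  expect_equal(res_b$contrasts$p_adj, pmin(res_b$contrasts$p * 3, 1))
  expect_true(all(res_t$contrasts$p_adj >= res_t$contrasts$p - 1e-12))
})

test_that("the choice chi-square matches its closed forms and textbook oracle", {
  # perfect diagonal, balanced: chi2 = 2 n, df = 4
  n_per <- 10
  pred <- rep(strategies(), each = n_per)
  res <- predicted_vs_actual_chi2(pred, pred)
  expect_equal(res$chi2, 2 * 3 * n_per)
  expect_equal(res$df, 4)
  # independence-exact table: chi2 = 0
  pred2 <- rep(strategies(), each = 9)
  act2 <- rep(rep(strategies(), times = 3), each = 3)
  res2 <- predicted_vs_actual_chi2(pred2, act2)
  expect_equal(res2$chi2, 0)
  # agreement with stats::chisq.test when margins are positive
  withr::with_seed(2, {
    pred3 <- sample(strategies(), 60, replace = TRUE)
    act3 <- sample(strategies(), 60, replace = TRUE)
  })
  res3 <- predicted_vs_actual_chi2(pred3, act3)
  ref <- suppressWarnings(chisq.test(table(pred3, act3), correct = FALSE))
  expect_equal(res3$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res3$p, ref$p.value, tolerance = 1e-12)
  # a level absent from both margins stays a structural zero
  res4 <- predicted_vs_actual_chi2(rep(c("distancing", "distraction"), 5),
                                   rep(c("distancing", "distraction"), 5))
  expect_equal(dim(res4$contingency), c(3L, 3L))
  expect_equal(res4$df, 4)
  expect_true(is.finite(res4$chi2))
})

test_that("the choice model finds positive own-SV effects on a clean cohort", {
  st <- generate_study(study_config(n = 120, choice_agreement = 0.85),
                       seed = 19)
  per_p <- st$study[!duplicated(st$study$participant_id), ]
  res <- ordinal_choice_model(st$profile_table, per_p$actual_choice,
                              mode = "multinomial")
  expect_false(res$separation)
  expect_gt(res$pseudo_r2, 0)
  co <- res$coefficients
  # own-SV coefficients (relative to the distancing baseline): the odds of
  # choosing a strategy rise with its own SV
  own_distr <- co$estimate[co$outcome == "distraction" &
                             co$term == "sv_distraction"]
  own_supp <- co$estimate[co$outcome == "suppression" &
                            co$term == "sv_suppression"]
  expect_gt(own_distr, 0)
  expect_gt(own_supp, 0)
  # ordinal mode runs and reports a pseudo R2
  res_ord <- ordinal_choice_model(st$profile_table, per_p$actual_choice)
  expect_equal(res_ord$mode, "ordinal")
  expect_true(is.finite(res_ord$pseudo_r2))
})

test_that("constant SVs raise the separation/degeneracy flag", {
  ptab <- data.frame(sv_distancing = rep(0.5, 30),
                     sv_distraction = rep(0.5, 30),
                     sv_suppression = rep(0.5, 30))
  act <- rep(strategies(), each = 10)
  expect_warning(res <- ordinal_choice_model(ptab, act), "separation|degenerate")
  expect_true(res$separation)
})

test_that("the flexibility regression recovers planted coefficients and fits", {
  withr::with_seed(33, {
    n <- 120
    ptab <- data.frame(intercept = runif(n, 0.4, 1),
                       slope = -runif(n, 0, 0.5))
    flexer <- 2 * ptab$intercept + rnorm(n, 0, 0.2)
  })
  res <- flexer_regression(ptab, flexer)
  ci <- res$coefficients[res$coefficients$term == "intercept", ]
  expect_true(ci$ci_lower < 2 && 2 < ci$ci_upper)
  # perfect linear relation
  suppressWarnings(
    res2 <- flexer_regression(ptab, 1 + 3 * ptab$intercept - 2 * ptab$slope))
  expect_equal(res2$r2, 1)
  expect_error(flexer_regression(ptab[1:3, ], flexer[1:3]), "insufficient")
})

test_that("the full pipeline wrapper runs end to end on a generated study", {
  st <- generate_study(study_config(n = 24), seed = 55)
  suppressWarnings(res <- analyze_study(st))
  expect_true(inherits(res$mlm$fit, "lmerMod"))
  expect_equal(res$choice_chi2$df, 4)
  expect_true(res$anova_effort$F > 0)
  expect_match(res$note, "Bayes factors")
})

test_that("rmANOVA agrees with the multivariate-lm route on random designs", {
  withr::with_seed(44, {
    for (rep in 1:3) {
      n <- 8; k <- 4
      y <- matrix(rnorm(n * k, mean = rep(c(0, 0.5, 1, 0.2), each = n)), n, k)
      tab <- data.frame(
        participant_id = rep(paste0("s", 1:n), times = k),
        condition = rep(paste0("c", 1:k), each = n),
        value = as.vector(y)
      )
      res <- rm_anova(tab, "value", "condition")
      mfit <- lm(y ~ 1)
      idata <- data.frame(cond = factor(paste0("c", 1:k)))
      s <- suppressWarnings(
        summary(car::Anova(mfit, idata = idata, idesign = ~cond, type = 3),
                multivariate = FALSE))
      expect_equal(res$F, unname(s$univariate.tests["cond", "F value"]),
                   tolerance = 1e-10)
      expect_equal(res$epsilon, unname(s$pval.adjustments["cond", "GG eps"]),
                   tolerance = 1e-10)
      expect_equal(res$p_gg, unname(s$pval.adjustments["cond", "Pr(>F[GG])"]),
                   tolerance = 1e-10)
      expect_equal(res$mauchly_p,
                   unname(s$sphericity.tests["cond", "p-value"]),
                   tolerance = 1e-8)
    }
  })
})
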