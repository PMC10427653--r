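test_that("invalid configurations are rejected", {
  expect_error(study_config(n = 1), "n must be >= 2")
  expect_error(study_config(sd_resid = -1), "negative SD")
})

test_that("cohort condition means sit within two standard errors of the targets", {
  cf <- study_config(n = 120)
  st <- generate_study(cf, seed = 8)
  for (dim in c("arousal", "effort")) {
    m <- cf$rating_means[[dim]]
    for (cond in names(m)) {
      got <- mean(st$ratings[st$ratings$condition == cond, dim])
      se <- cf$rating_sds[[dim]][[cond]] / sqrt(cf$n)
      expect_lt(abs(got - m[[cond]]), 2 * se + 1e-9,
                label = sprintf("%s/%s mean %.2f vs %.2f", dim, cond, got, m[[cond]]))
    }
  }
})

test_that("a noise-free configuration collapses to identical participants", {
  cf <- study_config(
    n = 4,
    rating_sds = list(
      arousal = c(view_neu = 0, view_neg = 0, distraction = 0,
                  distancing = 0, suppression = 0),
      effort = c(view_neu = 0, view_neg = 0, distraction = 0,
                 distancing = 0, suppression = 0),
      utility = c(distraction = 0, distancing = 0, suppression = 0)),
    emg_sds = list(
      corrugator = c(view_neu = 0, view_neg = 0, distraction = 0,
                     distancing = 0, suppression = 0),
      levator = c(view_neu = 0, view_neg = 0, distraction = 0,
                  distancing = 0, suppression = 0)),
    sd_subject = 0, sd_resid = 0, choice_agreement = 1,
    flexer_weights = c(intercept = 0, slope = 0), self_control_weight = 0)
  st <- generate_study(cf, seed = 2)
  svs <- st$profile_table[, c("sv_distancing", "sv_distraction",
                              "sv_suppression")]
  expect_true(all(vapply(svs, function(x) length(unique(x)) == 1L, TRUE)))
  expect_equal(length(unique(st$study$effort)), 3)  # one value per strategy
})

test_that("study-table SVs are exactly the valuation output of the session logs", {
  st <- generate_study(study_config(n = 12), seed = 5)
  recomputed <- sv_profile_table(lapply(st$sessions, aggregate_svs))
  per_p <- st$study[!duplicated(paste(st$study$participant_id,
                                      st$study$strategy)), ]
  for (s in strategies()) {
    expect_equal(per_p$sv[per_p$strategy == s],
                 recomputed[[paste0("sv_", s)]])
  }
  expect_identical(st$profile_table[, -1], recomputed[, -1])
})

test_that("engine SVs track the generator's target SVs up to staircase quantization", {
  st <- generate_study(study_config(n = 40), seed = 13)
  sv <- as.matrix(st$profile_table[, paste0("sv_", strategies())])
  colnames(sv) <- strategies()
  tgt <- st$truth$target_sv
  for (i in seq_len(nrow(sv))) {
    ord <- order(-tgt[i, ])
    t2 <- min(tgt[i, ord[2]], 0.995)
    t3 <- min(tgt[i, ord[3]], t2)
    expect_equal(unname(sv[i, ord[1]]), 1)
    # staircase quantization bounds per-pairing SV error by 0.03; targets
    # near the representable floor are clamped by the inversion
    if (t2 > 0.55) {
      expect_lt(abs(sv[i, ord[2]] - t2), 0.03 + 1e-9)
    }
    if (t3 > 0.55) {
      expect_lt(abs(sv[i, ord[3]] - t3), 0.03 + 1e-9)
    }
  }
})

test_that("null regression weights yield near-nominal false-positive rates", {
  cf <- study_config(n = 40, weights = c(effort = 0, arousal = 0, utility = 0,
                                         corrugator = 0, levator = 0))
  reps <- 24
  hits <- matrix(0, reps, 2, dimnames = list(NULL, c("effort", "utility")))
  for (r in seq_len(reps)) {
    st <- generate_study(cf, seed = 100 + r)
    # condition-level rows: one observation per rating unit, so the
    # mixed-model t-tests are calibrated under the null
    cl <- collapse_to_condition_level(st$study)
    m <- fit_sv_mlm(cl, compute_f2 = FALSE)
    fe <- m$fixed_effects
    hits[r, ] <- fe$p[match(colnames(hits), fe$term)] < 0.05
  }
  # binomial(24, 0.05): more than 4 rejections has probability < 0.01
  expect_lte(sum(hits[, "effort"]), 4)
  expect_lte(sum(hits[, "utility"]), 4)
})

test_that("condition-level collapse keeps one row per participant and strategy", {
  st <- generate_study(study_config(n = 6), seed = 3)
  cl <- collapse_to_condition_level(st$study)
  expect_equal(nrow(cl), 6 * 3)
  expect_equal(sort(unique(cl$strategy)), strategies())
  one <- cl[cl$participant_id == "p001" & cl$strategy == "distancing", ]
  raw <- st$study[st$study$participant_id == "p001" &
                    st$study$strategy == "distancing", ]
  expect_equal(one$corrugator, mean(raw$corrugator))
  expect_equal(one$sv, raw$sv[1])
})

test_that("without subject variance the null-model ICC vanishes at condition level", {
  for (s in 1:3) {
    st <- generate_study(study_config(n = 60, sd_subject = 0,
                                      self_control_weight = 0), seed = s)
    cl <- collapse_to_condition_level(st$study)
    m <- suppressMessages(fit_sv_mlm(cl, compute_f2 = FALSE))
    expect_lte(m$icc, 0.02)
  }
})
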