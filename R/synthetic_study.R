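#' Configuration of the synthetic study generator
#'
#' Defaults emulate the structure of the original study: 120 participants,
#' 5 blocks (neutral viewing, negative viewing, three regulation
#' strategies) of 20 trials, block-level ratings on a continuous 0-300
#' slider scale with the published condition means/SDs, trial-level facial
#' EMG summaries, questionnaire scores, and subjective values produced by
#' running deterministic agents through the titration engine.
#'
#' Target SVs for the two non-preferred strategies of each participant
#' follow an explicit random-intercept model on the SV scale,
#' `t = mu + b_subject + w'x_centered + e`, whose weights default to the
#' per-slider-unit (and per-mV) associations the generator is meant to
#' plant: negative for effort, positive for utility and corrugator
#' activity, essentially zero for arousal.  The subject-intercept SD
#' default (0.146) was derived by simulating the generator so that the
#' subject share of total trial-level SV variance is `icc_target`.
#'
#' @param n Number of participants (>= 2).
#' @param trials_per_block Trials per block (default 20).
#' @param scale_max Upper bound of the continuous rating slider (default
#'   300; the scale lower bound is 0).
#' @param rating_means,rating_sds Named lists (`arousal`, `effort`,
#'   `utility`) of per-condition means and SDs on the slider scale.
#' @param emg_means,emg_sds Named lists (`corrugator`, `levator`) of
#'   per-condition means and SDs in mV (baseline-corrected trial values).
#' @param rating_subject_share Share of rating/EMG variance placed at the
#'   subject level (0-1).
#' @param weights Named numeric: per-unit weights of centered effort,
#'   arousal, utility, corrugator, levator on the SV targets.
#' @param sv_nontop_mean Mean SV target of a non-preferred strategy.
#' @param sd_subject SD of the subject random intercept on the SV scale.
#' @param sd_resid SD of the strategy-level residual on the SV scale.
#' @param icc_target Nominal subject share of SV variance the defaults aim
#'   at (recorded in the truth bundle; informational).
#' @param choice_agreement Probability that the sampled actual choice
#'   equals the predicted (highest-SV) strategy.
#' @param flexer_weights Numeric `c(intercept, slope)` weights generating
#'   the FlexER score from the ordered-SV fit (default both 0: no
#'   association).
#' @param self_control_weight Weight of the subject SV intercept on the
#'   self-control score (level-2 association).
#' @return A `study_config` list.
#' @export
study_config <- function(n = 120,
                         trials_per_block = 20,
                         scale_max = 300,
                         rating_means = list(
                           arousal = c(view_neu = 26.6, view_neg = 187.8,
                                       distraction = 158.1, distancing = 164,
                                       suppression = 168.6),
                           effort = c(view_neu = 18.1, view_neg = 49.4,
                                      distraction = 208.5, distancing = 189.8,
                                      suppression = 158.3),
                           utility = c(distraction = 216.6, distancing = 214.8,
                                       suppression = 229.3)),
                         rating_sds = list(
                           arousal = c(view_neu = 39.1, view_neg = 87.3,
                                       distraction = 92.5, distancing = 87.2,
                                       suppression = 95.8),
                           effort = c(view_neu = 27.4, view_neg = 62.3,
                                      distraction = 96.1, distancing = 92.3,
                                      suppression = 99.5),
                           utility = c(distraction = 93.2, distancing = 78.6,
                                       suppression = 95)),
                         emg_means = list(
                           corrugator = c(view_neu = 0.04, view_neg = 1.03,
                                          distraction = 0, distancing = 0.25,
                                          suppression = 0.07),
                           levator = c(view_neu = 0.09, view_neg = 0.58,
                                       distraction = -0.05, distancing = 0.01,
                                       suppression = -0.03)),
                         emg_sds = list(
                           corrugator = c(view_neu = 6.99, view_neg = 7.21,
                                          distraction = 7.67, distancing = 1.92,
                                          suppression = 3.78),
                           levator = c(view_neu = 1.84, view_neg = 3.2,
                                       distraction = 1.16, distancing = 1,
                                       suppression = 0.92)),
                         rating_subject_share = 0.5,
                         weights = c(effort = -6.85e-4, arousal = -7.84e-5,
                                     utility = 1.42e-3, corrugator = 7.45e-3,
                                     levator = 5.32e-3),
                         sv_nontop_mean = 0.70,
                         sd_subject = 0.146,
                         sd_resid = 0.12,
                         icc_target = 0.19,
                         choice_agreement = 0.8,
                         flexer_weights = c(intercept = 0, slope = 0),
                         self_control_weight = 20) {
  if (n < 2) stop("configuration error: n must be >= 2", call. = FALSE)
  sds <- c(unlist(rating_sds), unlist(emg_sds), sd_subject, sd_resid)
  if (any(sds < 0)) stop("configuration error: negative SD", call. = FALSE)
  stopifnot(rating_subject_share >= 0, rating_subject_share <= 1,
            choice_agreement >= 0, choice_agreement <= 1)
  structure(as.list(environment()), class = "study_config")
}

# mean of a N(mu, sd) truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  ifelse(z > 0, mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z, mu)
}

# location mu* such that, with subject offsets b ~ N(0, sd_b), values drawn
# from N(mu* + b, sd_w) and resampled into [lo, hi] have cohort mean `target`
# (the offset is integrated out on a quadrature grid)
cohort_mean_shift <- function(target, sd_w, sd_b, lo, hi) {
  if (sd_w == 0 && sd_b == 0) return(target)
  nodes <- seq(-4, 4, length.out = 41)
  wts <- stats::dnorm(nodes); wts <- wts / sum(wts)
  f <- function(mu) {
    sum(wts * truncnorm_mean(mu + nodes * sd_b, max(sd_w, 1e-12), lo, hi)) -
      target
  }
  stats::uniroot(f, lower = lo - 4 * (sd_w + sd_b),
                 upper = hi + 4 * (sd_w + sd_b), extendInt = "yes")$root
}

# draw values from N(mu_i, sd) resampled (not clipped) into [lo, hi]
rtrunc_resample <- function(mu, sd, lo, hi) {
  n <- length(mu)
  if (sd == 0) return(pmin(pmax(mu, lo), hi))
  x <- stats::rnorm(n, mu, sd)
  bad <- which(x < lo | x > hi)
  it <- 0
  while (length(bad) && it < 100) {
    x[bad] <- stats::rnorm(length(bad), mu[bad], sd)
    bad <- which(x < lo | x > hi)
    it <- it + 1
  }
  pmin(pmax(x, lo), hi)
}

#' Generate a complete synthetic study
#'
#' Draws block-level ratings and trial-level EMG summaries with subject
#' random effects, builds per-participant SV targets from the configured
#' random-intercept model, inverts the targets to agent utilities, runs
#' every agent through the full titration engine ([run_session()]) and
#' computes SVs with [aggregate_svs()] — the study table carries the
#' engine-produced SVs, never the targets.
#'
#' @param config A [study_config()].
#' @param seed Integer seed; the whole study is identical on replay.
#' @return List with `study` (trial-level long table: participant x
#'   strategy x trial), `ratings` (block-level table over the five
#'   conditions), `profiles` (list of `sv_profile`), `profile_table`,
#'   `sessions` (the raw session logs), `truth` (generator parameters,
#'   target SVs, agent utilities) and `config`.
#' @export
generate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  cf <- config
  n <- cf$n
  ids <- sprintf("p%03d", seq_len(n))
  strat <- strategies()
  conds <- conditions()

  withr::with_seed(as.integer(seed), {
    share <- cf$rating_subject_share
    # block-level ratings over the five conditions, subject effect shared
    # across conditions within a rating dimension
    ratings <- list()
    for (dim in c("arousal", "effort", "utility")) {
      m <- cf$rating_means[[dim]]; s <- cf$rating_sds[[dim]]
      subj <- stats::rnorm(n, 0, 1)
      vals <- sapply(names(m), function(cond) {
        sd_b <- s[[cond]] * sqrt(share)
        sd_w <- s[[cond]] * sqrt(1 - share)
        mu <- cohort_mean_shift(m[[cond]], sd_w, sd_b, 0, cf$scale_max)
        rtrunc_resample(mu + subj * sd_b, sd_w, 0, cf$scale_max)
      })
      ratings[[dim]] <- vals  # n x conditions matrix
    }

    # trial-level EMG summaries: subject effect + trial noise, unbounded
    tb <- cf$trials_per_block
    emg <- list()
    for (ch in c("corrugator", "levator")) {
      m <- cf$emg_means[[ch]]; s <- cf$emg_sds[[ch]]
      subj <- stats::rnorm(n, 0, 1)
      emg[[ch]] <- lapply(stats::setNames(nm = names(m)), function(cond) {
        sd_b <- s[[cond]] * sqrt(share)
        sd_w <- s[[cond]] * sqrt(1 - share)
        matrix(m[[cond]] + rep(subj * sd_b, each = tb) +
                 stats::rnorm(n * tb, 0, sd_w), nrow = tb)  # tb x n
      })
    }

    # centered level-1 predictors per participant over the three strategies
    center3 <- function(x) x - rowMeans(x)
    xc <- list(
      effort = center3(ratings$effort[, strat, drop = FALSE]),
      arousal = center3(ratings$arousal[, strat, drop = FALSE]),
      utility = center3(ratings$utility[, strat, drop = FALSE]),
      corrugator = center3(t(sapply(seq_len(n), function(i)
        sapply(strat, function(s) mean(emg$corrugator[[s]][, i]))))),
      levator = center3(t(sapply(seq_len(n), function(i)
        sapply(strat, function(s) mean(emg$levator[[s]][, i])))))
    )

    # SV targets: score = planted fixed-effect part; the preferred (top)
    # strategy is the argmax of score + residual and is pinned at 1 by the
    # paradigm; the two others follow mu + b + score + e
    score <- Reduce(`+`, lapply(names(cf$weights), function(w)
      cf$weights[[w]] * xc[[w]]))
    resid <- matrix(stats::rnorm(n * 3, 0, cf$sd_resid), n, 3,
                    dimnames = list(NULL, strat))
    b_subj <- stats::rnorm(n, 0, cf$sd_subject)
    attract <- score + resid
    target <- cf$sv_nontop_mean + b_subj + attract
    colnames(target) <- strat

    # invert targets to agent utilities: top utility 0; the others chosen
    # so the staircase lands each aggregated SV near its target
    # (middle: u_top - u = 4 (1 - t); bottom: u_top + u_mid - 2 u = 4 (1 - t))
    utilities <- matrix(0, n, 3, dimnames = list(NULL, strat))
    for (i in seq_len(n)) {
      ord <- order(-attract[i, ])
      t2 <- min(target[i, ord[2]], 0.995)
      t3 <- min(target[i, ord[3]], t2)
      u2 <- max(-1.98, -4 * (1 - t2))
      u3 <- max(-1.98, (u2 - 4 * (1 - t3)) / 2)
      utilities[i, ord] <- c(0, u2, min(u2, u3))
    }

    session_seeds <- sample.int(.Machine$integer.max, n)
    agents <- lapply(seq_len(n), function(i) agent(utilities = utilities[i, ]))
    sessions <- lapply(seq_len(n), function(i)
      run_session(ids[i], agents[[i]], session_seeds[i]))
    profiles <- lapply(sessions, aggregate_svs)
    ptab <- sv_profile_table(profiles)

    # actual choice: agrees with the predicted (highest-SV) strategy at the
    # configured rate, otherwise uniform over the two others
    actual <- vapply(seq_len(n), function(i) {
      pred <- profiles[[i]]$predicted_choice
      if (stats::runif(1) < cf$choice_agreement) pred
      else sample(setdiff(strat, pred), 1)
    }, "")

    # questionnaires
    flexer <- 50 + cf$flexer_weights[["intercept"]] * ptab$intercept +
      cf$flexer_weights[["slope"]] * ptab$slope + stats::rnorm(n, 0, 10)
    self_control <- 50 + cf$self_control_weight * b_subj + stats::rnorm(n, 0, 10)
    nfc <- stats::rnorm(n, 50, 10)

    # long block-level rating table over the five conditions
    rating_rows <- do.call(rbind, lapply(conds, function(cond) {
      data.frame(
        participant_id = ids, condition = cond,
        arousal = ratings$arousal[, cond],
        effort = ratings$effort[, cond],
        utility = if (cond %in% strat) ratings$utility[, cond] else NA_real_,
        corrugator = colMeans(emg$corrugator[[cond]]),
        levator = colMeans(emg$levator[[cond]]),
        stringsAsFactors = FALSE
      )
    }))

    # trial-level study table: 3 strategies x trials per participant,
    # block ratings broadcast to trials, EMG at trial granularity
    sv_mat <- as.matrix(ptab[, paste0("sv_", strat)])
    colnames(sv_mat) <- strat
    pi <- rep(seq_len(n), each = 3L * tb)
    si <- rep(rep(1:3, each = tb), n)
    tr <- rep(seq_len(tb), 3L * n)
    emg_arr <- function(ch) {
      a <- array(NA_real_, c(tb, n, 3))
      for (j in 1:3) a[, , j] <- emg[[ch]][[strat[j]]]
      a[cbind(tr, pi, si)]
    }
    study <- data.frame(
      participant_id = ids[pi], strategy = strat[si], trial = tr,
      sv = sv_mat[cbind(pi, si)],
      effort = ratings$effort[, strat][cbind(pi, si)],
      arousal = ratings$arousal[, strat][cbind(pi, si)],
      utility = ratings$utility[, strat][cbind(pi, si)],
      corrugator = emg_arr("corrugator"),
      levator = emg_arr("levator"),
      flexer = flexer[pi], self_control = self_control[pi], nfc = nfc[pi],
      predicted_choice = ptab$predicted_choice[pi],
      actual_choice = actual[pi],
      stringsAsFactors = FALSE
    )
  })

  truth <- list(
    seed = as.integer(seed), weights = cf$weights,
    sd_subject = cf$sd_subject, sd_resid = cf$sd_resid,
    icc_target = cf$icc_target, sv_nontop_mean = cf$sv_nontop_mean,
    subject_intercepts = b_subj, target_sv = target,
    utilities = utilities, choice_agreement = cf$choice_agreement
  )
  list(study = study, ratings = rating_rows, profiles = profiles,
       profile_table = ptab, sessions = sessions, truth = truth,
       config = cf)
}

#' Collapse a trial-level study table to condition level
#'
#' Averages the trial-varying columns (the EMG summaries) within
#' participant and strategy, yielding the quick 3-rows-per-participant
#' granularity; block-level columns are carried through unchanged.
#'
#' @param study_table Trial-level table from [generate_study()].
#' @return Data frame with one row per participant and strategy.
#' @export
collapse_to_condition_level <- function(study_table) {
  keys <- c("participant_id", "strategy")
  num <- c("sv", "effort", "arousal", "utility", "corrugator", "levator",
           "flexer", "self_control", "nfc")
  agg <- stats::aggregate(study_table[num], study_table[keys], mean)
  extra <- study_table[!duplicated(study_table[keys]),
                       c(keys, "predicted_choice", "actual_choice")]
  merge(agg, extra, by = keys, sort = TRUE)
}
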