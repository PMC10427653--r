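#' Parametric simulated decision agents
#'
#' An agent maps an offer (two strategies with displayed euro values) to a
#' choice.  Option values are `displayed money + strategy utility`; a
#' deterministic agent (`inverse_temperature = Inf`) picks the argmax, a
#' stochastic agent chooses via a logistic function of the value difference
#' scaled by `inverse_temperature`, and with probability `lapse` the choice
#' is uniformly random (an independent mixture applied after the logistic
#' rule, the usual psychometric lapse convention).
#'
#' On an exact value tie a deterministic agent picks the option with the
#' lower displayed amount — in the titration that is the flexible strategy,
#' the documented tie-break — and at equal money the canonically first
#' strategy label.
#'
#' @param utilities Named numeric vector of euro-equivalent strategy
#'   utilities (names from [strategies()]); missing strategies default to 0.
#' @param inverse_temperature Non-negative; `Inf` means deterministic.
#' @param lapse Lapse probability in `[0, 0.5)`.
#' @param preferences Optional antisymmetric matrix of pairwise euro-valued
#'   preference offsets (rows/cols named by strategy), overriding
#'   `utilities`; allows intransitive (cyclic) agents.
#' @return An object of class `cad_agent`.
#' @seealso [indifference_agent()], [cyclic_agent()], [simulate_cohort()]
#' @export
agent <- function(utilities = c(distancing = 0, distraction = 0, suppression = 0),
                  inverse_temperature = Inf, lapse = 0, preferences = NULL) {
  stopifnot(inverse_temperature >= 0, lapse >= 0, lapse < 0.5)
  u <- stats::setNames(numeric(3), strategies())
  if (length(utilities)) {
    assert_strategy(names(utilities))
    u[names(utilities)] <- utilities
  }
  if (!is.null(preferences)) {
    stopifnot(is.matrix(preferences),
              identical(sort(rownames(preferences)), strategies()),
              identical(sort(colnames(preferences)), strategies()),
              max(abs(preferences + t(preferences))) < 1e-12)
  }
  structure(list(utilities = u, inverse_temperature = inverse_temperature,
                 lapse = lapse, preferences = preferences),
            class = "cad_agent")
}

#' Deterministic agent with a given indifference point for one pairing
#'
#' Constructs a deterministic agent that prefers `flexible` at equal money
#' and whose indifference point against a 2 EUR `fixed` anchor is `mstar`:
#' it chooses the flexible strategy at displayed value `x` iff `x >= mstar`.
#'
#' @param flexible,fixed Strategy labels.
#' @param mstar Indifference point in (0, 2).
#' @return A `cad_agent`.
#' @export
indifference_agent <- function(flexible, fixed, mstar) {
  stopifnot(mstar > 0, mstar < 2)
  u <- stats::setNames(c(0, mstar - 2), c(flexible, fixed))
  agent(utilities = u)
}

#' Deterministic agent with cyclic (intransitive) pairwise preferences
#'
#' Prefers distancing over distraction, distraction over suppression and
#' suppression over distancing, each by `gap` euros — the inconsistent
#' response pattern in which no strategy wins both of its pairings.
#'
#' @param gap Preference strength in euros (> 0).
#' @return A `cad_agent`.
#' @export
cyclic_agent <- function(gap = 0.5) {
  s <- strategies()
  pref <- matrix(0, 3, 3, dimnames = list(s, s))
  cycle <- rbind(c("distancing", "distraction"),
                 c("distraction", "suppression"),
                 c("suppression", "distancing"))
  for (i in 1:3) {
    pref[cycle[i, 1], cycle[i, 2]] <- gap
    pref[cycle[i, 2], cycle[i, 1]] <- -gap
  }
  agent(preferences = pref)
}

# signed euro-valued advantage of strategy a over strategy b (money excluded)
agent_advantage <- function(ag, a, b) {
  if (!is.null(ag$preferences)) ag$preferences[a, b]
  else ag$utilities[[a]] - ag$utilities[[b]]
}

#' Make an agent choose between two displayed offers
#'
#' Consumes the current RNG stream (lapse and logistic draws).  Exposed
#' mainly for testing custom agents; sessions call it internally.
#'
#' @param ag A `cad_agent`.
#' @param left,right Strategy labels.
#' @param left_value,right_value Displayed euro values.
#' @return The chosen strategy label.
#' @export
agent_choose <- function(ag, left, right, left_value, right_value) {
  stopifnot(inherits(ag, "cad_agent"))
  if (ag$lapse > 0 && stats::runif(1) < ag$lapse) {
    return(if (stats::runif(1) < 0.5) left else right)
  }
  d <- (left_value - right_value) + agent_advantage(ag, left, right)
  if (is.infinite(ag$inverse_temperature)) {
    if (d > 0) return(left)
    if (d < 0) return(right)
    # exact tie: lower displayed amount (the titrated, flexible side);
    # at equal money the canonically first label
    if (left_value < right_value) return(left)
    if (right_value < left_value) return(right)
    return(sort(c(left, right))[1])
  }
  p_left <- stats::plogis(ag$inverse_temperature * d)
  if (stats::runif(1) < p_left) left else right
}

#' Simulate a cohort of agents through full CAD sessions
#'
#' Draws `n` independent agents from a distribution specification and runs
#' each through [run_session()], pairing the logs with the ground-truth
#' utilities for recovery scoring.
#'
#' @param n Number of agents (>= 1).
#' @param distribution List with `u_mean` (named per-strategy means, euros),
#'   `u_sd` (common SD of utilities), `inverse_temperature`, `lapse`.
#' @param seed Integer seed; the cohort is identical on replay.
#' @return List with `sessions` (session logs), `agents`, and `truth`
#'   (data frame of participant ids and true utilities).
#' @export
simulate_cohort <- function(n,
                            distribution = list(
                              u_mean = c(distancing = 0, distraction = 0,
                                         suppression = 0),
                              u_sd = 0.5, inverse_temperature = Inf, lapse = 0),
                            seed = 1) {
  stopifnot(n >= 1)
  dist <- distribution
  u_mean <- stats::setNames(numeric(3), strategies())
  u_mean[names(dist$u_mean)] <- dist$u_mean
  draws <- withr::with_seed(as.integer(seed), {
    list(
      u = matrix(stats::rnorm(3 * n, mean = rep(u_mean, each = n),
                              sd = dist$u_sd %||% 0),
                 nrow = n, dimnames = list(NULL, strategies())),
      session_seeds = sample.int(.Machine$integer.max, n)
    )
  })
  ids <- sprintf("p%03d", seq_len(n))
  agents <- lapply(seq_len(n), function(i) {
    agent(utilities = draws$u[i, ],
          inverse_temperature = dist$inverse_temperature %||% Inf,
          lapse = dist$lapse %||% 0)
  })
  sessions <- lapply(seq_len(n), function(i) {
    run_session(ids[i], agents[[i]], draws$session_seeds[i])
  })
  truth <- data.frame(participant_id = ids, draws$u,
                      check.names = FALSE, stringsAsFactors = FALSE)
  list(sessions = sessions, agents = agents, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
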