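#' @title Subjective values from titration outcomes
#' @description
#' The flexible strategy of a pairing (preferred at equal money) has SV 1.
#' The fixed strategy's SV is derived from the last displayed flexible
#' offer: 0.02 EUR is subtracted if the sixth choice was the flexible
#' strategy (the walk would have continued down) or added if it was the
#' fixed strategy, and the result is divided by the 2 EUR anchor.  Per-
#' strategy SVs are then averaged across the two pairings each strategy
#' appears in.  SV arithmetic uses the rounded on-screen value, which is
#' what yields the attainable range 0.005 to 0.995 per pairing.
#' @name valuation
NULL

#' Per-pairing subjective value of the fixed strategy
#'
#' @param result A `pairing_result` from [run_pairing()].
#' @return List with `sv_flexible` (always 1), `sv_fixed` in
#'   `[0.005, 0.995]`, and the strategy labels.
#' @export
pairing_sv <- function(result) {
  stopifnot(inherits(result, "pairing_result"))
  v <- result$last_display_value
  stopifnot(v >= 0.03, v <= 1.97)
  adj_cents <- if (result$last_choice == result$fixed) 2 else -2
  # integer-cent arithmetic: (display +- 0.02) / 2 lands exactly on the
  # 0.005 grid (0.03 - 0.02 in floating point would not)
  list(flexible = result$flexible, fixed = result$fixed,
       sv_flexible = 1,
       sv_fixed = (round(v * 100) + adj_cents) / 200)
}

#' Aggregate per-pairing SVs into a participant's SV profile
#'
#' Each strategy appears in exactly two of the three pairings; its
#' aggregated SV is the mean of its two per-pairing SVs (1 where it was
#' flexible).  Strategies are rank-coded by descending SV as -1 (highest),
#' 0, 1 (lowest); ties are broken by canonical strategy order.
#'
#' @param session A `session_log` from [run_session()], or a list of three
#'   `pairing_result`s covering all pairings.
#' @return An `sv_profile` list: `participant_id`, `sv` (named vector),
#'   `rank_code` (named -1/0/1), `ordered_intercept`, `ordered_slope`,
#'   `predicted_choice` (argmax SV).
#' @export
aggregate_svs <- function(session) {
  if (inherits(session, "session_log")) {
    pairings <- session$pairings
    pid <- session$participant_id
  } else {
    pairings <- session
    pid <- pairings[[1]]$records$participant_id[1] %||% "p1"
  }
  if (length(pairings) != 3L) {
    stop("incomplete session: expected 3 pairing results, got ",
         length(pairings), call. = FALSE)
  }
  per <- lapply(pairings, pairing_sv)
  sv <- stats::setNames(numeric(3), strategies())
  cnt <- stats::setNames(integer(3), strategies())
  for (p in per) {
    sv[p$flexible] <- sv[p$flexible] + p$sv_flexible
    sv[p$fixed] <- sv[p$fixed] + p$sv_fixed
    cnt[p$flexible] <- cnt[p$flexible] + 1L
    cnt[p$fixed] <- cnt[p$fixed] + 1L
  }
  if (any(cnt != 2L)) {
    stop("incomplete session: every strategy must appear in exactly 2 pairings",
         call. = FALSE)
  }
  sv <- sv / 2
  ord <- order(-sv, match(names(sv), strategies()))
  rank_code <- stats::setNames(integer(3), names(sv))
  rank_code[ord] <- c(-1L, 0L, 1L)
  fit <- ordered_sv_fit(sv)
  structure(
    list(participant_id = pid, sv = sv, rank_code = rank_code,
         ordered_intercept = fit["intercept"], ordered_slope = fit["slope"],
         predicted_choice = names(sv)[ord[1]]),
    class = "sv_profile"
  )
}

#' Ordered-SV linear fit (flexibility summary)
#'
#' Sorts a participant's three SVs in descending order and regresses them on
#' the centered rank (-1, 0, 1) by ordinary least squares.  With three
#' equally spaced ranks the fit is closed-form: the intercept is the mean SV
#' (how valuable regulation strategies are overall) and the slope is
#' `(lowest - highest) / 2` (<= 0; nearer 0 means a flatter, more flexible
#' preference profile).
#'
#' @param sv Numeric vector of three SVs (any order).
#' @return Named numeric `c(intercept =, slope =)`.
#' @export
ordered_sv_fit <- function(sv) {
  stopifnot(length(sv) == 3L)
  s <- sort(as.numeric(sv), decreasing = TRUE)
  c(intercept = mean(s), slope = (s[3] - s[1]) / 2)
}

# pure staircase arithmetic for a deterministic chooser with indifference
# point mstar: flexible chosen iff displayed offer >= mstar
staircase_sv <- function(mstar) {
  v <- 1
  adj <- 0.5
  for (k in 1:5) {
    flex <- display_value(v) >= mstar
    v <- v + if (flex) -adj else adj
    adj <- adj / 2
  }
  d6 <- display_value(v)
  (round(d6 * 100) + if (d6 >= mstar) -2 else 2) / 200
}

#' Analytic expected SVs for a transitive deterministic agent
#'
#' Closed-loop prediction used to validate recovery: for each pairing the
#' higher-utility strategy wins the equal round; against the 2 EUR anchor
#' the agent's indifference point is `2 + u_fixed - u_flexible`, and the
#' staircase walks the displayed offer to the grid point bracketing it.
#' Aggregation follows [aggregate_svs()].
#'
#' @param ag A deterministic `cad_agent` with utility (not preference-matrix)
#'   parametrization.
#' @return Named numeric vector of expected aggregated SVs per strategy.
#' @export
expected_sv <- function(ag) {
  stopifnot(inherits(ag, "cad_agent"), is.infinite(ag$inverse_temperature),
            is.null(ag$preferences))
  sv <- stats::setNames(numeric(3), strategies())
  for (pair in strategy_pairs()) {
    d <- agent_advantage(ag, pair[1], pair[2])
    # equal-money winner; exact tie goes to the canonically first label
    flex <- if (d > 0 || (d == 0 && pair[1] == sort(pair)[1])) pair[1] else pair[2]
    fixed <- setdiff(pair, flex)
    mstar <- 2 + agent_advantage(ag, fixed, flex)
    sv[flex] <- sv[flex] + 1
    sv[fixed] <- sv[fixed] + staircase_sv(mstar)
  }
  sv / 2
}

#' Tabulate SV profiles
#'
#' @param profiles List of `sv_profile` objects.
#' @return Data frame with one row per participant: SVs, rank codes,
#'   ordered intercept/slope and predicted choice.
#' @export
sv_profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      participant_id = p$participant_id,
      sv_distancing = unname(p$sv["distancing"]),
      sv_distraction = unname(p$sv["distraction"]),
      sv_suppression = unname(p$sv["suppression"]),
      rank_distancing = unname(p$rank_code["distancing"]),
      rank_distraction = unname(p$rank_code["distraction"]),
      rank_suppression = unname(p$rank_code["suppression"]),
      intercept = unname(p$ordered_intercept),
      slope = unname(p$ordered_slope),
      predicted_choice = p$predicted_choice,
      stringsAsFactors = FALSE
    )
  }))
}
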