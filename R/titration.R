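#' @title Adaptive monetary titration (CAD staircase)
#' @description
#' One CAD session compares the three strategy pairings.  Each pairing has
#' an equal-value round (three 1 EUR vs 1 EUR presentations; the strategy
#' chosen at least twice becomes the *flexible* strategy) followed by six
#' consecutive titration presentations of the flexible strategy against the
#' other strategy anchored at 2 EUR.  After each of the first five titration
#' choices the flexible offer is lowered (flexible chosen) or raised (fixed
#' chosen) by a halving adjustment: 0.50, 0.25, 0.125, 0.0625, 0.03125 EUR.
#' The internal offer is kept exact (a multiple of 2^-5 EUR); only the
#' *displayed* value is rounded, half away from zero, to 2 decimals.  The
#' sixth choice is logged and its 0.02 EUR effect applied at valuation.
#' @name titration
NULL

#' Round a euro amount for display
#'
#' Rounds half away from zero to two decimals, the display rule of the
#' titration: the internal values 1.96875 and 0.03125 map to the on-screen
#' 1.97 and 0.03 endpoints, and midpoints such as 1.875 map to 1.88.
#'
#' @param internal_value Numeric euro amount(s) in (0, 2); exact multiples
#'   of 2^-5 in the titration, so the scaling by 100 below is float-exact.
#' @return Numeric rounded to 2 decimals.
#' @export
#' @examples
#' display_value(1.96875)  # 1.97
#' display_value(0.03125)  # 0.03
display_value <- function(internal_value) {
  stopifnot(all(internal_value > 0), all(internal_value < 2))
  sign(internal_value) * floor(abs(internal_value) * 100 + 0.5) / 100
}

#' Create the titration state for one pairing
#'
#' @param flexible,fixed Strategy labels: the equal-round winner (offer
#'   titrated from 1 EUR) and the loser (anchored at 2 EUR).
#' @return A `titration_state` list with the exact internal offer, the next
#'   adjustment magnitude (0.50 EUR at the start) and the step counter.
#' @export
new_titration_state <- function(flexible, fixed) {
  assert_pair(c(flexible, fixed))
  structure(
    list(flexible = flexible, fixed = fixed,
         internal_value = 1, adjustment = 0.5, step = 0L),
    class = "titration_state"
  )
}

#' Apply one titration adjustment
#'
#' Lowers the internal flexible offer by the current adjustment if the
#' flexible strategy was chosen, raises it if the fixed strategy was chosen,
#' then halves the adjustment (exactly) and increments the step counter.
#'
#' @param state A `titration_state`.
#' @param choice Strategy label chosen on the current presentation.
#' @return The updated `titration_state`.
#' @export
titration_step <- function(state, choice) {
  stopifnot(inherits(state, "titration_state"))
  if (state$step >= 5L) {
    stop("titration already complete: five adjustments have been applied",
         call. = FALSE)
  }
  if (!choice %in% c(state$flexible, state$fixed)) {
    stop("invalid choice '", choice, "': not part of this pairing", call. = FALSE)
  }
  dir <- if (choice == state$flexible) -1 else 1
  state$internal_value <- state$internal_value + dir * state$adjustment
  state$adjustment <- state$adjustment / 2
  state$step <- state$step + 1L
  state
}

# assemble the 9 per-pairing choice rows from parallel vectors
pairing_records <- function(participant_id, pair, phase, left, right,
                            left_value, right_value, chosen) {
  data.frame(
    participant_id = participant_id, phase = phase, pair_id = pair_id(pair),
    presentation_index = seq_along(phase),
    left_strategy = left, right_strategy = right,
    left_value = left_value, right_value = right_value,
    chosen = chosen, stringsAsFactors = FALSE
  )
}

#' Run the equal-value round for one pairing
#'
#' Presents the pair three times at 1 EUR vs 1 EUR with randomized sides.
#' The strategy chosen on at least two of the three presentations becomes
#' the flexible strategy (a strict majority always exists for binary votes).
#'
#' @param pair Length-2 character vector of distinct strategies.
#' @param agent An [agent()].
#' @param participant_id Identifier written into the choice records.
#' @return List with `flexible`, `fixed`, `votes` (the three chosen labels)
#'   and the per-presentation side assignments (`lefts`, `rights`).
#'   Consumes the current RNG stream for side randomization and stochastic
#'   agents.
#' @export
run_equal_round <- function(pair, agent, participant_id = "p1") {
  assert_pair(pair)
  votes <- character(3)
  lefts <- character(3); rights <- character(3)
  for (i in 1:3) {
    left_first <- stats::runif(1) < 0.5
    lefts[i] <- if (left_first) pair[1] else pair[2]
    rights[i] <- setdiff(pair, lefts[i])
    votes[i] <- agent_choose(agent, lefts[i], rights[i], 1, 1)
  }
  n1 <- sum(votes == pair[1])
  flexible <- if (n1 >= 2) pair[1] else pair[2]
  list(flexible = flexible, fixed = setdiff(pair, flexible),
       votes = votes, lefts = lefts, rights = rights)
}

#' Run one full pairing: equal round plus six-presentation titration
#'
#' After the equal round, the flexible strategy starts at a displayed
#' 1.00 EUR against the fixed strategy's 2.00 EUR.  Five halving adjustments
#' are applied after choices 1-5; the sixth choice is only logged (its
#' 0.02 EUR analysis-stage effect is applied by [pairing_sv()]).
#'
#' @inheritParams run_equal_round
#' @return A `pairing_result` list: `flexible`, `fixed`,
#'   `last_display_value` (the sixth on-screen flexible offer),
#'   `last_choice`, `equal_round_votes`, and `records` (all nine choice
#'   records of the pairing).
#' @export
run_pairing <- function(pair, agent, participant_id = "p1") {
  eq <- run_equal_round(pair, agent, participant_id)
  state <- new_titration_state(eq$flexible, eq$fixed)
  lefts <- c(eq$lefts, character(6)); rights <- c(eq$rights, character(6))
  lv <- c(rep(1, 3), numeric(6)); rv <- c(rep(1, 3), numeric(6))
  chosen <- c(eq$votes, character(6))
  disp <- NA_real_
  for (k in 1:6) {
    disp <- display_value(state$internal_value)
    i <- 3L + k
    if (stats::runif(1) < 0.5) {
      lefts[i] <- state$flexible; rights[i] <- state$fixed
      lv[i] <- disp; rv[i] <- 2
    } else {
      lefts[i] <- state$fixed; rights[i] <- state$flexible
      lv[i] <- 2; rv[i] <- disp
    }
    chosen[i] <- agent_choose(agent, lefts[i], rights[i], lv[i], rv[i])
    if (k < 6) state <- titration_step(state, chosen[i])
  }
  structure(
    list(flexible = eq$flexible, fixed = eq$fixed,
         last_display_value = disp, last_choice = chosen[9],
         equal_round_votes = eq$votes,
         records = pairing_records(participant_id, pair,
                                   c(rep("equal", 3), rep("titration", 6)),
                                   lefts, rights, lv, rv, chosen)),
    class = "pairing_result"
  )
}

#' Run a complete CAD session for one participant
#'
#' The three pairings are presented in randomized order; within each
#' presentation the side assignment is randomized.  Given the same agent and
#' seed the session log is bit-exact on replay.
#'
#' @param participant_id Identifier written into the log.
#' @param agent An [agent()].
#' @param seed Integer seed for the session's single random generator
#'   (pair order, side randomization, stochastic choices).
#' @return A `session_log` list with `participant_id`, `pairings` (list of
#'   three `pairing_result`s keyed by pair id) and `records` (a 27-row data
#'   frame: 3 pairs x (3 equal + 6 titration)).
#' @export
run_session <- function(participant_id, agent, seed) {
  withr::with_seed(as.integer(seed), {
    pairs <- strategy_pairs()[sample.int(3)]
    pairings <- lapply(pairs, run_pairing, agent = agent,
                       participant_id = participant_id)
  })
  names(pairings) <- vapply(pairings, function(p) pair_id(c(p$flexible, p$fixed)), "")
  structure(
    list(participant_id = participant_id, pairings = pairings,
         records = do.call(rbind, c(lapply(pairings, `[[`, "records"),
                                    make.row.names = FALSE))),
    class = "session_log"
  )
}
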