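#' Emotion-regulation strategy labels
#'
#' The three regulation strategies of the paradigm, in canonical
#' (alphabetical) order.  The canonical order is used only for tie-breaking
#' and bookkeeping; it carries no assumption about difficulty or preference.
#'
#' @return Character vector `c("distancing", "distraction", "suppression")`.
#' @export
strategies <- function() c("distancing", "distraction", "suppression")

#' Viewing and regulation condition labels of the block design
#'
#' The five blocks: neutral viewing, negative viewing, and the three
#' regulation strategies.
#'
#' @return Character vector of the five condition labels.
#' @export
conditions <- function() {
  c("view_neu", "view_neg", "distraction", "distancing", "suppression")
}

#' The three unordered strategy pairings
#'
#' @return List of three length-2 character vectors, each a strategy pair,
#'   ordered canonically within and across pairs.
#' @export
strategy_pairs <- function() {
  s <- strategies()
  list(c(s[1], s[2]), c(s[1], s[3]), c(s[2], s[3]))
}

assert_strategy <- function(x) {
  if (!all(x %in% strategies())) {
    stop("unknown strategy label: ", paste(setdiff(x, strategies()), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

assert_pair <- function(pair) {
  if (length(pair) != 2L || anyDuplicated(pair)) {
    stop("a pairing needs two distinct strategies", call. = FALSE)
  }
  assert_strategy(pair)
  invisible(pair)
}

# canonical id like "distancing:distraction", order-insensitive
pair_id <- function(pair) {
  assert_pair(pair)
  paste(sort(pair), collapse = ":")
}
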