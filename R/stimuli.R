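#' Partition picture ratings into matched stimulus sets
#'
#' Evolutionary search that splits `k * set_size` pictures into `k` disjoint
#' sets of equal size with comparable mean valence and arousal.  Candidate
#' solutions are permutations of the item indices (consecutive blocks form
#' the sets); the objective is the sum, over the two rating dimensions, of
#' the variance of the set means.  Search uses tournament selection, swap
#' mutation and elitism; with elitism the best objective is non-increasing
#' across generations, and the run is deterministic given `seed`.
#'
#' @param ratings Data frame or matrix with columns `valence` and `arousal`,
#'   one row per picture.
#' @param k Number of sets.
#' @param set_size Items per set; `nrow(ratings)` must equal `k * set_size`.
#' @param ga_params List: `pop_size`, `generations`, `tournament_size`,
#'   `swap_prob` (per-offspring expected number of swaps is 1 plus a
#'   geometric tail), `elite`.
#' @param seed Integer seed.
#' @return List with `sets` (list of `k` lists: `member_ids`,
#'   `mean_valence`, `mean_arousal`), `objective` (best value), and
#'   `history` (best objective per generation).
#' @export
partition_stimuli <- function(ratings, k = 5, set_size = 20,
                              ga_params = list(pop_size = 60,
                                               generations = 150,
                                               tournament_size = 3,
                                               swap_prob = 0.3,
                                               elite = 2),
                              seed = 1) {
  ratings <- as.data.frame(ratings)
  stopifnot(all(c("valence", "arousal") %in% names(ratings)))
  n_items <- nrow(ratings)
  if (n_items != k * set_size) {
    stop("invalid input: ", n_items, " items cannot form ", k,
         " sets of ", set_size, call. = FALSE)
  }
  val <- ratings$valence
  aro <- ratings$arousal
  grp <- rep(seq_len(k), each = set_size)

  objective <- function(perm) {
    mv <- tapply(val[perm], grp, mean)
    ma <- tapply(aro[perm], grp, mean)
    stats::var(mv) + stats::var(ma)
  }

  gp <- utils::modifyList(list(pop_size = 60, generations = 150,
                               tournament_size = 3, swap_prob = 0.3,
                               elite = 2), ga_params)

  withr::with_seed(as.integer(seed), {
    pop <- replicate(gp$pop_size, sample.int(n_items), simplify = FALSE)
    fit <- vapply(pop, objective, 0)
    history <- numeric(gp$generations)
    for (g in seq_len(gp$generations)) {
      ord <- order(fit)
      newpop <- pop[ord[seq_len(gp$elite)]]
      while (length(newpop) < gp$pop_size) {
        idx <- sample.int(gp$pop_size, gp$tournament_size)
        parent <- pop[[idx[which.min(fit[idx])]]]
        child <- parent
        repeat {  # at least one swap, geometric number of extras
          sw <- sample.int(n_items, 2)
          child[sw] <- child[rev(sw)]
          if (stats::runif(1) > gp$swap_prob) break
        }
        newpop[[length(newpop) + 1L]] <- child
      }
      pop <- newpop
      fit <- vapply(pop, objective, 0)
      history[g] <- min(fit)
    }
    best <- pop[[which.min(fit)]]
  })

  sets <- lapply(seq_len(k), function(j) {
    ids <- sort(best[grp == j])
    list(member_ids = ids, mean_valence = mean(val[ids]),
         mean_arousal = mean(aro[ids]))
  })
  list(sets = sets, objective = min(fit), history = history)
}

#' Synthetic normative picture ratings
#'
#' Draws valence/arousal ratings with the location and spread typical of
#' negative picture-set norms on 9-point scales (valence around 2.7,
#' arousal around 5.6).  Purely synthetic; no normative database ships with
#' the package.
#'
#' @param n Number of pictures.
#' @param seed Integer seed.
#' @return Data frame with columns `picture_id`, `valence`, `arousal`.
#' @export
synthetic_picture_ratings <- function(n = 100, seed = 1) {
  withr::with_seed(as.integer(seed), {
    data.frame(
      picture_id = seq_len(n),
      valence = stats::rnorm(n, 2.7, 0.6),
      arousal = stats::rnorm(n, 5.6, 0.37)
    )
  })
}
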