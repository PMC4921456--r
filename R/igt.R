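#' Default four-deck payoff schedule
#'
#' The classic gambling-task contingencies at the reward magnitudes used in
#' the scanner version: decks 1 and 3 pay $150 per card, decks 2 and 4 pay
#' $200. Penalties are arranged per 10-card cycle so that decks 1 and 3 net
#' +$250 per 10 cards (advantageous) and decks 2 and 4 net -$250
#' (disadvantageous); decks 1 and 2 carry one large infrequent penalty per
#' cycle, decks 3 and 4 five small frequent ones. The schedule is data — a
#' loss amount per position in the 10-card cycle — so alternative
#' contingencies can be swapped in.
#'
#' @return list of class `deck_schedule`: per deck, `reward` (dollars/card)
#'   and `loss_cycle` (length-10 loss amounts applied cyclically in selection
#'   order from that deck).
#' @export
default_schedule <- function() {
  decks <- list(
    deck1 = list(reward = 150, loss_cycle = c(0, 0, 0, 0, 0, 0, 0, 0, 1250, 0)),
    deck2 = list(reward = 200, loss_cycle = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2250)),
    deck3 = list(reward = 150, loss_cycle = c(0, 250, 0, 250, 0, 250, 0, 250, 0, 250)),
    deck4 = list(reward = 200, loss_cycle = c(450, 0, 450, 0, 450, 0, 450, 0, 450, 0)))
  structure(list(decks = decks), class = "deck_schedule")
}

#' Expected net payoff per 10-card cycle
#'
#' @param schedule a [default_schedule()]-style schedule.
#' @return named numeric: expected net dollars per 10 consecutive selections
#'   from each deck (exact, since the cycle is deterministic).
#' @export
expected_net_per_cycle <- function(schedule = default_schedule()) {
  vapply(schedule$decks,
         function(d) 10 * d$reward - sum(d$loss_cycle), numeric(1))
}

#' Simulate an agent playing the gambling task
#'
#' Two stock policies: `"uniform"` picks decks uniformly at random;
#' `"epsilon_greedy"` tracks the running mean net payoff of each deck
#' (initialized at 0) and picks the current best deck with probability
#' `1 - epsilon` (first-index tie-break), exploring uniformly otherwise.
#' Missed responses (probability `miss_prob`) are recorded with deck `NA` and
#' zero payoff; they count toward no deck.
#'
#' @param schedule a `deck_schedule`.
#' @param policy `"uniform"` or `"epsilon_greedy"`.
#' @param n_trials selections per block (default 60).
#' @param epsilon exploration rate for the greedy policy.
#' @param miss_prob probability a trial is missed (no response within the
#'   window).
#' @param seed optional RNG seed; same seed, same record.
#' @return An `igt_record`: data.frame with columns `trial`, `deck`, `win`,
#'   `loss`, `total` (running total, starting from $0).
#' @export
simulate_agent <- function(schedule = default_schedule(),
                           policy = c("uniform", "epsilon_greedy"),
                           n_trials = 60, epsilon = 0.1, miss_prob = 0,
                           seed = NULL) {
  policy <- tryCatch(match.arg(policy),
                     error = function(e) stop("unknown policy: ",
                                              policy[1], call. = FALSE))
  stopifnot(n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_decks <- length(schedule$decks)
  picks_per_deck <- integer(n_decks)   # position in each deck's cycle
  value <- numeric(n_decks)            # running mean net payoff
  n_sampled <- integer(n_decks)
  deck <- win <- loss <- rep(NA_real_, n_trials)
  total <- numeric(n_trials)
  running <- 0
  for (t in seq_len(n_trials)) {
    if (miss_prob > 0 && stats::runif(1) < miss_prob) {
      win[t] <- 0; loss[t] <- 0; total[t] <- running
      next
    }
    d <- if (policy == "uniform" || stats::runif(1) < epsilon) {
      sample.int(n_decks, 1)
    } else {
      which.max(value)
    }
    picks_per_deck[d] <- picks_per_deck[d] + 1L
    dk <- schedule$decks[[d]]
    pos <- ((picks_per_deck[d] - 1L) %% length(dk$loss_cycle)) + 1L
    w <- dk$reward
    l <- dk$loss_cycle[pos]
    running <- running + w - l
    n_sampled[d] <- n_sampled[d] + 1L
    value[d] <- value[d] + ((w - l) - value[d]) / n_sampled[d]
    deck[t] <- d; win[t] <- w; loss[t] <- l; total[t] <- running
  }
  structure(data.frame(trial = seq_len(n_trials), deck = deck, win = win,
                       loss = loss, total = total),
            class = c("igt_record", "data.frame"))
}

#' Net-advantageous score
#'
#' Behavioral performance: selections from advantageous decks (1 and 3) minus
#' selections from disadvantageous decks (2 and 4). Missed trials count toward
#' neither.
#'
#' @param record an `igt_record` (or data.frame with a `deck` column).
#' @return integer score in \[-n_trials, n_trials\].
#' @export
net_advantageous <- function(record) {
  if (nrow(record) == 0L) stop("empty trial record")
  d <- record$deck[!is.na(record$deck)]
  as.integer(sum(d %in% c(1, 3)) - sum(d %in% c(2, 4)))
}

#' Write / read trial logs as CSV
#'
#' @param record an `igt_record`.
#' @param path CSV path.
#' @return `path` / the record, invisibly for the writer.
#' @export
write_igt_record <- function(record, path) {
  utils::write.csv(record, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_igt_record
#' @export
read_igt_record <- function(path) {
  rec <- utils::read.csv(path)
  structure(rec, class = c("igt_record", "data.frame"))
}
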