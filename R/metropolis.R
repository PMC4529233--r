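#' Metropolis acceptance on docking scores
#'
#' Accepts a proposed score with probability
#' `min(1, exp(-(s_new - s_old) / kBT))`: score decreases (better predicted
#' binding) are always accepted, increases are accepted with Boltzmann
#' probability controlled by the temperature-like parameter `kBT`, expressed
#' in the same units as the scores (kcal/mol). Vectorised; every decision
#' consumes exactly one uniform deviate, including certain acceptances, so
#' the random stream advances identically whatever the scores.
#'
#' @param s_old,s_new Current and proposed scores (kcal/mol).
#' @param kBT Positive temperature parameter (kcal/mol).
#' @return Logical vector of acceptance decisions.
#' @export
#' @examples
#' set.seed(1)
#' mean(metropolis_accept(0, rep(0.6, 1e4), kBT = 0.6)) # ~ exp(-1)
metropolis_accept <- function(s_old, s_new, kBT) {
  if (any(!is.finite(s_old)) || any(!is.finite(s_new))) {
    abort("scores must be finite.", class = "pepremc_nonfinite_score")
  }
  if (any(!is.finite(kBT)) || any(kBT <= 0)) {
    abort("`kBT` must be positive and finite.", class = "pepremc_bad_temperature")
  }
  n <- max(length(s_old), length(s_new), length(kBT))
  p <- pmin(1, exp(-(rep_len(s_new, n) - rep_len(s_old, n)) / rep_len(kBT, n)))
  runif(n) < p
}

#' Replica-swap acceptance probability
#'
#' The parallel-tempering criterion
#' `min(1, exp((1/kBT_a - 1/kBT_b) * (s_a - s_b)))`, which preserves detailed
#' balance for the product of per-temperature Boltzmann measures: a better
#' (lower) score moving to the colder temperature is always accepted, the
#' reverse exchange pays the corresponding Boltzmann factor. Equal scores
#' always swap.
#'
#' @param s_a,s_b Scores of the two replicas (kcal/mol).
#' @param kBT_a,kBT_b Their distinct ladder temperatures (kcal/mol).
#' @return Acceptance probability in (0, 1].
#' @export
swap_probability <- function(s_a, s_b, kBT_a, kBT_b) {
  if (any(kBT_a <= 0) || any(kBT_b <= 0)) {
    abort("temperatures must be positive.", class = "pepremc_bad_temperature")
  }
  if (any(kBT_a == kBT_b)) {
    abort("swap requires two distinct temperatures.",
          class = "pepremc_same_temperature")
  }
  pmin(1, exp((1 / kBT_a - 1 / kBT_b) * (s_a - s_b)))
}

#' A replica state
#'
#' Bundles a peptide with its current accepted score and ladder temperature.
#'
#' @param sequence Residue string.
#' @param score Last accepted score (kcal/mol).
#' @param kBT Ladder temperature (kcal/mol).
#' @param replica_index Slot index on the ladder.
#' @return A `replica_state` list.
#' @export
replica_state <- function(sequence, score, kBT, replica_index = 1L) {
  stopifnot(is.finite(score), kBT > 0)
  structure(list(sequence = sequence, score = score, kBT = kBT,
                 replica_index = as.integer(replica_index)),
            class = "replica_state")
}

#' Attempt a replica exchange between two states
#'
#' Draws one uniform deviate against [swap_probability()]; on acceptance the
#' two replicas exchange (sequence, score) while keeping their temperature
#' slots.
#'
#' @param a,b `replica_state` objects at distinct temperatures.
#' @return List with `accepted`, and the post-decision states `a` and `b`.
#' @export
attempt_swap <- function(a, b) {
  stopifnot(inherits(a, "replica_state"), inherits(b, "replica_state"))
  p <- swap_probability(a$score, b$score, a$kBT, b$kBT)
  accepted <- runif(1) < p
  if (accepted) {
    tmp <- list(sequence = a$sequence, score = a$score)
    a$sequence <- b$sequence
    a$score <- b$score
    b$sequence <- tmp$sequence
    b$score <- tmp$score
  }
  list(accepted = accepted, a = a, b = b)
}
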