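#' Run one replica exchange Monte Carlo optimisation
#'
#' The optimisation kernel: every replica on the temperature ladder starts
#' from the same sequence (scored once at step 0), and at each step performs
#' mutate -> score -> Metropolis accept; after the mutation sweep one swap is
#' attempted between two uniformly chosen distinct ladder temperatures (no
#' swap is attempted on a single-temperature ladder). Scores of the current
#' state are cached, never re-evaluated, so with a stochastic backend the
#' chain is an independence-proposal Metropolis sampler in (sequence, score)
#' space.
#'
#' Draw order (fixed, so trajectories are bit-reproducible given a seed): per
#' step, for each replica in ladder order, mutation position, mutation
#' residue, one score draw, one acceptance uniform; then one pair draw and
#' one swap uniform. A backend failure rejects the proposal without consuming
#' the acceptance uniform and logs a warning.
#'
#' @param start Starting sequence (default: octa-alanine).
#' @param backend Scoring backend (see [score_sequence()]).
#' @param ladder Distinct positive temperatures kBT (kcal/mol); default the
#'   three-temperature ladder 0.2/0.4/0.6.
#' @param n_steps Number of optimisation steps (default 100). `0` returns the
#'   start sequence scored once.
#' @param site Site label passed to the backend.
#' @param config Optional [docking_config()] forwarded to adapter backends.
#' @param seed Integer seed scoped to this run (the global RNG state is
#'   restored afterwards). `NULL` continues the current stream.
#' @param run_index Campaign run number recorded in the trajectory.
#' @param alphabet Residue alphabet for the mutation move; defaults to the
#'   backend's alphabet for synthetic landscapes, else the 20 amino acids.
#' @return An `remc_trajectory`: list with `steps` (a tibble with one
#'   mutation-state record per replica per step, post-decision, plus one swap
#'   record per step) and `meta`.
#' @export
#' @examples
#' land <- generate_landscape(length = 4, alphabet = c("A", "G", "Y", "R"),
#'                            noise_sd = 0, seed = 1)
#' tr <- run_remc("AAAA", land, n_steps = 20, seed = 7)
#' dplyr::glimpse(tr$steps)
run_remc <- function(start = strrep("A", 8),
                     backend,
                     ladder = c(0.2, 0.4, 0.6),
                     n_steps = 100,
                     site = "binding",
                     config = NULL,
                     seed = NULL,
                     run_index = 1L,
                     alphabet = backend_alphabet(backend)) {
  if (length(ladder) < 1 || any(!is.finite(ladder)) || any(ladder <= 0) ||
      anyDuplicated(ladder)) {
    abort("`ladder` must be distinct positive temperatures.",
          class = "pepremc_bad_temperature")
  }
  stopifnot(n_steps >= 0, n_steps == floor(n_steps))
  alphabet <- check_alphabet(alphabet)
  start <- make_peptide(start, alphabet)
  if (!is.null(seed)) withr::local_seed(seed)

  R <- length(ladder)
  L <- nchar(start)
  A <- length(alphabet)
  scorer <- make_scorer(backend, site, alphabet, config)

  start_idx <- encode_seq(start, alphabet)
  state_idx <- replicate(R, start_idx, simplify = FALSE)
  state_score <- numeric(R)
  state_seq <- rep(start, R)

  n_mut <- R * (n_steps + 1)
  do_swaps <- R >= 2
  n_swap <- if (do_swaps) n_steps else 0
  pairs <- if (do_swaps) utils::combn(R, 2) else NULL

  rec <- list(
    step = integer(n_mut + n_swap), replica = integer(n_mut + n_swap),
    partner = rep(NA_integer_, n_mut + n_swap),
    kBT = rep(NA_real_, n_mut + n_swap),
    move = character(n_mut + n_swap),
    sequence = rep(NA_character_, n_mut + n_swap),
    score = rep(NA_real_, n_mut + n_swap),
    accepted = logical(n_mut + n_swap)
  )
  k <- 0L
  n_failures <- 0L

  for (r in seq_len(R)) {
    s0 <- scorer(start_idx)
    if (is.na(s0)) {
      abort("backend failed while scoring the starting sequence.",
            class = "pepremc_backend_failure")
    }
    state_score[r] <- s0
    k <- k + 1L
    rec$step[k] <- 0L; rec$replica[k] <- r; rec$kBT[k] <- ladder[r]
    rec$move[k] <- "mutation"; rec$sequence[k] <- start
    rec$score[k] <- s0; rec$accepted[k] <- TRUE
  }

  if (n_steps >= 1) {
    for (t in seq_len(n_steps)) {
      for (r in seq_len(R)) {
        idx <- state_idx[[r]]
        pos <- sample.int(L, 1L)
        cur <- idx[pos]
        cand <- sample.int(A - 1L, 1L)
        if (cand >= cur) cand <- cand + 1L
        prop <- idx
        prop[pos] <- cand
        s_new <- scorer(prop)
        acc <- FALSE
        if (is.na(s_new)) {
          n_failures <- n_failures + 1L
        } else {
          acc <- runif(1) < min(1, exp(-(s_new - state_score[r]) / ladder[r]))
          if (acc) {
            state_idx[[r]] <- prop
            state_score[r] <- s_new
            state_seq[r] <- decode_seq(prop, alphabet)
          }
        }
        k <- k + 1L
        rec$step[k] <- t; rec$replica[k] <- r; rec$kBT[k] <- ladder[r]
        rec$move[k] <- "mutation"; rec$sequence[k] <- state_seq[r]
        rec$score[k] <- state_score[r]; rec$accepted[k] <- acc
      }
      if (do_swaps) {
        pair <- pairs[, sample.int(ncol(pairs), 1L)]
        i <- pair[1]; j <- pair[2]
        p <- min(1, exp((1 / ladder[i] - 1 / ladder[j]) *
                          (state_score[i] - state_score[j])))
        acc <- runif(1) < p
        if (acc) {
          tmp_idx <- state_idx[[i]]; tmp_s <- state_score[i]; tmp_q <- state_seq[i]
          state_idx[[i]] <- state_idx[[j]]; state_score[i] <- state_score[j]
          state_seq[i] <- state_seq[j]
          state_idx[[j]] <- tmp_idx; state_score[j] <- tmp_s; state_seq[j] <- tmp_q
        }
        k <- k + 1L
        rec$step[k] <- t; rec$replica[k] <- i; rec$partner[k] <- j
        rec$move[k] <- "swap"; rec$accepted[k] <- acc
      }
    }
  }

  steps <- as_tibble(rec)
  steps$run <- as.integer(run_index)
  steps <- steps[, c("run", "step", "replica", "partner", "kBT", "move",
                     "sequence", "score", "accepted")]
  if (n_failures > 0) {
    inform(sprintf("run %d: %d proposals rejected due to backend failures",
                   run_index, n_failures))
  }
  structure(
    list(steps = steps,
         meta = list(run = as.integer(run_index), start = start,
                     ladder = ladder, n_steps = as.integer(n_steps),
                     site = site, seed = seed, alphabet = alphabet,
                     backend_class = class(backend)[1],
                     n_backend_failures = n_failures)),
    class = "remc_trajectory"
  )
}

#' @export
print.remc_trajectory <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<remc_trajectory> run %d: %d steps, ladder {%s} kcal/mol, start %s\n",
              m$run, m$n_steps, paste(m$ladder, collapse = ", "), m$start))
  best <- select_best(x)
  cat(sprintf("  best end-simulation peptide: %s (%.3f kcal/mol at kBT %.2g)\n",
              best$sequence, best$score, best$kBT))
  invisible(x)
}

#' Final-step replica states of a trajectory
#'
#' @param trajectory An `remc_trajectory`.
#' @return Tibble with one row per replica at the last step.
#' @export
final_states <- function(trajectory) {
  stopifnot(inherits(trajectory, "remc_trajectory"))
  st <- trajectory$steps
  st[st$move == "mutation" & st$step == trajectory$meta$n_steps,
     c("run", "replica", "kBT", "sequence", "score")]
}

#' Lowest-scoring end-simulation peptide of a run
#'
#' Selects the final-step state with minimum score across the ladder's
#' replicas; ties broken by lower kBT, then lexicographically by sequence.
#'
#' @param trajectory An `remc_trajectory`.
#' @return One-row tibble (`run`, `replica`, `kBT`, `sequence`, `score`).
#' @export
select_best <- function(trajectory) {
  fin <- final_states(trajectory)
  dplyr::arrange(fin, .data$score, .data$kBT, .data$sequence)[1, ]
}

#' Run an optimisation campaign
#'
#' Repeats [run_remc()] `n_runs` times with per-run seeds derived
#' deterministically from the campaign seed, and selects each run's lowest
#' scoring end-simulation peptide for further analysis. The protocol defaults
#' (9 runs of 100 steps on the 0.2/0.4/0.6 ladder from octa-alanine) are the
#' campaign conditions of the design study this implements.
#'
#' @inheritParams run_remc
#' @param n_runs Number of independent optimisation runs (default 9).
#' @param verbose Emit a one-line summary per run.
#' @return An `remc_campaign`: list with `trajectories`, `selected` (tibble of
#'   per-run best peptides) and `meta`.
#' @export
run_campaign <- function(start = strrep("A", 8),
                         backend,
                         ladder = c(0.2, 0.4, 0.6),
                         n_steps = 100,
                         n_runs = 9,
                         site = "binding",
                         config = NULL,
                         seed = NULL,
                         verbose = FALSE,
                         alphabet = backend_alphabet(backend)) {
  stopifnot(n_runs >= 1)
  run_seeds <- if (!is.null(seed)) {
    withr::with_seed(seed, sample.int(.Machine$integer.max, n_runs))
  }
  trajectories <- purrr::map(seq_len(n_runs), function(i) {
    tr <- run_remc(start = start, backend = backend, ladder = ladder,
                   n_steps = n_steps, site = site, config = config,
                   seed = run_seeds[i], run_index = i, alphabet = alphabet)
    if (verbose) {
      g <- glance(tr)
      inform(sprintf(
        "run %d/%d: best %s (%.2f kcal/mol), mutation acceptance %.2f, swap acceptance %.2f",
        i, n_runs, g$best_sequence, g$best_score,
        g$mutation_acceptance, g$swap_acceptance))
    }
    tr
  })
  selected <- purrr::map_dfr(trajectories, select_best)
  structure(
    list(trajectories = trajectories, selected = selected,
         meta = list(start = start, ladder = ladder,
                     n_steps = as.integer(n_steps), n_runs = as.integer(n_runs),
                     site = site, seed = seed, run_seeds = run_seeds)),
    class = "remc_campaign"
  )
}

#' @export
print.remc_campaign <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<remc_campaign> %d runs x %d steps, ladder {%s} kcal/mol\n",
              m$n_runs, m$n_steps, paste(m$ladder, collapse = ", ")))
  print(x$selected)
  invisible(x)
}
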