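#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an REMC trajectory
#'
#' @param x An `remc_trajectory`.
#' @param ... Unused.
#' @return The per-step record tibble.
#' @method tidy remc_trajectory
#' @export
tidy.remc_trajectory <- function(x, ...) x$steps

#' One-row summary of an REMC trajectory
#'
#' @param x An `remc_trajectory`.
#' @param ... Unused.
#' @return Tibble with run, step count, ladder size, per-move acceptance
#'   rates and the best end-simulation peptide.
#' @method glance remc_trajectory
#' @export
glance.remc_trajectory <- function(x, ...) {
  st <- x$steps
  mut <- st[st$move == "mutation" & st$step > 0, ]
  sw <- st[st$move == "swap", ]
  best <- select_best(x)
  tibble(
    run = x$meta$run,
    n_steps = x$meta$n_steps,
    n_replicas = length(x$meta$ladder),
    mutation_acceptance = if (nrow(mut)) mean(mut$accepted) else NA_real_,
    swap_acceptance = if (nrow(sw)) mean(sw$accepted) else NA_real_,
    best_sequence = best$sequence,
    best_score = best$score,
    best_kBT = best$kBT
  )
}

#' Tidy a campaign
#'
#' @param x An `remc_campaign`.
#' @param ... Unused.
#' @return The selected-peptides tibble (one row per run).
#' @method tidy remc_campaign
#' @export
tidy.remc_campaign <- function(x, ...) x$selected

#' Per-run summaries of a campaign
#'
#' @param x An `remc_campaign`.
#' @param ... Unused.
#' @return Tibble with one [glance.remc_trajectory()] row per run.
#' @method glance remc_campaign
#' @export
glance.remc_campaign <- function(x, ...) {
  purrr::map_dfr(x$trajectories, glance)
}

#' Tidy a rescoring result
#'
#' @param x A `rescore_result`.
#' @param ... Unused.
#' @return The retained-sample tibble (`run`, `step`, `score`).
#' @method tidy rescore_result
#' @export
tidy.rescore_result <- function(x, ...) x$samples

#' One-row summary of a rescoring result
#'
#' @param x A `rescore_result`.
#' @param ... Unused.
#' @method glance rescore_result
#' @export
glance.rescore_result <- function(x, ...) {
  tibble(peptide = x$name, sequence = x$sequence, site = x$site,
         mean = x$mean, sd = x$sd, sem = x$sem,
         sem_samples = x$sem_samples, sd_run_means = x$sd_run_means,
         n_samples = nrow(x$samples), n_runs = x$n_runs,
         n_steps = x$n_steps, retain_last = x$retain_last, kBT = x$kBT)
}

#' Tidy a theory-experiment comparison
#'
#' @param x A `theory_experiment`.
#' @param ... Unused.
#' @return The joined per-peptide tibble.
#' @method tidy theory_experiment
#' @export
tidy.theory_experiment <- function(x, ...) x$data

#' One-row summary of a theory-experiment comparison
#'
#' @param x A `theory_experiment`.
#' @param ... Unused.
#' @return Tibble with Pearson `r`, its p-value, the peptide counts and `rt`.
#' @method glance theory_experiment
#' @export
glance.theory_experiment <- function(x, ...) {
  tibble(r = x$r, p.value = x$cor_test$p.value,
         n = nrow(x$data), n_excluded = nrow(x$excluded), rt = x$rt)
}
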