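#' Mutation-off multi-docking rescoring
#'
#' Characterises a fixed sequence by running the optimisation kernel with the
#' mutation step switched off: each of `n_runs` independent chains draws a
#' fresh score sample for the same sequence at every step and applies
#' Metropolis acceptance at `kBT`, so the chain walks toward the low tail of
#' the backend's score distribution. The chain states of the last
#' `retain_last` steps of every run (duplicates included when proposals were
#' rejected) are the retained sample; their mean and SD (over all retained
#' samples) summarise the rescoring. The standard error of the mean is
#' estimated by batch means over the independent runs,
#' `sem = sd(per-run means) / sqrt(n_runs)`, because consecutive retained
#' states of one chain are strongly autocorrelated (rejected proposals
#' repeat the state) and the naive all-samples `sd/sqrt(n)` would understate
#' the error severalfold; that naive variant is still reported as
#' `sem_samples`. Defaults (10 runs of 100 steps at kBT = 0.6, retaining the
#' last 10 configurations, i.e. 100 samples) are the rescoring protocol of
#' the design study. `n_steps = 1, retain_last = 1` degenerates to
#' single-shot docking (one draw per run, no Monte Carlo selection).
#'
#' The first draw of each chain initialises the state; subsequent draws face
#' a Metropolis decision.
#'
#' @param sequence Residue string to rescore.
#' @param backend Scoring backend.
#' @param site Site label (`"binding"` or `"control"`).
#' @param kBT Acceptance temperature (kcal/mol).
#' @param n_runs Independent chains.
#' @param n_steps Score draws per chain.
#' @param retain_last How many final per-step states to retain per chain.
#' @param config Optional [docking_config()] for adapter backends.
#' @param seed Integer seed scoped to this rescoring.
#' @param name Peptide label carried into downstream tables.
#' @return A `rescore_result`: list with `samples` (tibble `run`, `step`,
#'   `score`), `mean`, `sd`, `sem` (batch means over runs), `sem_samples`,
#'   `sd_run_means` and the protocol parameters.
#' @export
#' @examples
#' land <- generate_landscape(length = 4, alphabet = c("A", "G", "Y", "R"),
#'                            noise_sd = 0, seed = 1)
#' rescore("AAAA", land, seed = 1)$mean
rescore <- function(sequence, backend, site = "binding",
                    kBT = 0.6, n_runs = 10, n_steps = 100, retain_last = 10,
                    config = NULL, seed = NULL, name = sequence) {
  stopifnot(n_runs >= 1, n_steps >= 1, retain_last >= 1)
  if (retain_last > n_steps) {
    abort("`retain_last` cannot exceed `n_steps`.", class = "pepremc_bad_config")
  }
  if (!is.finite(kBT) || kBT <= 0) {
    abort("`kBT` must be positive.", class = "pepremc_bad_temperature")
  }
  alphabet <- backend_alphabet(backend)
  sequence <- make_peptide(sequence, alphabet)
  if (!is.null(seed)) withr::local_seed(seed)

  idx <- encode_seq(sequence, alphabet)
  scorer <- make_scorer(backend, site, alphabet, config)
  keep_from <- n_steps - retain_last + 1L

  samples <- purrr::map_dfr(seq_len(n_runs), function(run) {
    states <- numeric(n_steps)
    s <- scorer(idx)
    if (is.na(s)) {
      abort("backend failed on the first draw of a rescoring chain.",
            class = "pepremc_backend_failure")
    }
    states[1] <- s
    if (n_steps > 1) {
      for (t in 2:n_steps) {
        prop <- scorer(idx)
        if (!is.na(prop) && runif(1) < min(1, exp(-(prop - s) / kBT))) {
          s <- prop
        }
        states[t] <- s
      }
    }
    tibble(run = run, step = keep_from:n_steps, score = states[keep_from:n_steps])
  })

  n <- nrow(samples)
  run_means <- tapply(samples$score, samples$run, mean)
  sd_run_means <- if (n_runs > 1) sd(run_means) else 0
  sem_samples <- if (n > 1) sd(samples$score) / sqrt(n) else 0
  structure(
    list(
      name = name, sequence = sequence, site = site,
      samples = samples,
      mean = mean(samples$score),
      sd = if (n > 1) sd(samples$score) else 0,
      sem = if (n_runs > 1) sd_run_means / sqrt(n_runs) else sem_samples,
      sem_samples = sem_samples,
      sd_run_means = sd_run_means,
      kBT = kBT, n_runs = as.integer(n_runs), n_steps = as.integer(n_steps),
      retain_last = as.integer(retain_last), seed = seed
    ),
    class = "rescore_result"
  )
}

#' @export
print.rescore_result <- function(x, ...) {
  cat(sprintf(
    "<rescore_result> %s (%s site): %.3f +/- %.3f kcal/mol (SD %.3f, %d samples)\n",
    x$name, x$site, x$mean, x$sem, x$sd, nrow(x$samples)))
  invisible(x)
}

#' Negative-control-corrected binding energy
#'
#' The corrected binding energy statistic
#' `BE = <E_binding site> - <E_no binding site>`: the mean rescored energy at
#' the designated binding site minus the mean at an experimentally validated
#' non-binding (negative control) site. Docking scores carry
#' sequence-dependent offsets that have nothing to do with the specific site;
#' differencing against the control cancels them. The reported uncertainty is
#' the sum of the two standard errors of the means (the convention used for
#' the published error bars); `err_method = "quadrature"` gives the
#' root-sum-of-squares alternative instead.
#'
#' @param binding,control `rescore_result`s for the same peptide at the two
#'   sites.
#' @param err_method `"sum"` (default) or `"quadrature"`.
#' @return A one-row `be_result` tibble: `peptide`, `sequence`,
#'   `mean_binding`, `sem_binding`, `mean_control`, `sem_control`, `be`,
#'   `err`.
#' @export
compute_be <- function(binding, control, err_method = c("sum", "quadrature")) {
  err_method <- match.arg(err_method)
  stopifnot(inherits(binding, "rescore_result"), inherits(control, "rescore_result"))
  if (!identical(binding$sequence, control$sequence)) {
    abort(sprintf("peptide mismatch: binding result is for %s, control for %s",
                  binding$sequence, control$sequence),
          class = "pepremc_peptide_mismatch")
  }
  err <- switch(err_method,
                sum = binding$sem + control$sem,
                quadrature = sqrt(binding$sem^2 + control$sem^2))
  out <- tibble(
    peptide = binding$name, sequence = binding$sequence,
    mean_binding = binding$mean, sem_binding = binding$sem,
    mean_control = control$mean, sem_control = control$sem,
    be = binding$mean - control$mean, err = err
  )
  class(out) <- c("be_result", class(out))
  out
}

#' Rank candidate peptides by corrected binding energy
#'
#' Orders a table of BE results ascending (most negative, i.e. best, first),
#' breaking ties by peptide name, and flags every entry whose
#' `[be - err, be + err]` interval overlaps the best entry's interval as
#' statistically unresolved from it (the best entry itself is flagged when
#' any other overlaps).
#'
#' @param results Data frame with columns `peptide`, `be`, `err` (e.g. rows
#'   from [compute_be()]).
#' @return A `be_ranking` tibble with `rank` and `unresolved` columns added.
#' @export
rank_candidates <- function(results) {
  results <- as_tibble(results)
  if (nrow(results) == 0) {
    abort("no candidates to rank.", class = "pepremc_empty_input")
  }
  stopifnot(all(c("peptide", "be", "err") %in% names(results)))
  out <- dplyr::arrange(results, .data$be, .data$peptide)
  out$rank <- seq_len(nrow(out))
  lo <- out$be - out$err
  hi <- out$be + out$err
  overlaps_best <- lo <= hi[1] & hi >= lo[1]
  overlaps_best[1] <- any(overlaps_best[-1])
  out$unresolved <- if (nrow(out) == 1) FALSE else overlaps_best
  class(out) <- c("be_ranking", class(out))
  out
}

#' Rescore a candidate table at both sites and rank by BE
#'
#' Convenience pipeline: for each candidate row, runs [rescore()] at the
#' binding and control sites (per-candidate seeds derived from `seed`),
#' computes [compute_be()], and returns the ranked table.
#'
#' @param candidates Data frame with columns `name` and `sequence` (e.g. from
#'   [read_peptide_fasta()]).
#' @param backend Scoring backend.
#' @param ... Passed to [rescore()] (kBT, n_runs, n_steps, retain_last).
#' @param binding_config,control_config Optional [docking_config()]s per site.
#' @param err_method Forwarded to [compute_be()].
#' @param seed Campaign seed for the per-candidate chains.
#' @return A `be_ranking` tibble.
#' @export
rescore_candidates <- function(candidates, backend, ...,
                               binding_config = NULL, control_config = NULL,
                               err_method = "sum", seed = NULL) {
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) {
    abort("empty candidate table.", class = "pepremc_empty_input")
  }
  stopifnot(all(c("name", "sequence") %in% names(candidates)))
  seeds <- if (!is.null(seed)) {
    withr::with_seed(seed, matrix(sample.int(.Machine$integer.max,
                                             2 * nrow(candidates)), ncol = 2))
  }
  rows <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    b <- rescore(candidates$sequence[i], backend, site = "binding", ...,
                 config = binding_config,
                 seed = if (!is.null(seeds)) seeds[i, 1],
                 name = candidates$name[i])
    cc <- rescore(candidates$sequence[i], backend, site = "control", ...,
                  config = control_config,
                  seed = if (!is.null(seeds)) seeds[i, 2],
                  name = candidates$name[i])
    compute_be(b, cc, err_method = err_method)
  })
  rank_candidates(rows)
}
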