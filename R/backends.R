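#' Docking box configuration for adapter backends
#'
#' Carries the search-box and sampling parameters an external docking engine
#' (e.g. AutoDock Vina) needs: a cubic box constraining the peptide to the
#' target pocket, centred on a chosen atom, with the engine's exhaustiveness
#' and energy-range settings. The synthetic landscape backend ignores this
#' metadata; external adapters receive it verbatim. Defaults are a 25 A cube
#' with exhaustiveness 10 and energy_range 4; the centre is target-specific
#' (for the maltose site of MBP it is the sulfur atom of Met330).
#'
#' @param box_center Numeric xyz centre in Angstrom.
#' @param box_size Numeric xyz edge lengths in Angstrom, all positive.
#' @param exhaustiveness Engine search effort (integer).
#' @param energy_range Energy window (kcal/mol) for retained poses.
#' @param site_label `"binding"` or `"control"`.
#' @param receptor Optional receptor structure path (PDB/PDBQT), never parsed
#'   by the core.
#' @return A `docking_config` object.
#' @export
docking_config <- function(box_center = c(0, 0, 0),
                           box_size = c(25, 25, 25),
                           exhaustiveness = 10L,
                           energy_range = 4,
                           site_label = c("binding", "control"),
                           receptor = NULL) {
  site_label <- match.arg(site_label)
  stopifnot(length(box_center) == 3, length(box_size) == 3)
  if (any(!is.finite(box_size)) || any(box_size <= 0)) {
    abort("`box_size` components must be positive.", class = "pepremc_bad_config")
  }
  structure(
    list(box_center = as.numeric(box_center), box_size = as.numeric(box_size),
         exhaustiveness = as.integer(exhaustiveness),
         energy_range = as.numeric(energy_range),
         site_label = site_label, receptor = receptor),
    class = "docking_config"
  )
}

#' Score a peptide sequence with a backend
#'
#' The scoring-backend contract. A backend takes a sequence and a site label
#' and returns one stochastic docking-like score observation: a list with
#' `value` (kcal/mol, more negative = better predicted binding), a fresh
#' opaque `pose_id`, and the echoed `site_label`. A backend that cannot
#' produce a pose must signal a condition of class
#' `"pepremc_backend_failure"`; the Monte Carlo engines treat that as a
#' rejected proposal, never as a crash.
#'
#' For the synthetic landscape the value is
#' `landscape_mean(sequence, site) + noise_sd[site] * z` with `z` a standard
#' normal draw; exactly one normal deviate is consumed per call regardless of
#' the noise setting, so draw order does not depend on noise.
#'
#' @param backend A scoring backend (`synthetic_landscape`, a replay backend,
#'   or a user adapter implementing this generic).
#' @param sequence Residue string.
#' @param site `"binding"` or `"control"`.
#' @param config Optional [docking_config()] metadata (ignored by the
#'   synthetic backend).
#' @param ... Passed to methods.
#' @return List with `value`, `pose_id`, `site_label`.
#' @export
score_sequence <- function(backend, sequence, site = "binding", config = NULL, ...) {
  UseMethod("score_sequence")
}

#' @export
score_sequence.synthetic_landscape <- function(backend, sequence,
                                               site = "binding",
                                               config = NULL, ...) {
  mu <- landscape_mean(backend, sequence, site)
  value <- mu + rnorm(1) * backend$noise_sd[[site]]
  list(value = value, pose_id = next_pose_id(), site_label = site)
}

#' Recorded-replay scoring backend
#'
#' Returns a pre-recorded list of score values in order, independent of the
#' sequence asked about; an `NA` in the recording simulates a backend failure
#' (no pose produced). Used to verify that the Monte Carlo engines depend
#' only on the backend contract, not on any particular backend, and to test
#' the failure-as-rejection semantics.
#'
#' @param values Numeric vector of scores to replay; `NA` entries fail.
#' @return A `replay_backend` object. Its `$log` environment records every
#'   sequence scored.
#' @export
replay_backend <- function(values) {
  stopifnot(is.numeric(values), length(values) > 0)
  env <- new.env(parent = emptyenv())
  env$cursor <- 0L
  env$values <- as.numeric(values)
  env$sequences <- character(0)
  structure(list(log = env), class = "replay_backend")
}

#' @export
score_sequence.replay_backend <- function(backend, sequence, site = "binding",
                                          config = NULL, ...) {
  env <- backend$log
  env$cursor <- env$cursor + 1L
  if (env$cursor > length(env$values)) {
    abort("replay backend exhausted its recording.",
          class = "pepremc_backend_failure")
  }
  v <- env$values[env$cursor]
  if (is.na(v)) {
    abort("replay backend: no pose produced.",
          class = "pepremc_backend_failure")
  }
  env$sequences <- c(env$sequences, sequence)
  list(value = v, pose_id = next_pose_id(), site_label = site)
}

backend_alphabet <- function(backend, default = aa_alphabet()) {
  if (inherits(backend, "synthetic_landscape")) backend$alphabet else default
}

# Scoring closure over integer-encoded sequences used by the engine hot
# loops. Returns NA_real_ on backend failure (after warning).
make_scorer <- function(backend, site, alphabet, config = NULL) {
  if (inherits(backend, "synthetic_landscape")) {
    terms <- backend$terms
    use_control_terms <- site == "control" && !is.null(backend$control_terms)
    if (use_control_terms) terms <- backend$control_terms
    offset <- if (site == "control" && !use_control_terms) backend$control_offset else 0
    nsd <- backend$noise_sd[[site]]
    epi <- if (!use_control_terms) backend$epistasis else NULL
    L <- backend$length
    pos_seq <- seq_len(L)
    if (is.null(epi)) {
      function(idx) sum(terms[cbind(pos_seq, idx)]) + offset + rnorm(1) * nsd
    } else {
      ab <- backend$alphabet
      function(idx) {
        sum(terms[cbind(pos_seq, idx)]) + epistasis_sum(epi, ab, idx) +
          offset + rnorm(1) * nsd
      }
    }
  } else {
    function(idx) {
      seq_chr <- decode_seq(idx, alphabet)
      tryCatch(
        score_sequence(backend, seq_chr, site = site, config = config)$value,
        pepremc_backend_failure = function(cnd) {
          warn(paste0("backend failure treated as rejected proposal: ",
                      conditionMessage(cnd)),
               class = "pepremc_backend_failure_warning")
          NA_real_
        }
      )
    }
  }
}
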