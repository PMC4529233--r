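#' Campaign configuration
#'
#' Programmatic constructor for a full run configuration. Defaults mirror the
#' reference protocol: octapeptides evolved from octa-alanine for 100 steps
#' on the 0.2/0.4/0.6 kcal/mol ladder, 9 independent runs; rescoring with 10
#' runs of 100 steps at kBT = 0.6 retaining the last 10 configurations;
#' RT = 0.593 kcal/mol for affinity conversions.
#'
#' @param length Peptide chain length.
#' @param start_sequence Starting sequence (defaults to poly-alanine of
#'   `length`).
#' @param ladder Temperature ladder (kcal/mol).
#' @param n_steps Optimisation steps per run.
#' @param n_runs Optimisation runs per campaign.
#' @param seed Campaign seed.
#' @param backend Backend block: a list with `type` (`"synthetic"`,
#'   `"replay"` or `"external"`) plus type-specific fields (see
#'   [build_backend()]).
#' @param sites Optional named list of [docking_config()]-style blocks for
#'   the `binding` and `control` sites (adapter metadata).
#' @param rescore Rescoring block: `kBT`, `n_runs`, `n_steps`, `retain_last`.
#' @param rt Thermal energy for affinity conversions (kcal/mol).
#' @return A validated `campaign_config` object.
#' @export
campaign_config <- function(length = 8,
                            start_sequence = strrep("A", length),
                            ladder = c(0.2, 0.4, 0.6),
                            n_steps = 100,
                            n_runs = 9,
                            seed = 1,
                            backend = list(type = "synthetic"),
                            sites = NULL,
                            rescore = list(kBT = 0.6, n_runs = 10,
                                           n_steps = 100, retain_last = 10),
                            rt = 0.593) {
  cfg <- structure(
    list(length = length, start_sequence = start_sequence, ladder = ladder,
         n_steps = n_steps, n_runs = n_runs, seed = seed, backend = backend,
         sites = sites, rescore = rescore, rt = rt),
    class = "campaign_config"
  )
  validate_campaign_config(cfg)
}

validate_campaign_config <- function(cfg) {
  problems <- character(0)
  need <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)

  need(is.numeric(cfg$length) && length(cfg$length) == 1 && cfg$length >= 1 &&
         cfg$length == floor(cfg$length),
       "`length` must be a positive integer")
  need(is.character(cfg$start_sequence) && length(cfg$start_sequence) == 1 &&
         nzchar(cfg$start_sequence),
       "`start_sequence` must be a non-empty string")
  if (is.character(cfg$start_sequence) && is.numeric(cfg$length) &&
      length(cfg$start_sequence) == 1 &&
      nchar(cfg$start_sequence) != cfg$length) {
    problems <- c(problems, "`start_sequence` length must equal `length`")
  }
  need(is.numeric(cfg$ladder) && length(cfg$ladder) >= 1 &&
         all(is.finite(cfg$ladder)) && all(cfg$ladder > 0) &&
         !anyDuplicated(cfg$ladder),
       "`ladder` must be distinct positive temperatures")
  need(is.numeric(cfg$n_steps) && length(cfg$n_steps) == 1 && cfg$n_steps >= 0,
       "`n_steps` must be a non-negative integer")
  need(is.numeric(cfg$n_runs) && length(cfg$n_runs) == 1 && cfg$n_runs >= 1,
       "`n_runs` must be a positive integer")
  need(is.numeric(cfg$seed) && length(cfg$seed) == 1,
       "`seed` must be a single integer")
  need(is.list(cfg$backend) && !is.null(cfg$backend$type),
       "`backend` must be a block with a `type` field")
  if (is.list(cfg$rescore)) {
    rs <- cfg$rescore
    need(is.numeric(rs$kBT %||% 0.6) && (rs$kBT %||% 0.6) > 0,
         "`rescore.kBT` must be positive")
    if (!is.null(rs$retain_last) && !is.null(rs$n_steps) &&
        rs$retain_last > rs$n_steps) {
      problems <- c(problems, "`rescore.retain_last` cannot exceed `rescore.n_steps`")
    }
  } else {
    problems <- c(problems, "`rescore` must be a block")
  }
  need(is.numeric(cfg$rt) && cfg$rt > 0, "`rt` must be positive")

  if (length(problems) > 0) {
    abort(c("invalid campaign configuration:", setNames(problems, rep("x", length(problems)))),
          class = "pepremc_bad_config")
  }
  cfg
}

#' Read a campaign configuration from YAML
#'
#' Key-value run configuration. `ladder` and `backend` must be stated
#' explicitly (a config file is a complete record of a campaign); every other
#' field falls back to the protocol defaults of [campaign_config()].
#' Validation reports all offending fields by name.
#'
#' @param path YAML file path.
#' @return A validated `campaign_config`.
#' @export
read_campaign_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  missing <- setdiff(c("ladder", "backend"), names(raw))
  if (length(missing) > 0) {
    abort(c("invalid campaign configuration:",
            setNames(sprintf("missing required field `%s`", missing),
                     rep("x", length(missing)))),
          class = "pepremc_bad_config")
  }
  defaults <- list(length = 8, n_steps = 100, n_runs = 9, seed = 1,
                   rescore = list(kBT = 0.6, n_runs = 10, n_steps = 100,
                                  retain_last = 10),
                   rt = 0.593)
  merged <- utils::modifyList(defaults, raw)
  if (is.null(merged$start_sequence)) {
    merged$start_sequence <- strrep("A", merged$length)
  }
  merged$ladder <- as.numeric(unlist(merged$ladder))
  cfg <- structure(merged[c("length", "start_sequence", "ladder", "n_steps",
                            "n_runs", "seed", "backend", "sites", "rescore",
                            "rt")],
                   class = "campaign_config")
  validate_campaign_config(cfg)
}

#' Build a scoring backend from a config block
#'
#' Backend `type`s:
#' * `"synthetic"` — either `landscape: <path>` (a [write_landscape()] TSV)
#'   or a `generate:` sub-block of [generate_landscape()] arguments.
#' * `"replay"` — `values:` a numeric vector of recorded scores.
#' * `"external"` — adapter metadata only; constructing one errors with a
#'   pointer to the [score_sequence()] contract, since no docking engine is
#'   bundled.
#'
#' @param cfg A `campaign_config` or a backend block list.
#' @return A scoring backend object.
#' @export
build_backend <- function(cfg) {
  block <- if (inherits(cfg, "campaign_config")) cfg$backend else cfg
  type <- block$type %||% "synthetic"
  switch(
    type,
    synthetic = {
      if (!is.null(block$landscape)) {
        read_landscape(block$landscape)
      } else {
        gen <- block$generate %||% list()
        do.call(generate_landscape, gen)
      }
    },
    replay = replay_backend(as.numeric(unlist(block$values))),
    external = abort(
      paste("no external docking engine is bundled;",
            "implement a score_sequence() method for your adapter",
            "(the docking_config block carries box/exhaustiveness metadata)."),
      class = "pepremc_bad_config"),
    abort(sprintf("unknown backend type '%s'", type), class = "pepremc_bad_config")
  )
}

#' Stable hash of a configuration
#'
#' Used to stamp output files so results can be traced to the exact
#' configuration that produced them.
#'
#' @param cfg Any R object.
#' @return Character hash.
#' @export
config_hash <- function(cfg) {
  rlang::hash(cfg)
}
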