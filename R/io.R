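output_header <- function(seed = NULL, hash = NULL) {
  c(sprintf("# pepremc_version=%s", as.character(packageVersion("pepremc"))),
    sprintf("# seed=%s", if (is.null(seed)) "NA" else format(seed)),
    sprintf("# config_hash=%s", hash %||% "NA"))
}

#' Write a trajectory (or campaign) as TSV
#'
#' One row per recorded move (columns `run`, `step`, `replica`, `partner`,
#' `kBT`, `move`, `sequence`, `score`, `accepted`), preceded by `#` header
#' comments carrying the tool version, seed and configuration hash. Output is
#' byte-identical for identical inputs: no timestamps, fixed number
#' formatting.
#'
#' @param x An `remc_trajectory` or `remc_campaign`.
#' @param path Output TSV path.
#' @param hash Optional configuration hash to stamp into the header.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path, hash = NULL) {
  steps <- if (inherits(x, "remc_campaign")) {
    purrr::map_dfr(x$trajectories, "steps")
  } else if (inherits(x, "remc_trajectory")) {
    x$steps
  } else {
    abort("`x` must be an remc_trajectory or remc_campaign.",
          class = "pepremc_bad_config")
  }
  writeLines(output_header(seed = x$meta$seed, hash = hash), path)
  readr::write_tsv(steps, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a campaign's selected peptides as FASTA
#'
#' One record per run's best end-simulation peptide, with run index, score,
#' temperature, seed, tool version and config hash as `key=value` metadata on
#' the description line (FASTA has no comment lines).
#'
#' @param campaign An `remc_campaign`.
#' @param path Output FASTA path.
#' @param hash Optional configuration hash.
#' @return `path`, invisibly.
#' @export
write_selected_fasta <- function(campaign, path, hash = NULL) {
  stopifnot(inherits(campaign, "remc_campaign"))
  sel <- campaign$selected
  x <- tibble(
    name = sprintf("candidate_run%d", sel$run),
    sequence = sel$sequence,
    run = sel$run,
    score = sprintf("%.6f", sel$score),
    kBT = format(sel$kBT)
  )
  write_peptide_fasta(
    x, path,
    metadata = c(
      pepremc_version = as.character(packageVersion("pepremc")),
      seed = if (is.null(campaign$meta$seed)) "NA" else format(campaign$meta$seed),
      config_hash = hash %||% "NA"
    )
  )
}

#' Write a BE ranking table as TSV
#'
#' Per-peptide binding/control means and SEMs, corrected binding energy,
#' summed error, rank and unresolved flag, with `#` provenance header.
#'
#' @param ranking A `be_ranking` (or compatible data frame).
#' @param path Output TSV path.
#' @param seed,hash Optional provenance stamped into the header.
#' @return `path`, invisibly.
#' @export
write_be_table <- function(ranking, path, seed = NULL, hash = NULL) {
  writeLines(output_header(seed = seed, hash = hash), path)
  readr::write_tsv(as_tibble(ranking), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
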