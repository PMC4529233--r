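#' Convert a dissociation constant to binding free energy
#'
#' `delta_g = rt * ln(kd)` with `kd` in molar units, so sub-molar constants
#' give negative (favourable) free energies. The default thermal energy
#' `rt = 0.593` kcal/mol corresponds to room temperature (298 K); `rt = 0.6`
#' is a common rounded convention and is exposed because published affinity
#' ranges are sometimes quoted on that scale.
#'
#' @param kd Dissociation constant(s), molar. Must be positive.
#' @param rt Thermal energy RT in kcal/mol.
#' @return Free energy in kcal/mol (vectorised).
#' @export
#' @examples
#' delta_g_from_kd(7.2e-5)          # MBP-9-scale affinity, RT = 0.593
#' delta_g_from_kd(4.2e-3, rt = 0.6)
delta_g_from_kd <- function(kd, rt = 0.593) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    abort("`kd` must be positive and finite (molar units).",
          class = "pepremc_bad_kd")
  }
  stopifnot(rt > 0)
  rt * log(kd)
}

#' @rdname delta_g_from_kd
#' @param delta_g Free energy in kcal/mol.
#' @export
kd_from_delta_g <- function(delta_g, rt = 0.593) {
  stopifnot(rt > 0)
  exp(delta_g / rt)
}

#' Propagated uncertainty of the converted free energy
#'
#' The convention `sigma_delta_g = 0.434 * (sigma_kd / kd)`: the relative
#' uncertainty of the dissociation constant scaled by log10(e) = 0.434,
#' i.e. the absolute uncertainty of log10(kd), reported in kcal/mol. Applied
#' literally as stated in the source convention (note it omits the
#' 2.303 * RT factor that a first-order propagation of `rt * ln(kd)` would
#' carry; see the package vignette).
#'
#' @param kd Dissociation constant(s), molar (or any unit, the ratio is
#'   dimensionless).
#' @param sigma_kd Uncertainty of `kd`, same units.
#' @return Uncertainty in kcal/mol (vectorised).
#' @export
#' @examples
#' sigma_delta_g(72, 3) # 0.434 * 3/72
sigma_delta_g <- function(kd, sigma_kd) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    abort("`kd` must be positive and finite.", class = "pepremc_bad_kd")
  }
  if (any(sigma_kd < 0)) {
    abort("`sigma_kd` must be non-negative.", class = "pepremc_bad_kd")
  }
  0.434 * sigma_kd / kd
}

kd_unit_factors <- c("M" = 1, "mM" = 1e-3, "uM" = 1e-6, "μM" = 1e-6,
                     "µM" = 1e-6, "nM" = 1e-9, "pM" = 1e-12)

#' Parse a dissociation constant with unit suffix
#'
#' Accepts values like `"72 uM"`, `"4200 μM"`, `"1 M"`; the unit suffix is
#' required (a bare number is ambiguous and rejected). Vectorised; `NA`
#' inputs stay `NA`.
#'
#' @param text Character vector of value-with-unit strings.
#' @return Numeric vector in molar units.
#' @export
#' @examples
#' parse_kd(c("72 uM", "1 M", "200nM"))
parse_kd <- function(text) {
  vapply(text, function(x) {
    if (is.na(x)) return(NA_real_)
    m <- regexec("^\\s*([-+0-9.eE]+)\\s*([A-Za-zμµ]*)\\s*$", x)[[1]]
    parts <- regmatches(x, list(m))[[1]]
    if (length(parts) < 3 || !nzchar(parts[2]) ||
        is.na(suppressWarnings(as.numeric(parts[2])))) {
      abort(sprintf("cannot parse dissociation constant '%s'", x),
            class = "pepremc_bad_kd")
    }
    unit <- parts[3]
    if (!nzchar(unit)) {
      abort(sprintf("missing unit on dissociation constant '%s' (use M, mM, uM, nM or pM)", x),
            class = "pepremc_missing_unit")
    }
    if (!unit %in% names(kd_unit_factors)) {
      abort(sprintf("unknown dissociation-constant unit '%s' in '%s'", unit, x),
            class = "pepremc_unknown_unit")
    }
    as.numeric(parts[2]) * kd_unit_factors[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read an experimental affinity table
#'
#' Delimited text (TSV, `#` comments allowed) with columns `peptide`, `kd`,
#' and optionally `sequence` and `sigma_kd`; `kd`/`sigma_kd` are
#' value-with-unit strings. Non-numeric entries (e.g. `"CBE"` for constants
#' that cannot be estimated, or `"No binding"`) are kept verbatim and handled
#' by [convert_affinities()].
#'
#' @param path File path.
#' @return Tibble of the raw table.
#' @export
read_affinity_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(tab) == 0) {
    abort(sprintf("affinity table '%s' has no rows", path),
          class = "pepremc_empty_input")
  }
  if (!all(c("peptide", "kd") %in% names(tab))) {
    abort("affinity table needs at least columns `peptide` and `kd`.",
          class = "pepremc_bad_config")
  }
  tab
}

#' Convert an affinity table to free energies
#'
#' Parses each row's dissociation constant, converts it to a binding free
#' energy with [delta_g_from_kd()] and propagates its uncertainty with
#' [sigma_delta_g()]. Rows whose affinity is not quantifiable (entries such
#' as `"CBE"` or `"No binding"`) are retained with `quantifiable = FALSE` and
#' the original text as `status`, so they can be listed separately rather
#' than silently dropped.
#'
#' @param x Data frame with columns `peptide`, `kd` and optionally
#'   `sigma_kd` (value-with-unit strings or numeric molar values).
#' @param rt Thermal energy RT in kcal/mol.
#' @return Tibble with `kd_molar`, `sigma_kd_molar`, `delta_g`,
#'   `sigma_delta_g`, `rt`, `quantifiable`, `status` columns added.
#' @export
convert_affinities <- function(x, rt = 0.593) {
  x <- as_tibble(x)
  if (nrow(x) == 0) abort("empty affinity table.", class = "pepremc_empty_input")
  stopifnot(all(c("peptide", "kd") %in% names(x)))
  has_sigma <- "sigma_kd" %in% names(x)

  parse_one <- function(v) {
    if (is.numeric(v)) return(v)
    tryCatch(parse_kd(v), pepremc_bad_kd = function(e) NA_real_)
  }
  out <- x
  out$kd_molar <- vapply(x$kd, parse_one, numeric(1), USE.NAMES = FALSE)
  out$sigma_kd_molar <- if (has_sigma) {
    vapply(x$sigma_kd, parse_one, numeric(1), USE.NAMES = FALSE)
  } else {
    NA_real_
  }
  out$quantifiable <- !is.na(out$kd_molar)
  out$status <- ifelse(out$quantifiable, "converted", as.character(x$kd))
  out$delta_g <- ifelse(out$quantifiable,
                        rt * log(out$kd_molar), NA_real_)
  out$sigma_delta_g <- ifelse(out$quantifiable & !is.na(out$sigma_kd_molar),
                              0.434 * out$sigma_kd_molar / out$kd_molar,
                              NA_real_)
  out$rt <- rt
  out
}

#' Compare computed binding energies with experimental affinities
#'
#' Joins a corrected-binding-energy table with an experimental affinity table
#' by peptide name, converts the affinities to free energies, and reports the
#' Pearson correlation between the two energy scales. Peptides without a
#' quantifiable affinity are excluded from the correlation and listed
#' separately.
#'
#' @param be_table Data frame with columns `peptide`, `be`, and optionally
#'   `err` (kcal/mol), e.g. a [rank_candidates()] result.
#' @param affinity_table Data frame accepted by [convert_affinities()].
#' @param rt Thermal energy RT in kcal/mol.
#' @return A `theory_experiment` object: list with `data` (the joined
#'   per-peptide table), `excluded` (non-quantifiable rows), `r`, and the
#'   full `cor_test`.
#' @export
compare_theory_experiment <- function(be_table, affinity_table, rt = 0.593) {
  be_table <- as_tibble(be_table)
  stopifnot(all(c("peptide", "be") %in% names(be_table)))
  conv <- convert_affinities(affinity_table, rt = rt)
  usable <- conv[conv$quantifiable, ]
  joined <- dplyr::inner_join(
    be_table[, intersect(c("peptide", "sequence", "be", "err"), names(be_table))],
    usable[, c("peptide", "kd_molar", "sigma_kd_molar", "delta_g", "sigma_delta_g")],
    by = "peptide"
  )
  joined <- joined[is.finite(joined$be) & is.finite(joined$delta_g), ]
  if (nrow(joined) < 2) {
    abort("need at least 2 peptides with finite values in both tables.",
          class = "pepremc_insufficient_overlap")
  }
  ct <- suppressWarnings(cor.test(joined$be, joined$delta_g))
  structure(
    list(data = joined,
         excluded = conv[!conv$quantifiable, ],
         r = unname(ct$estimate),
         cor_test = ct,
         rt = rt),
    class = "theory_experiment"
  )
}

#' @export
print.theory_experiment <- function(x, ...) {
  cat(sprintf(
    "<theory_experiment> %d peptides compared (%d excluded), Pearson r = %.3f\n",
    nrow(x$data), nrow(x$excluded), x$r))
  print(x$data)
  invisible(x)
}
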