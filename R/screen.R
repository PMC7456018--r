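# cfDNA tumor-variant screening: quality-control, somatic multi-focus, and
# germline allele-fraction filters, plus per-patient and cohort summaries.
#
# All three filters are row subsets on exact (chrom, pos, ref, alt)
# identity, so they are idempotent, commute, and never grow the call set.

#' Screening filter configuration
#'
#' @param min_depth Minimum read depth at the variant site (default 500).
#' @param min_alt_reads Minimum reads supporting the alternate allele
#'   (default 5).
#' @param germline_af_max Allele fractions at or above this bound are
#'   treated as presumptively germline and removed; the bound is strict
#'   (`af < germline_af_max`), default 0.20.
#' @param min_foci Minimum number of distinct tumor foci a variant must be
#'   called in (default 2; multi-focus presence is evidence of clonality).
#' @return A `screen_config` list.
#' @export
screen_config <- function(min_depth = 500, min_alt_reads = 5,
                          germline_af_max = 0.20, min_foci = 2) {
  stopifnot(min_depth >= 0, min_alt_reads >= 0,
            germline_af_max > 0, germline_af_max <= 1, min_foci >= 1)
  structure(
    list(min_depth = min_depth, min_alt_reads = min_alt_reads,
         germline_af_max = germline_af_max, min_foci = min_foci),
    class = "screen_config"
  )
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf(
    "<screen_config> depth >= %g, alt reads >= %g, AF < %g, foci >= %g\n",
    x$min_depth, x$min_alt_reads, x$germline_af_max, x$min_foci
  ))
  invisible(x)
}

#' Quality-control filter on depth and alt-read support
#'
#' Retains calls with `depth >= min_depth` and
#' `alt_reads >= min_alt_reads`.
#'
#' @param calls Variant call set with `depth` and `alt_reads` columns.
#' @param config A [screen_config()].
#' @return Filtered call set.
#' @export
qc_filter <- function(calls, config = screen_config()) {
  miss <- setdiff(c("depth", "alt_reads"), names(calls))
  if (length(miss) > 0) {
    abort(paste0("Calls missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  filter(calls, .data$depth >= config$min_depth,
         .data$alt_reads >= config$min_alt_reads)
}

#' Somatic multi-focus filter
#'
#' Retains cfDNA calls whose variant is called in at least `min_foci`
#' distinct tumor foci and absent from the matched normal. Presence is an
#' exact `(chrom, pos, ref, alt)` match; no fuzzy indel matching.
#'
#' @param cf_calls cfDNA variant call set.
#' @param tumor_calls Per-focus tumor call set(s): a tibble with a
#'   `focus_id` column covering all foci.
#' @param normal_calls Matched normal call set.
#' @param config A [screen_config()].
#' @return Filtered cfDNA call set.
#' @export
somatic_multifoci_filter <- function(cf_calls, tumor_calls, normal_calls,
                                     config = screen_config()) {
  key <- c("chrom", "pos", "ref", "alt")
  foci_n <- summarise(
    group_by(tumor_calls, dplyr::across(dplyr::all_of(key))),
    n_foci = n_distinct(.data$focus_id),
    .groups = "drop"
  )
  keep <- filter(foci_n, .data$n_foci >= config$min_foci)
  out <- semi_join(cf_calls, keep, by = key)
  anti_join(out, normal_calls, by = key)
}

#' Germline allele-fraction filter
#'
#' Retains calls with `allele_fraction` strictly below the germline bound
#' (default 20%): heterozygous germline variants sit near 50% in cfDNA,
#' far above tumor-derived fractions.
#'
#' @param calls Variant call set with `allele_fraction`.
#' @param config A [screen_config()].
#' @return Filtered call set.
#' @export
germline_af_filter <- function(calls, config = screen_config()) {
  if (!"allele_fraction" %in% names(calls)) {
    abort("Calls missing required column: allele_fraction")
  }
  filter(calls, .data$allele_fraction < config$germline_af_max)
}

#' Screen one patient's cfDNA against tumor foci and normal
#'
#' Applies the QC, somatic multi-focus, and germline allele-fraction
#' filters in sequence (the filters commute, so the order is
#' presentational). Filter settings are echoed in the `config` attribute
#' for provenance.
#'
#' @inheritParams somatic_multifoci_filter
#' @return Detected tumor variants in cfDNA, with the screen configuration
#'   attached as attribute `config`.
#' @export
screen_patient <- function(cf_calls, tumor_calls, normal_calls,
                           config = screen_config()) {
  out <- qc_filter(cf_calls, config)
  out <- somatic_multifoci_filter(out, tumor_calls, normal_calls, config)
  out <- germline_af_filter(out, config)
  attr(out, "config") <- config
  out
}

#' Cohort-level screening summary
#'
#' Summarizes detected variants per patient and across the cohort, and
#' tests (Spearman) whether per-patient median allele fraction tracks
#' supplied clinical covariates.
#'
#' @param detected Detected-variant tibble with `patient_id` and
#'   `allele_fraction` (e.g. rows of [screen_patient()] results bound
#'   together). Patients with zero detected variants may be included as
#'   zero-row groups only if listed in `patients`.
#' @param patients Optional character vector of all screened patients, so
#'   patients with no detections appear with `n_detected = 0`.
#' @param covariates Optional tibble `patient_id` plus numeric covariate
#'   columns (e.g. age, stage, Gleason score).
#' @return An object of class `screen_summary` with `patients` (per-patient
#'   counts and AF summaries), `cohort` (one-row min/median/max of counts
#'   and AFs), and `correlations` (Spearman rho and p per covariate).
#' @export
summarize_screen <- function(detected, patients = NULL, covariates = NULL) {
  per <- summarise(
    group_by(detected, .data$patient_id),
    n_detected = n(),
    median_af = median(.data$allele_fraction),
    min_af = min(.data$allele_fraction),
    max_af = max(.data$allele_fraction),
    .groups = "drop"
  )
  if (!is.null(patients)) {
    missing <- setdiff(patients, per$patient_id)
    if (length(missing) > 0) {
      per <- bind_rows(per, tibble(patient_id = missing, n_detected = 0L,
                                   median_af = NA_real_, min_af = NA_real_,
                                   max_af = NA_real_))
    }
    per <- arrange(per, .data$patient_id)
  }
  pos <- filter(per, .data$n_detected > 0)
  cohort <- tibble(
    n_patients = nrow(per),
    n_patients_detected = nrow(pos),
    min_detected = if (nrow(per)) min(per$n_detected) else NA_integer_,
    median_detected = if (nrow(per)) median(per$n_detected) else NA_real_,
    max_detected = if (nrow(per)) max(per$n_detected) else NA_integer_,
    min_af = if (nrow(detected)) min(detected$allele_fraction) else NA_real_,
    median_af = if (nrow(detected)) median(detected$allele_fraction) else NA_real_,
    max_af = if (nrow(detected)) max(detected$allele_fraction) else NA_real_
  )
  correlations <- tibble(covariate = character(), rho = numeric(),
                         p_value = numeric())
  if (!is.null(covariates)) {
    cv <- inner_join(pos, covariates, by = "patient_id")
    vars <- setdiff(names(covariates), "patient_id")
    correlations <- purrr::map_dfr(vars, function(v) {
      ok <- is.finite(cv[[v]]) & is.finite(cv$median_af)
      if (sum(ok) < 3) {
        return(tibble(covariate = v, rho = NA_real_, p_value = NA_real_))
      }
      ct <- suppressWarnings(
        cor.test(cv$median_af[ok], cv[[v]][ok], method = "spearman")
      )
      tibble(covariate = v, rho = unname(ct$estimate), p_value = ct$p.value)
    })
  }
  structure(
    list(patients = per, cohort = cohort, correlations = correlations),
    class = "screen_summary"
  )
}

#' @export
print.screen_summary <- function(x, ...) {
  co <- x$cohort
  cat(sprintf(
    "<screen_summary> %d patients (%d with detections); detected per patient: min %s, median %s, max %s\n",
    co$n_patients, co$n_patients_detected, co$min_detected,
    co$median_detected, co$max_detected
  ))
  if (is.finite(co$median_af %||% NA)) {
    cat(sprintf("  allele fraction: min %.4f, median %.4f, max %.4f\n",
                co$min_af, co$median_af, co$max_af))
  }
  invisible(x)
}
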