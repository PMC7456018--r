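# Comparison panels and in-silico capture evaluation against per-focus
# somatic variant call sets.
#
# A variant call set is a tibble with columns patient_id, focus_id, chrom,
# pos, ref, alt and, where downstream filters need them, allele_fraction,
# depth, alt_reads.

#' Build a recurrence ("frequency") comparison panel
#'
#' Panel members are the unique variants carried by at least `min_donors`
#' distinct donors of the training catalog (default 2, i.e. frequency
#' greater than one donor); probes are built as in [build_probes()].
#'
#' @param mut Mutation tibble (records with `donor_id`).
#' @param min_donors Minimum number of distinct carriers (default 2).
#' @param flank Probe flank in bp (default 175).
#' @return A `probe_panel`.
#' @export
build_frequency_panel <- function(mut, min_donors = 2, flank = 175) {
  uv <- distinct_variants(mut)
  build_probes(filter(uv, .data$n_donors >= min_donors), flank = flank)
}

#' Build a gene-centric comparison panel
#'
#' Probes are the merged union of the coding intervals of the listed genes
#' (the usual design of clinically available cancer gene panels). Gene
#' names that do not resolve in the coding model are reported with a
#' warning; if none resolve, an error is raised.
#'
#' @param gene_list Character vector of gene names (duplicates ignored).
#' @param coding_model Tibble `gene, chrom, start, end` of coding intervals,
#'   1-based inclusive.
#' @return A `probe_panel` with no member mutations.
#' @export
build_gene_panel <- function(gene_list, coding_model) {
  gene_list <- unique(gene_list)
  need <- c("gene", "chrom", "start", "end")
  miss <- setdiff(need, names(coding_model))
  if (length(miss) > 0) {
    abort(paste0("coding_model missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  hit <- coding_model[coding_model$gene %in% gene_list, , drop = FALSE]
  unresolved <- setdiff(gene_list, hit$gene)
  if (nrow(hit) == 0) abort("None of the listed genes resolve in the coding model.")
  if (length(unresolved) > 0) {
    warn(paste0(length(unresolved), " gene(s) not in the coding model: ",
                paste(head(unresolved, 5), collapse = ", ")))
  }
  gr <- GenomicRanges::GRanges(hit$chrom,
                               IRanges::IRanges(hit$start, hit$end))
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  probes <- tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  )
  structure(
    list(probes = probes,
         members = tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character()),
         flank = 0, footprint_bp = sum(probes$end - probes$start)),
    class = "probe_panel"
  )
}

#' In-silico capture of a variant call set by a panel
#'
#' A variant is captured when its 1-based reference span
#' `[pos, pos + nchar(ref) - 1]` intersects any probe interval by at least
#' one base (hybrid capture pulls any overlapping fragment, so indels
#' grazing a probe edge count).
#'
#' @param calls Variant call set tibble.
#' @param panel A `probe_panel`.
#' @return `calls` with a logical `captured` column.
#' @export
in_silico_capture <- function(calls, panel) {
  stopifnot(inherits(panel, "probe_panel"))
  if (nrow(calls) == 0) {
    calls$captured <- logical(0)
    return(as_tibble(calls))
  }
  shared <- intersect(unique(calls$chrom), unique(panel$probes$chrom))
  if (length(shared) == 0 && nrow(panel$probes) > 0) {
    abort(paste0(
      "No chromosome names shared between calls and panel (calls e.g. ",
      paste(head(unique(calls$chrom), 3), collapse = ", "),
      "; panel e.g. ",
      paste(head(unique(panel$probes$chrom), 3), collapse = ", "), ")."
    ))
  }
  calls$captured <- FALSE
  if (nrow(panel$probes) > 0) {
    gr_c <- GenomicRanges::GRanges(
      calls$chrom,
      IRanges::IRanges(calls$pos, calls$pos + nchar(calls$ref) - 1L)
    )
    gr_p <- GenomicRanges::GRanges(
      panel$probes$chrom,
      IRanges::IRanges(panel$probes$start + 1L, panel$probes$end)
    )
    calls$captured <- GenomicRanges::countOverlaps(gr_c, gr_p) > 0
  }
  as_tibble(calls)
}

#' Per-focus capture report
#'
#' Runs [in_silico_capture()] and summarizes captured and total variant
#' counts per (patient, focus).
#'
#' @inheritParams in_silico_capture
#' @return Tibble `patient_id, focus_id, captured_count, total_count`.
#' @export
capture_report <- function(calls, panel) {
  cap <- in_silico_capture(calls, panel)
  summarise(
    group_by(cap, .data$patient_id, .data$focus_id),
    captured_count = sum(.data$captured),
    total_count = n(),
    .groups = "drop"
  )
}

#' Compare two panels' capture counts
#'
#' Paired two-sided t-test on per-focus captured counts of two capture
#' reports over the same (patient, focus) units. With fewer than two pairs
#' the statistic is undefined and flagged rather than computed. A Welch
#' two-sample test is available as an alternative.
#'
#' @param report_a,report_b Capture reports from [capture_report()], same
#'   (patient, focus) keys.
#' @param method `"paired"` (default) or `"welch"`.
#' @return One-row tibble `n_pairs, t, df, p_value, undefined`.
#' @export
compare_panels <- function(report_a, report_b,
                           method = c("paired", "welch")) {
  method <- match.arg(method)
  a <- arrange(report_a, .data$patient_id, .data$focus_id)
  b <- arrange(report_b, .data$patient_id, .data$focus_id)
  if (nrow(a) != nrow(b) ||
      !all(a$patient_id == b$patient_id & a$focus_id == b$focus_id)) {
    abort("Reports do not cover the same (patient, focus) units.")
  }
  n <- nrow(a)
  if (n < 2) {
    return(tibble(n_pairs = n, t = NA_real_, df = NA_real_,
                  p_value = NA_real_, undefined = TRUE))
  }
  if (method == "paired" && all(a$captured_count == b$captured_count)) {
    # zero differences: t = 0 by convention, nothing to test
    return(tibble(n_pairs = n, t = 0, df = n - 1, p_value = 1,
                  undefined = FALSE))
  }
  tt <- if (method == "paired") {
    t.test(a$captured_count, b$captured_count, paired = TRUE)
  } else {
    t.test(a$captured_count, b$captured_count)
  }
  tibble(n_pairs = n, t = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         undefined = FALSE)
}
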