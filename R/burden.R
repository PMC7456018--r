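# Donor mutational burden, LB/HB class labels, driver enrichment, and
# ratio-preserving down-sampling of the training matrix.

#' Per-donor mutational burden
#'
#' Counts mutation records per donor. Burden is the raw record count: a
#' donor carrying the same variant as another donor still contributes one
#' record of their own.
#'
#' @param mut Mutation tibble.
#' @return Tibble `donor_id, n_mutations`, one row per donor.
#' @export
compute_burden <- function(mut) {
  if (nrow(mut) == 0) abort("Mutation set is empty.")
  count(mut, .data$donor_id, name = "n_mutations")
}

#' Split donors into low- and high-burden classes
#'
#' Sorts donors by mutation count (ties broken by `donor_id` lexicographic
#' order, so the split is deterministic) and assigns the lower half to the
#' low-burden (LB) class and the upper half to the high-burden (HB) class.
#' With an even donor count the halves are equal sized; with an odd count
#' the extra donor goes to the side named by `odd_to` (LB by default, so
#' that candidate drivers are not discarded).
#'
#' @param burdens Tibble from [compute_burden()].
#' @param odd_to Class receiving the middle donor when the count is odd.
#' @return `burdens` with a `burden_class` column (`"LB"`/`"HB"`).
#' @export
split_burden_classes <- function(burdens, odd_to = c("LB", "HB")) {
  odd_to <- match.arg(odd_to)
  if (nrow(burdens) < 2) abort("Need at least two donors to split.")
  b <- arrange(burdens, .data$n_mutations, .data$donor_id)
  n <- nrow(b)
  n_lb <- if (odd_to == "LB") ceiling(n / 2) else floor(n / 2)
  b$burden_class <- rep(c("LB", "HB"), c(n_lb, n - n_lb))
  b
}

#' Label mutations with their donor's burden class
#'
#' Each mutation record inherits the burden class of its donor. In the
#' unique-variant view (see [distinct_variants()]) a variant carried by
#' donors of both classes is labeled LB: the working hypothesis is that the
#' LB class is *enriched* for driver-like, clonal mutations, so a variant
#' with any LB carrier remains a candidate.
#'
#' @param mut Mutation tibble.
#' @param burdens Tibble from [split_burden_classes()].
#' @return `mut` with a `burden_class` column.
#' @export
label_mutations <- function(mut, burdens) {
  if (!"burden_class" %in% names(burdens)) {
    abort("`burdens` has no burden_class; call split_burden_classes() first.")
  }
  missing <- setdiff(unique(mut$donor_id), burdens$donor_id)
  if (length(missing) > 0) {
    abort(paste0("Donor(s) missing from burden table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  left_join(mut, burdens[, c("donor_id", "burden_class")], by = "donor_id")
}

#' Hypergeometric enrichment of a gene set
#'
#' Upper-tail hypergeometric test of the overlap between a hit set (e.g.
#' genes carrying LB-class mutations) and a category (e.g. known driver
#' genes) within a gene universe: `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` with `N` the universe size, `K` the
#' category size, `n` the number of hits drawn and `k` the observed
#' overlap.
#'
#' @param hit_genes Character vector of hit gene names (subset of universe).
#' @param category_genes Character vector of category gene names (subset of
#'   universe).
#' @param universe_genes Character vector: the gene universe.
#' @return One-row tibble `N, K, n, k, p_value`.
#' @export
hypergeom_enrichment <- function(hit_genes, category_genes, universe_genes) {
  universe_genes <- unique(universe_genes)
  if (length(universe_genes) == 0) abort("Gene universe is empty.")
  hit_genes <- unique(hit_genes)
  category_genes <- unique(category_genes)
  out_h <- setdiff(hit_genes, universe_genes)
  out_c <- setdiff(category_genes, universe_genes)
  if (length(out_h) > 0 || length(out_c) > 0) {
    abort("hit_genes and category_genes must be subsets of universe_genes.")
  }
  N <- length(universe_genes)
  K <- length(category_genes)
  n <- length(hit_genes)
  k <- length(intersect(hit_genes, category_genes))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(N = N, K = K, n = n, k = k, p_value = p)
}

#' Down-sample a labeled feature matrix, preserving the class ratio
#'
#' Uniform sampling without replacement within each burden class, with
#' per-class sample sizes `round(target_n * class_fraction)`, so the output
#' LB:HB ratio deviates from the input ratio only by rounding. Rows of the
#' feature matrix are unique variants, so "target_n mutations" counts
#' deduplicated variants, not donor-mutation pairs.
#'
#' @param fm Labeled feature-matrix tibble (a `label` column of
#'   `"LB"`/`"HB"`).
#' @param target_n Total rows to keep (default 50000).
#' @param seed Integer seed; the same seed reproduces the same selection.
#' @return Down-sampled feature matrix (original row order preserved).
#' @export
downsample_mutations <- function(fm, target_n = 50000, seed = 1) {
  .check_labels(fm$label)
  n <- nrow(fm)
  if (target_n > n) abort("target_n exceeds the number of rows.")
  idx_lb <- which(fm$label == "LB")
  idx_hb <- which(fm$label == "HB")
  n_lb <- round(target_n * length(idx_lb) / n)
  n_lb <- max(1L, min(n_lb, length(idx_lb), target_n - 1L))
  n_hb <- target_n - n_lb
  if (n_hb > length(idx_hb)) {
    n_hb <- length(idx_hb)
    n_lb <- target_n - n_hb
  }
  keep <- withr::with_seed(seed, {
    c(sample(idx_lb, n_lb), sample(idx_hb, n_hb))
  })
  out <- fm[sort(keep), , drop = FALSE]
  .set_features(out, feature_names(fm))
}

#' Read a driver-gene list
#'
#' One gene symbol per line; blank lines and `#` comments are skipped.
#'
#' @param path Path to the list.
#' @return Character vector of gene names.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
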