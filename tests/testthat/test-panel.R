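mk_scored <- function(gene, gene_length, raw, coding = TRUE,
                      chrom = "chr1") {
  n <- length(raw)
  tibble::tibble(
    chrom = chrom, pos = seq_len(n) * 1000L, ref = "A", alt = "T",
    gene = gene, gene_length = gene_length, coding = coding,
    raw_distance = raw, rank = rank(-raw, ties.method = "first")
  )
}

test_that("within-bin z-scoring preserves order and spares unannotated mutations", {
  s <- mk_scored(gene = c("g1", "g1", NA), gene_length = c(5000, 5000, NA),
                 raw = c(2, 4, 0.5), coding = c(TRUE, TRUE, FALSE))
  out <- standardize_scores(s, n_bins = 1)
  z <- out$std_score[match(c(1000L, 2000L), out$pos)]
  expect_equal(z, c(-1, 1) / sqrt(2)) # two-point z-scores, order kept
  expect_equal(out$std_score[out$pos == 3000L], 0.5) # intergenic untouched
  expect_equal(out$rank, seq_len(3))

  # affine transforms of raw scores within a bin leave z-scores unchanged
  s2 <- dplyr::mutate(s, raw_distance = 10 * .data$raw_distance + 3)
  out2 <- standardize_scores(s2, n_bins = 1)
  expect_equal(out2$std_score[match(c(1000L, 2000L), out2$pos)],
               out$std_score[match(c(1000L, 2000L), out$pos)])
})

test_that("non-coding mutations keep their raw score even when gene-annotated", {
  s <- mk_scored(gene = c("g1", "g1", "g1"), gene_length = 5000,
                 raw = c(1, 2, 3), coding = c(TRUE, TRUE, FALSE))
  out <- standardize_scores(s, n_bins = 1)
  expect_equal(out$std_score[out$pos == 3000L], 3)
})

test_that("sparse bins pass through with a warning", {
  s <- mk_scored(gene = c("g1", "g2"), gene_length = c(100, 1e6),
                 raw = c(1, 2))
  expect_warning(out <- standardize_scores(s, n_bins = 2), "unscaled")
  expect_equal(sort(out$std_score), c(1, 2))
})

test_that("standardization decorrelates gene length from panel membership", {
  # long genes get inflated raw scores: a length-biased score process
  withr::with_seed(17, {
    n_genes <- 60
    glen <- round(exp(runif(n_genes, log(1e3), log(1e6))))
    per_gene <- 5 + rpois(n_genes, 15)
    gene <- rep(sprintf("g%02d", seq_len(n_genes)), per_gene)
    gl <- rep(glen, per_gene)
    raw <- rnorm(length(gene)) + 0.8 * scale(log(gl))[, 1]
    s <- mk_scored(gene = gene, gene_length = gl, raw = raw)
  })
  k <- round(nrow(s) * 0.25)
  count_cor <- function(scored) {
    top <- select_top(scored, k)
    per <- dplyr::count(top, .data$gene)
    per <- dplyr::left_join(tibble::tibble(gene = sprintf("g%02d", 1:60),
                                           gene_length = glen),
                            per, by = "gene")
    per$n[is.na(per$n)] <- 0
    cor(per$gene_length, per$n)
  }
  before <- count_cor(s)
  after <- count_cor(standardize_scores(s, n_bins = 10))
  expect_gt(before, 0.15) # bias is real before correction
  expect_lt(after, before) # and strictly reduced after
})

test_that("top-k selection is deterministic, tie-stable, and bounds-checked", {
  s <- mk_scored(gene = NA_character_, gene_length = NA_real_,
                 raw = c(3, 1, 2))[, setdiff(names(mk_scored(NA, NA, 1)),
                                             "coding")]
  expect_equal(select_top(s, 3)$pos, c(1000L, 3000L, 2000L))
  expect_equal(select_top(s, 1)$pos, 1000L)
  expect_error(select_top(s, 4), "exceeds")

  tie <- tibble::tibble(chrom = "chr1", pos = c(7L, 2L, 9L), ref = "A",
                        alt = "T", raw_distance = c(5, 5, 5))
  expect_equal(select_top(tie, 2)$pos, c(2L, 7L))
  expect_identical(select_top(tie, 2), select_top(tie, 2))
})

test_that("probe expansion does the +/-175 bp arithmetic and merges neighbors", {
  one <- tibble::tibble(chrom = "chr1", pos = 1000L, ref = "A", alt = "T")
  p1 <- build_probes(one, flank = 175)
  expect_equal(p1$probes$start, 824L)
  expect_equal(p1$probes$end, 1175L)
  expect_equal(p1$footprint_bp, 351)

  two <- tibble::tibble(chrom = "chr1", pos = c(1000L, 1100L), ref = "A",
                        alt = "T")
  p2 <- build_probes(two, flank = 175)
  expect_equal(nrow(p2$probes), 1)
  expect_equal(p2$footprint_bp, 451)

  # an indel expands from its full reference span
  del <- tibble::tibble(chrom = "chr1", pos = 1000L, ref = "ACCCCCCCCCC",
                        alt = "A")
  pd <- build_probes(del, flank = 175)
  expect_equal(pd$footprint_bp, 351 + 10)

  expect_warning(p0 <- build_probes(
    tibble::tibble(chrom = "chr1", pos = 50L, ref = "A", alt = "T"),
    flank = 175
  ), "clipped")
  expect_equal(p0$probes$start, 0L)
})

test_that("probe footprint equals a per-base coverage count", {
  withr::with_seed(23, {
    for (i in 1:4) {
      members <- tibble::tibble(
        chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
        pos = sample(500:9000, 30), ref = "A", alt = "T"
      )
      panel <- build_probes(members, flank = sample(c(0, 50, 175), 1))
      per_base <- sum(vapply(unique(panel$probes$chrom), function(ch) {
        covered <- logical(10000)
        pr <- panel$probes[panel$probes$chrom == ch, ]
        for (j in seq_len(nrow(pr))) {
          covered[(pr$start[j] + 1L):pr$end[j]] <- TRUE
        }
        sum(covered)
      }, numeric(1)))
      expect_equal(panel$footprint_bp, per_base)
      expect_true(all(panel$probes$end > panel$probes$start))
      # merged probes never touch or overlap
      for (ch in unique(panel$probes$chrom)) {
        pr <- panel$probes[panel$probes$chrom == ch, ]
        if (nrow(pr) > 1) expect_true(all(pr$start[-1] > pr$end[-nrow(pr)]))
      }
    }
  })
})

test_that("panel summaries count consequences and coding fractions", {
  members <- tibble::tibble(
    chrom = "chr1", pos = seq_len(100) * 1000L, ref = "A", alt = "T",
    coding = rep(c(TRUE, FALSE), c(82, 18)),
    consequence = rep(c("missense_variant", "regulatory_region_variant"),
                      c(82, 18)),
    impact = rep(c("MODERATE", "MODIFIER"), c(82, 18))
  )
  sm <- summarize_panel(build_probes(members, flank = 10))
  expect_equal(sm$overview$noncoding_fraction, 0.18)
  expect_equal(sm$consequences$n[sm$consequences$consequence ==
                                   "missense_variant"], 82)

  all_mis <- dplyr::mutate(members, consequence = "missense_variant",
                           impact = "MODERATE", coding = TRUE)
  sm2 <- summarize_panel(build_probes(all_mis, flank = 10))
  expect_equal(nrow(sm2$consequences), 1)

  empty <- summarize_panel(build_probes(members[0, ]))
  expect_equal(empty$overview$n_members, 0)
  expect_equal(empty$overview$footprint_bp, 0)
})

test_that("BED export is 0-based half-open with member names and scaled scores", {
  members <- tibble::tibble(
    chrom = "chr1", pos = c(1000L, 5000L), ref = "A", alt = "T",
    std_score = c(2, 4)
  )
  panel <- build_probes(members, flank = 175)
  f <- withr::local_tempfile(fileext = ".bed")
  write_panel_bed(panel, f)
  bed <- readr::read_tsv(f, col_names = c("chrom", "start", "end", "name",
                                          "score", "strand"),
                         show_col_types = FALSE)
  expect_equal(bed$start, c(824, 4824))
  expect_equal(bed$end, c(1175, 5175))
  expect_equal(bed$name, c("chr1:1000:A:T", "chr1:5000:A:T"))
  expect_equal(bed$score, c(0, 1000))
  expect_true(all(bed$strand == "."))
})
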