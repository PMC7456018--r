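# Panel construction: gene-length score standardization, top-K selection,
# probe interval expansion/merging, and composition summaries.
#
# Internal variant coordinates are 1-based; probe intervals are 0-based
# half-open and only converted at the BED boundary.

#' Standardize hyperplane-distance scores within gene-length bins
#'
#' Longer genes accumulate more mutations and can carry gene-level feature
#' annotations that inflate raw scores, so unchecked top-K selection
#' over-represents long genes. This correction bins genes into `n_bins`
#' quantile groups by gene length and z-scores the raw distances within
#' each bin (`std_score = (raw_distance - bin mean) / bin sd`). Mutations
#' that are non-coding or lack gene annotation are unaffected
#' (`std_score = raw_distance`). Ranks are recomputed on the standardized
#' score.
#'
#' @param scored Scored-mutation tibble from [score_mutations()]; rows with
#'   a `gene` must carry `gene_length` (bp). An optional logical `coding`
#'   column restricts the correction to coding mutations.
#' @param n_bins Number of gene-length quantile bins (default 10).
#' @return `scored` with `std_score` added and `rank` recomputed (ties
#'   broken by variant key). Bins with fewer than 2 mutations or zero score
#'   spread pass scores through unscaled with a warning.
#' @export
standardize_scores <- function(scored, n_bins = 10) {
  stopifnot("raw_distance" %in% names(scored))
  if (!"gene" %in% names(scored)) {
    out <- scored
    out$std_score <- out$raw_distance
    return(.rerank(out))
  }
  affected <- !is.na(scored$gene)
  if ("coding" %in% names(scored)) {
    affected <- affected & !is.na(scored$coding) & scored$coding
  }
  gl <- scored[["gene_length"]]
  if (is.null(gl)) gl <- rep(NA_real_, nrow(scored))
  if (any(affected & is.na(gl))) {
    abort("gene_length must be present wherever gene is present.")
  }

  out <- scored
  out$std_score <- out$raw_distance
  if (any(affected)) {
    genes <- distinct(out[affected, c("gene", "gene_length")])
    genes <- group_by(genes, .data$gene)
    genes <- summarise(genes, gene_length = max(.data$gene_length),
                       .groups = "drop")
    brk <- unique(quantile(genes$gene_length,
                           probs = seq(0, 1, length.out = n_bins + 1)))
    genes$length_bin <- cut(genes$gene_length, breaks = brk,
                            include.lowest = TRUE, labels = FALSE)
    bin_of <- setNames(genes$length_bin, genes$gene)
    bins <- bin_of[out$gene[affected]]
    idx <- split(which(affected), bins)
    passed <- 0L
    for (ii in idx) {
      s <- out$raw_distance[ii]
      if (length(ii) < 2 || sd(s) == 0) {
        passed <- passed + 1L
        next
      }
      out$std_score[ii] <- (s - mean(s)) / sd(s)
    }
    if (passed > 0) {
      warn(sprintf(
        "%d gene-length bin(s) had <2 mutations or no score spread; their scores pass through unscaled.",
        passed
      ))
    }
  }
  .rerank(out)
}

.rerank <- function(scored) {
  by <- if ("std_score" %in% names(scored)) scored$std_score
        else scored$raw_distance
  ord <- order(-by, variant_key(scored), method = "radix")
  scored <- scored[ord, , drop = FALSE]
  scored$rank <- seq_len(nrow(scored))
  as_tibble(scored)
}

#' Select the top-ranked mutations for the panel
#'
#' Takes the `k` highest-scoring mutations (standardized score when
#' present, raw distance otherwise), with ties broken deterministically by
#' variant key.
#'
#' @param scored Scored-mutation tibble.
#' @param k Panel size in mutations (default 7034).
#' @return Tibble of the `k` selected mutations.
#' @export
select_top <- function(scored, k = 7034) {
  if (k > nrow(scored)) {
    abort(sprintf("k (%d) exceeds the number of scored mutations (%d).",
                  k, nrow(scored)))
  }
  head(.rerank(scored), k)
}

#' Expand panel mutations into merged probe intervals
#'
#' Expands each member mutation's reference span by `flank` bp on both
#' sides (an SNV becomes a `2 * flank + 1` bp window, 351 bp at the default
#' +/-175 bp, matching the modal dinucleosomal cfDNA fragment) and merges
#' overlapping or bookended intervals per chromosome. Intervals are 0-based
#' half-open; starts that would fall below the chromosome origin are
#' clipped at 0 with a warning.
#'
#' @param members Tibble of panel mutations (`chrom, pos, ref, alt`, 1-based).
#' @param flank Flank size in bp (>= 0), default 175.
#' @return An object of class `probe_panel`: merged probe intervals
#'   (`probes`), the member mutations (`members`), the flank, and the total
#'   genomic footprint in bp.
#' @export
build_probes <- function(members, flank = 175) {
  stopifnot(flank >= 0)
  if (nrow(members) == 0) {
    return(structure(
      list(probes = tibble(chrom = character(), start = integer(),
                           end = integer()),
           members = members, flank = flank, footprint_bp = 0),
      class = "probe_panel"
    ))
  }
  ref_end <- members$pos + nchar(members$ref) - 1L # 1-based inclusive span
  start0 <- members$pos - 1L - as.integer(flank)
  end0 <- ref_end + as.integer(flank)
  if (any(start0 < 0)) {
    warn(sprintf("%d probe interval(s) clipped at the chromosome origin.",
                 sum(start0 < 0)))
    start0 <- pmax(start0, 0L)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = members$chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
  )
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  probes <- tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  )
  structure(
    list(probes = probes, members = as_tibble(members), flank = flank,
         footprint_bp = sum(probes$end - probes$start)),
    class = "probe_panel"
  )
}

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf(
    "<probe_panel> %d probes, %d member mutations, flank +/-%d bp, footprint %s bp\n",
    nrow(x$probes), nrow(x$members), x$flank,
    format(x$footprint_bp, big.mark = ",")
  ))
  invisible(x)
}

#' Summarize panel composition
#'
#' Tabulates member mutations by consequence term and impact tier and
#' reports the coding/non-coding split alongside the probe footprint.
#'
#' @param panel A `probe_panel`.
#' @return An object of class `panel_summary` with elements `overview`
#'   (one-row tibble: member count, probe count, footprint, coding and
#'   non-coding fractions), `consequences` (counts per consequence term
#'   with modal impact), and `impacts` (counts per impact tier).
#' @export
summarize_panel <- function(panel) {
  stopifnot(inherits(panel, "probe_panel"))
  m <- panel$members
  n <- nrow(m)
  coding_frac <- if (n == 0) 0 else {
    if ("coding" %in% names(m)) mean(m$coding %in% TRUE)
    else if ("gene" %in% names(m)) mean(!is.na(m$gene))
    else NA_real_
  }
  overview <- tibble(
    n_members = n,
    n_probes = nrow(panel$probes),
    footprint_bp = panel$footprint_bp,
    coding_fraction = coding_frac,
    noncoding_fraction = if (is.na(coding_frac)) NA_real_ else 1 - coding_frac
  )
  consequences <- if (n > 0 && "consequence" %in% names(m)) {
    cc <- count(m, .data$consequence, sort = TRUE)
    if ("impact" %in% names(m)) {
      imp <- distinct(m, .data$consequence, .data$impact)
      imp <- imp[!duplicated(imp$consequence), ]
      cc <- left_join(cc, imp, by = "consequence")
    }
    cc
  } else {
    tibble(consequence = character(), n = integer())
  }
  impacts <- if (n > 0 && "impact" %in% names(m)) {
    count(m, .data$impact, sort = TRUE)
  } else {
    tibble(impact = character(), n = integer())
  }
  structure(
    list(overview = overview, consequences = consequences,
         impacts = impacts),
    class = "panel_summary"
  )
}

#' @export
print.panel_summary <- function(x, ...) {
  ov <- x$overview
  cat(sprintf("<panel_summary> %d members over %d probes (%s bp)\n",
              ov$n_members, ov$n_probes,
              format(ov$footprint_bp, big.mark = ",")))
  if (!is.na(ov$coding_fraction)) {
    cat(sprintf("  coding %.1f%% / non-coding %.1f%%\n",
                100 * ov$coding_fraction, 100 * ov$noncoding_fraction))
  }
  if (nrow(x$consequences) > 0) {
    cat("  top consequences:\n")
    print(head(x$consequences, 5))
  }
  invisible(x)
}

#' Write panel probes as 6-column BED
#'
#' BED is 0-based half-open. Each probe's name is the variant key of its
#' highest-scoring member mutation and its score is that member's
#' standardized score rescaled to 0-1000 across the panel; strand is `"."`.
#'
#' @param panel A `probe_panel`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(inherits(panel, "probe_panel"))
  pr <- panel$probes
  m <- panel$members
  name <- rep(".", nrow(pr))
  score <- rep(0L, nrow(pr))
  if (nrow(m) > 0) {
    s <- m$std_score %||% m$raw_distance %||% rep(0, nrow(m))
    rng <- range(s)
    scl <- if (diff(rng) == 0) rep(500L, nrow(m))
           else as.integer(round(1000 * (s - rng[1]) / diff(rng)))
    gr_p <- GenomicRanges::GRanges(pr$chrom,
                                   IRanges::IRanges(pr$start + 1L, pr$end))
    gr_m <- GenomicRanges::GRanges(m$chrom,
                                   IRanges::IRanges(m$pos,
                                                    m$pos + nchar(m$ref) - 1L))
    hits <- GenomicRanges::findOverlaps(gr_m, gr_p)
    hdf <- tibble(member = S4Vectors::queryHits(hits),
                  probe = S4Vectors::subjectHits(hits),
                  s = s[S4Vectors::queryHits(hits)])
    best <- slice(group_by(hdf, .data$probe), which.max(.data$s))
    name[best$probe] <- variant_key(m[best$member, ])
    score[best$probe] <- scl[best$member]
  }
  bed <- tibble(chrom = pr$chrom, start = pr$start, end = pr$end,
                name = name, score = score, strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
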