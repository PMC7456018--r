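# Synthetic cohorts with known ground truth: donor burden laws, planted
# feature signal, gene models, multi-focus tumor sharing, and cfDNA
# read-count sampling. Every stage of the pipeline is testable against
# these generators without any controlled-access download.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: 550 donors split into a
#' low- and a high-burden component whose 1:40 mutation ratio matches the
#' training label imbalance, 339 per-mutation features of which 20 carry a
#' +1.5 standard-deviation mean shift for low-burden-class mutations, a
#' compact 4 x 50 Mb genome with 200 genes spanning ~1 kb to 2 Mb, 3 tumor
#' foci per patient with 0.8 sharing, and cfDNA sampled at 2500x depth
#' with 4% tumor fraction. Per-donor burden means (20 and 800) are a
#' deliberately scaled-down stand-in for whole-genome burdens that
#' preserves the class ratio.
#'
#' @param n_donors Number of cohort donors.
#' @param burden_mean_low,burden_mean_high Mean per-donor mutation count of
#'   the low/high-burden components (negative binomial).
#' @param burden_dispersion Negative-binomial size parameter.
#' @param n_features,n_informative Total and informative feature counts.
#' @param effect_size Mean shift of informative features for low-burden
#'   mutations, in feature standard deviations.
#' @param genome Tibble `chrom, length` of chromosome sizes.
#' @param n_genes Number of genes in the simulated gene model.
#' @param gene_length_range Log-uniform range of gene lengths in bp.
#' @param p_recurrent Probability a mutation is drawn from a shared hotspot
#'   pool (creates recurrent variants, irrespective of class).
#' @param n_hotspots Size of the hotspot pool.
#' @param indel_fraction Fraction of mutations that are indels.
#' @param n_foci Tumor foci per patient.
#' @param sharing Probability a truth variant appears in a given focus.
#' @param tumor_fraction Tumor-derived fraction of cfDNA molecules.
#' @param depth Mean cfDNA sequencing depth.
#' @param n_germline Planted germline variants per patient (allele
#'   fraction near 0.5, exercising the germline bound from above).
#' @param seed Integer seed; all generators are fully deterministic given
#'   the seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_donors = 550,
                       burden_mean_low = 20, burden_mean_high = 800,
                       burden_dispersion = 3,
                       n_features = 339, n_informative = 20,
                       effect_size = 1.5,
                       genome = tibble(chrom = paste0("chr", 1:4),
                                       length = 5e7),
                       n_genes = 200,
                       gene_length_range = c(1e3, 2e6),
                       p_recurrent = 0.05, n_hotspots = 200,
                       indel_fraction = 0.09,
                       n_foci = 3, sharing = 0.8,
                       tumor_fraction = 0.04, depth = 2500,
                       n_germline = 50,
                       seed = 1) {
  stopifnot(
    n_donors >= 2, n_informative <= n_features,
    effect_size >= 0, sharing >= 0, sharing <= 1,
    tumor_fraction >= 0, tumor_fraction <= 1,
    all(c("chrom", "length") %in% names(genome)),
    n_foci >= 1, depth > 0
  )
  structure(
    list(n_donors = n_donors, burden_mean_low = burden_mean_low,
         burden_mean_high = burden_mean_high,
         burden_dispersion = burden_dispersion,
         n_features = n_features, n_informative = n_informative,
         effect_size = effect_size, genome = genome, n_genes = n_genes,
         gene_length_range = gene_length_range,
         p_recurrent = p_recurrent, n_hotspots = n_hotspots,
         indel_fraction = indel_fraction, n_foci = n_foci,
         sharing = sharing, tumor_fraction = tumor_fraction,
         depth = depth, n_germline = n_germline, seed = seed),
    class = "sim_config"
  )
}

.feature_ids <- function(p) sprintf("f%03d", seq_len(p))

.random_variants <- function(n, cfg) {
  bases <- c("A", "C", "G", "T")
  chrom_i <- sample.int(nrow(cfg$genome), n, replace = TRUE,
                        prob = cfg$genome$length)
  pos <- floor(runif(n, min = 1, max = cfg$genome$length[chrom_i])) # 1-based
  kind <- sample(c("SNV", "INS", "DEL"), n, replace = TRUE,
                 prob = c(1 - cfg$indel_fraction, cfg$indel_fraction / 2,
                          cfg$indel_fraction / 2))
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  len <- 1L + stats::rgeom(n, 0.4)
  ins <- kind == "INS"
  del <- kind == "DEL"
  if (any(ins)) {
    alt[ins] <- paste0(ref[ins], vapply(len[ins], function(l) {
      paste(sample(bases, l, replace = TRUE), collapse = "")
    }, ""))
  }
  if (any(del)) {
    ref[del] <- paste0(ref[del], vapply(len[del], function(l) {
      paste(sample(bases, l, replace = TRUE), collapse = "")
    }, ""))
    alt[del] <- substr(ref[del], 1, 1)
  }
  tibble(chrom = cfg$genome$chrom[chrom_i], pos = as.integer(pos),
         ref = ref, alt = alt)
}

#' Simulate a gene model
#'
#' Places `n_genes` non-overlapping genes on the simulated genome with
#' log-uniform lengths spanning `gene_length_range`.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to the config seed).
#' @return Tibble `gene, chrom, start, end, gene_length` (1-based
#'   inclusive).
#' @export
simulate_gene_model <- function(cfg = sim_config(), seed = cfg$seed) {
  withr::with_seed(seed, {
    lens <- round(exp(runif(cfg$n_genes, log(cfg$gene_length_range[1]),
                            log(cfg$gene_length_range[2]))))
    chrom_i <- sample.int(nrow(cfg$genome), cfg$n_genes, replace = TRUE,
                          prob = cfg$genome$length)
    out <- purrr::map_dfr(seq_len(nrow(cfg$genome)), function(ci) {
      li <- lens[chrom_i == ci]
      if (length(li) == 0) return(tibble())
      L <- cfg$genome$length[ci]
      spare <- L - sum(li)
      if (spare < 0) abort("Gene lengths exceed chromosome length; shrink n_genes or gene_length_range.")
      gaps <- diff(c(0, sort(runif(length(li))))) * spare
      start <- cumsum(gaps) + c(0, cumsum(head(li, -1))) + 1
      tibble(chrom = cfg$genome$chrom[ci], start = floor(start),
             gene_length = li)
    })
    out <- arrange(out, .data$chrom, .data$start)
    out$gene <- sprintf("g%03d", seq_len(nrow(out)))
    mutate(out, start = as.integer(.data$start),
           end = as.integer(.data$start + .data$gene_length - 1L))[
             , c("gene", "chrom", "start", "end", "gene_length")]
  })
}

.annotate_genes <- function(mut, gene_model) {
  gr_m <- GenomicRanges::GRanges(mut$chrom, IRanges::IRanges(mut$pos, mut$pos))
  gr_g <- GenomicRanges::GRanges(gene_model$chrom,
                                 IRanges::IRanges(gene_model$start,
                                                  gene_model$end))
  hits <- GenomicRanges::findOverlaps(gr_m, gr_g, select = "first")
  mut$gene <- gene_model$gene[hits]
  mut$gene_length <- gene_model$gene_length[hits]
  in_gene <- !is.na(mut$gene)
  csq <- rep("intergenic_variant", nrow(mut))
  csq[in_gene] <- sample(
    c("missense_variant", "synonymous_variant", "stop_gained",
      "intron_variant"),
    sum(in_gene), replace = TRUE, prob = c(0.40, 0.25, 0.05, 0.30)
  )
  impact_map <- c(missense_variant = "MODERATE", synonymous_variant = "LOW",
                  stop_gained = "HIGH", intron_variant = "MODIFIER",
                  intergenic_variant = "MODIFIER")
  mut$consequence <- csq
  mut$impact <- unname(impact_map[csq])
  mut$coding <- csq %in% c("missense_variant", "synonymous_variant",
                           "stop_gained")
  mut
}

#' Simulate a mutation cohort with planted feature signal
#'
#' Draws per-donor mutation counts from a two-component negative-binomial
#' burden law (half the donors low-burden, half high-burden in truth),
#' scatters mutations over the genome (a fraction recurrent via a shared
#' hotspot pool), annotates them against the simulated gene model, and
#' generates per-variant features: independent unit-variance noise, with
#' the informative features mean-shifted by `effect_size` for variants
#' carried by truth-low-burden donors.
#'
#' @param cfg A [sim_config()].
#' @param gene_model Optional gene model (default [simulate_gene_model()]).
#' @param features Generate the feature table? (Set `FALSE` for burden-only
#'   work at full cohort scale.)
#' @return List with `mutations` (record tibble), `features` (feature
#'   table, or `NULL`), and `truth` (donor classes, per-variant truth
#'   labels, informative feature names); the configuration is attached as
#'   attribute `provenance`.
#' @export
simulate_cohort <- function(cfg = sim_config(), gene_model = NULL,
                            features = TRUE) {
  gene_model <- gene_model %||% simulate_gene_model(cfg)
  out <- withr::with_seed(cfg$seed, {
    n_low <- ceiling(cfg$n_donors / 2)
    donors <- tibble(
      donor_id = sprintf("D%04d", seq_len(cfg$n_donors)),
      truth_class = rep(c("low", "high"),
                        c(n_low, cfg$n_donors - n_low))
    )
    mu <- ifelse(donors$truth_class == "low", cfg$burden_mean_low,
                 cfg$burden_mean_high)
    burden <- pmax(1L, rnbinom(cfg$n_donors, mu = mu,
                               size = cfg$burden_dispersion))

    hotspots <- .random_variants(cfg$n_hotspots, cfg)
    n_total <- sum(burden)
    recs <- .random_variants(n_total, cfg)
    hot <- runif(n_total) < cfg$p_recurrent
    if (any(hot)) {
      hi <- sample.int(cfg$n_hotspots, sum(hot), replace = TRUE)
      recs[hot, ] <- hotspots[hi, ]
    }
    recs$donor_id <- rep(donors$donor_id, burden)
    recs <- distinct(recs, .data$donor_id, .data$chrom, .data$pos,
                     .data$ref, .data$alt, .keep_all = TRUE)
    recs$mtype <- .infer_mtype(recs$ref, recs$alt)
    recs <- .annotate_genes(recs, gene_model)
    recs <- recs[, c("chrom", "pos", "ref", "alt", "mtype", "donor_id",
                     "gene", "gene_length", "consequence", "impact",
                     "coding")]

    truth_lb_donors <- donors$donor_id[donors$truth_class == "low"]
    uv <- distinct(recs, .data$chrom, .data$pos, .data$ref, .data$alt)
    carrier_lb <- summarise(
      group_by(recs, .data$chrom, .data$pos, .data$ref, .data$alt),
      truth_lb = any(.data$donor_id %in% truth_lb_donors),
      .groups = "drop"
    )

    ft <- NULL
    if (features) {
      p <- cfg$n_features
      nv <- nrow(carrier_lb)
      X <- matrix(rnorm(nv * p), nv, p)
      m <- cfg$n_informative
      if (m > 0) {
        X[carrier_lb$truth_lb, seq_len(m)] <-
          X[carrier_lb$truth_lb, seq_len(m)] + cfg$effect_size
      }
      colnames(X) <- .feature_ids(p)
      ft <- bind_cols(
        carrier_lb[, c("chrom", "pos", "ref", "alt")],
        as_tibble(X)
      )
      ft <- .set_features(ft, .feature_ids(p))
    }

    list(
      mutations = recs,
      features = ft,
      truth = list(
        donors = donors,
        variants = carrier_lb,
        informative_features = .feature_ids(cfg$n_features)[
          seq_len(cfg$n_informative)]
      )
    )
  })
  attr(out, "provenance") <- cfg
  out
}

#' Simulate a labeled planted-signal feature matrix
#'
#' The direct design-matrix fixture for classifier work: `n` labeled rows
#' with `n_features` independent unit-variance Gaussian features, of which
#' the first `n_informative` are mean-shifted by `effect_size` for LB
#' rows. Rows carry synthetic, mutually distant variant keys so the matrix
#' can flow through scoring and panel construction unchanged.
#'
#' @param n Number of rows.
#' @param n_features,n_informative Total and informative feature counts.
#' @param effect_size Mean shift for LB rows, in standard deviations.
#' @param lb_fraction Fraction of LB rows (default 0.5).
#' @param seed Integer seed.
#' @return Labeled feature-matrix tibble with attributes `features` and
#'   `informative` (the planted feature names).
#' @export
simulate_feature_matrix <- function(n = 5000, n_features = 339,
                                    n_informative = 20, effect_size = 1.5,
                                    lb_fraction = 0.5, seed = 1) {
  stopifnot(n_informative <= n_features, lb_fraction > 0, lb_fraction < 1)
  withr::with_seed(seed, {
    n_lb <- round(n * lb_fraction)
    label <- sample(rep(c("LB", "HB"), c(n_lb, n - n_lb)))
    X <- matrix(rnorm(n * n_features), n, n_features)
    if (n_informative > 0) {
      lb <- label == "LB"
      X[lb, seq_len(n_informative)] <-
        X[lb, seq_len(n_informative)] + effect_size
    }
    colnames(X) <- .feature_ids(n_features)
    fm <- bind_cols(
      tibble(chrom = "chr1", pos = seq_len(n) * 400L, ref = "A", alt = "T",
             label = label),
      as_tibble(X)
    )
    fm <- .set_features(fm, .feature_ids(n_features))
    attr(fm, "informative") <- .feature_ids(n_features)[
      seq_len(n_informative)]
    fm
  })
}

#' Simulate tumor foci, normal, and cfDNA call sets for one patient
#'
#' Each truth variant enters each of `n_foci` foci independently with
#' probability `sharing`. Planted germline heterozygous variants (allele
#' fraction near 0.5) appear in every focus, the normal, and the cfDNA.
#' cfDNA alt-read counts are binomial with success probability
#' `tumor_fraction * clonal_fraction` (germline: 0.5) at Poisson depths
#' around `depth`; calls require at least one supporting read.
#'
#' @param truth_variants Tibble `chrom, pos, ref, alt` of the patient's
#'   somatic truth variants; an optional `clonal_fraction` column in
#'   `[0, 1]` scales detectability (default 1, fully clonal).
#' @param cfg A [sim_config()].
#' @param patient_id Patient identifier attached to all output rows.
#' @param seed Seed (defaults to the config seed).
#' @return List of call-set tibbles `tumor` (all foci, `focus_id` column),
#'   `normal`, and `cfdna`, each with `depth`, `alt_reads`, and
#'   `allele_fraction`; the configuration is attached as attribute
#'   `provenance`.
#' @export
simulate_foci_and_cfdna <- function(truth_variants, cfg = sim_config(),
                                    patient_id = "P001", seed = cfg$seed) {
  stopifnot(cfg$n_foci >= 1)
  key <- c("chrom", "pos", "ref", "alt")
  tv <- as_tibble(truth_variants)[, c(
    key, intersect("clonal_fraction", names(truth_variants)))]
  if (!"clonal_fraction" %in% names(tv)) tv$clonal_fraction <- 1
  out <- withr::with_seed(seed, {
    germ <- .random_variants(cfg$n_germline, cfg)
    germ <- anti_join(germ, tv, by = key)

    tumor_depth <- 200
    one_focus <- function(fid) {
      present <- tv[runif(nrow(tv)) < cfg$sharing, , drop = FALSE]
      calls <- bind_rows(
        mutate(present[, key],
               allele_fraction = pmin(1, pmax(
                 0.01, present$clonal_fraction / 2 +
                   rnorm(nrow(present), 0, 0.02)))),
        mutate(germ, allele_fraction = pmin(1, pmax(
          0.01, rnorm(nrow(germ), 0.5, 0.02))))
      )
      calls$depth <- rpois(nrow(calls), tumor_depth)
      calls$alt_reads <- pmin(calls$depth,
                              round(calls$allele_fraction * calls$depth))
      mutate(calls, patient_id = patient_id, focus_id = fid)
    }
    tumor <- purrr::map_dfr(sprintf("f%d", seq_len(cfg$n_foci)), one_focus)

    normal <- mutate(
      germ,
      allele_fraction = pmin(1, pmax(0.01, rnorm(nrow(germ), 0.5, 0.02))),
      depth = rpois(nrow(germ), tumor_depth),
      patient_id = patient_id, focus_id = "normal"
    )
    normal$alt_reads <- pmin(normal$depth,
                             round(normal$allele_fraction * normal$depth))

    cf <- bind_rows(
      mutate(tv[, key], p_alt = cfg$tumor_fraction * tv$clonal_fraction),
      mutate(germ, p_alt = 0.5)
    )
    cf$depth <- rpois(nrow(cf), cfg$depth)
    cf$alt_reads <- rbinom(nrow(cf), cf$depth, cf$p_alt)
    cf$allele_fraction <- ifelse(cf$depth > 0, cf$alt_reads / cf$depth, 0)
    cf <- filter(cf, .data$alt_reads >= 1)
    cf <- mutate(select(cf, -"p_alt"),
                 patient_id = patient_id, focus_id = "cfdna")

    cols <- c("patient_id", "focus_id", key, "depth", "alt_reads",
              "allele_fraction")
    list(tumor = tumor[, cols], normal = normal[, cols], cfdna = cf[, cols])
  })
  attr(out, "provenance") <- cfg
  out
}
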