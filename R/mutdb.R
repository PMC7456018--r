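# Somatic mutation catalogs: reading, validation, filtering, feature joins.
#
# Internal conventions: coordinates are 1-based and indels are VCF-style
# reference-anchored; MAF coordinates are converted on load. A variant locus
# is identified by (chrom, pos, ref, alt) independent of the donor carrying
# it; donors sharing a variant collapse to one row with a donor count in the
# unique-variant view.

#' Read a somatic mutation catalog
#'
#' Reads somatic mutations from a VCF (plain or bgzipped), a MAF, or the
#' package's tabular dialect (TSV with columns
#' `chrom, pos, ref, alt, donor_id` and optionally
#' `gene, consequence, impact`). Returns one row per mutation record
#' (donor x variant); multi-allelic VCF rows are split into one record per
#' alternate allele and the mutation type (`SNV`/`INS`/`DEL`) is inferred
#' from allele lengths.
#'
#' For VCF input the donor is taken from a `DONOR` INFO key if present,
#' otherwise from the single sample column name. MAF insertions/deletions
#' use `-` alleles and unanchored coordinates; they are converted to the
#' reference-anchored convention with an `N` placeholder anchor base (no
#' reference genome is consulted), which keeps variant identity internally
#' consistent.
#'
#' @param path Path to the input file.
#' @param format One of `"auto"`, `"tsv"`, `"vcf"`, `"maf"`. `"auto"` picks
#'   by file extension.
#' @return A tibble of mutation records with columns `chrom, pos, ref, alt,
#'   mtype, donor_id` plus any of `gene, consequence, impact` present in the
#'   input.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tpos\tref\talt\tdonor_id",
#'              "chr1\t1000\tA\tT\tD1",
#'              "chr1\t2000\tAT\tA\tD2"), tf)
#' read_mutations(tf)
#' @export
read_mutations <- function(path, format = c("auto", "tsv", "vcf", "maf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "auto") {
    format <- dplyr::case_when(
      grepl("\\.vcf(\\.b?gz)?$", path, ignore.case = TRUE) ~ "vcf",
      grepl("\\.maf(\\.gz)?$", path, ignore.case = TRUE) ~ "maf",
      TRUE ~ "tsv"
    )
  }
  mut <- switch(format,
    tsv = .read_mut_tsv(path),
    vcf = .read_mut_vcf(path),
    maf = .read_mut_maf(path)
  )
  if (nrow(mut) > 0) {
    .check_dna(mut$ref, "ref")
    .check_dna(mut$alt, "alt")
    mut$mtype <- .infer_mtype(mut$ref, mut$alt)
  } else {
    mut$mtype <- character(0)
    mut <- mut[, c("chrom", "pos", "ref", "alt", "mtype", "donor_id")]
  }
  opt <- intersect(c("gene", "consequence", "impact"), names(mut))
  mut <- mut[, c("chrom", "pos", "ref", "alt", "mtype", "donor_id", opt)]
  as_tibble(mut)
}

.read_mut_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         chrom = "c", pos = "i", ref = "c", alt = "c",
                         donor_id = "c", .default = "c"
                       ))
  pr <- readr::problems(x)
  if (nrow(pr) > 0) {
    abort(sprintf("Malformed row at line %d of %s: %s", pr$row[1] + 1L, path,
                  pr$expected[1]))
  }
  need <- c("chrom", "pos", "ref", "alt", "donor_id")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("Missing required column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- which(!complete.cases(x[need]))
  if (length(bad) > 0) {
    abort(sprintf("Malformed row at line %d: missing required field",
                  bad[1] + 1L))
  }
  x
}

.read_mut_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), donor_id = character()))
  }
  donor <- vcfR::extract.info(v, "DONOR")
  if (all(is.na(donor))) {
    smp <- colnames(v@gt)
    smp <- setdiff(smp, "FORMAT")
    if (length(smp) == 1) {
      donor <- rep(smp, nrow(fix))
    } else {
      abort("VCF has no DONOR INFO key and not exactly one sample column; donor identity cannot be inferred.")
    }
  }
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT),
    donor_id = donor
  )
  # split multi-allelic ALT into one record per allele
  tidyr::separate_rows(out, "alt", sep = ",")
}

.read_mut_maf <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  need <- c("Chromosome", "Start_Position", "Reference_Allele",
            "Tumor_Seq_Allele2", "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("MAF missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  ref <- toupper(x$Reference_Allele)
  alt <- toupper(x$Tumor_Seq_Allele2)
  pos <- as.integer(x$Start_Position)
  ins <- ref %in% c("-", "")
  del <- alt %in% c("-", "")
  # reference-anchored conversion; anchor base is an N placeholder because
  # no reference genome is read
  out <- tibble(
    chrom = as.character(x$Chromosome),
    pos = dplyr::if_else(del, pos - 1L, pos),
    ref = dplyr::case_when(ins ~ "N", del ~ paste0("N", ref), TRUE ~ ref),
    alt = dplyr::case_when(ins ~ paste0("N", alt), del ~ "N", TRUE ~ alt),
    donor_id = as.character(x$Tumor_Sample_Barcode)
  )
  if ("Hugo_Symbol" %in% names(x)) out$gene <- as.character(x$Hugo_Symbol)
  out
}

#' Write mutations in the tabular dialect
#'
#' Writes a mutation table as the package's TSV dialect, which
#' [read_mutations()] reads back unchanged.
#'
#' @param mut Mutation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mut, path) {
  cols <- intersect(c("chrom", "pos", "ref", "alt", "donor_id", "gene",
                      "consequence", "impact"), names(mut))
  readr::write_tsv(mut[, cols], path, progress = FALSE)
  invisible(path)
}

#' Filter indels by length
#'
#' Retains all SNVs and only those insertions/deletions whose length change
#' `abs(nchar(alt) - nchar(ref))` is at most `max_len` (default 200 bp, the
#' usual small-indel bound for capture panel design).
#'
#' @param mut Mutation tibble (with `mtype`).
#' @param max_len Maximum indel length in bp (>= 1).
#' @return Filtered mutation tibble.
#' @export
filter_indel_length <- function(mut, max_len = 200) {
  stopifnot(max_len >= 1)
  filter(mut, .data$mtype == "SNV" |
           abs(nchar(.data$alt) - nchar(.data$ref)) <= max_len)
}

#' Unique-variant view of a mutation catalog
#'
#' Deduplicates mutation records on `(chrom, pos, ref, alt)` and counts the
#' distinct donors carrying each variant. Optional annotation columns keep
#' their first observed value. If records carry a `burden_class`, the unique
#' variant's `label` is `"LB"` when any carrier is LB (see
#' [label_mutations()] for the rationale).
#'
#' @param mut Mutation tibble.
#' @return Tibble of unique variants with an `n_donors` column (and `label`
#'   when burden classes are present), sorted by chromosome and position.
#' @export
distinct_variants <- function(mut) {
  opt <- intersect(c("mtype", "gene", "gene_length", "consequence",
                     "impact", "coding"), names(mut))
  g <- group_by(mut, .data$chrom, .data$pos, .data$ref, .data$alt)
  out <- summarise(
    g,
    dplyr::across(dplyr::all_of(opt), ~ .x[1]),
    n_donors = n_distinct(.data$donor_id),
    .groups = "drop"
  )
  if ("burden_class" %in% names(mut)) {
    lab <- summarise(
      g,
      label = ifelse(any(.data$burden_class == "LB"), "LB", "HB"),
      .groups = "drop"
    )
    out <- left_join(out, lab, by = c("chrom", "pos", "ref", "alt"))
  }
  arrange(out, .data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Read a per-mutation feature annotation table
#'
#' A feature table is a TSV keyed by `chrom, pos, ref, alt` followed by
#' numeric feature columns (for example the output of an external mutation
#' annotation pipeline). Feature annotation is consumed here, never
#' computed.
#'
#' @param path Path to the TSV.
#' @return Tibble with a `features` attribute naming the feature columns.
#' @export
read_feature_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("Feature table missing key column(s): ",
                 paste(miss, collapse = ", ")))
  }
  feats <- setdiff(names(x), need)
  if (length(feats) == 0) abort("Feature table has no feature columns.")
  x[feats] <- lapply(x[feats], as.numeric)
  .set_features(as_tibble(x), feats)
}

#' Join a mutation catalog to its feature annotations
#'
#' Deduplicates the catalog to unique variants, then inner-joins the feature
#' table on `(chrom, pos, ref, alt)`. Variants missing from the feature
#' table are dropped and their count reported via a message and the
#' `n_missing` attribute; per-variant donor counts (and burden labels, if
#' present) are carried through.
#'
#' @param mut Mutation tibble (records, possibly labeled).
#' @param features Feature table from [read_feature_table()] or
#'   [simulate_cohort()].
#' @return Feature-matrix tibble: unique variants x features, with
#'   attributes `features` (feature column names) and `n_missing`.
#' @export
join_features <- function(mut, features) {
  feats <- feature_names(features)
  key <- c("chrom", "pos", "ref", "alt")
  dup <- features[duplicated(features[key]), key, drop = FALSE]
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate feature rows for variant ",
                 variant_key(dup[1, ])))
  }
  uv <- distinct_variants(mut)
  fm <- inner_join(uv, features[, c(key, feats)], by = key)
  if (nrow(fm) == 0) {
    abort("No variants shared between catalog and feature table; check the coordinate convention of the keys.")
  }
  n_missing <- nrow(uv) - nrow(fm)
  if (n_missing > 0) {
    message(n_missing, " variant(s) had no feature annotation and were dropped.")
  }
  fm <- .set_features(fm, feats)
  attr(fm, "n_missing") <- n_missing
  fm
}
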