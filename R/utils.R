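# Internal helpers shared across modules.

# Columns that are never treated as model features.
.reserved_cols <- c(
  "chrom", "pos", "ref", "alt", "mtype", "donor_id", "n_donors",
  "burden_class", "label", "gene", "consequence", "impact", "gene_length",
  "coding", "raw_distance", "std_score", "rank", "patient_id", "focus_id",
  "allele_fraction", "depth", "alt_reads", "variant_key"
)

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Feature column names of a feature matrix
#'
#' Returns the names of the numeric feature columns of a mutation feature
#' matrix. If the table carries a `features` attribute (set by
#' [join_features()], [read_feature_table()] or the simulators) that is used;
#' otherwise all numeric columns whose names are not reserved bookkeeping
#' columns are taken.
#'
#' @param fm A feature-matrix tibble.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(fm) {
  ft <- attr(fm, "features")
  if (!is.null(ft)) {
    missing <- setdiff(ft, names(fm))
    if (length(missing) > 0) {
      abort(paste0("Feature columns absent from table: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    return(ft)
  }
  cand <- setdiff(names(fm), .reserved_cols)
  cand[vapply(fm[cand], is.numeric, logical(1))]
}

.set_features <- function(fm, feats) {
  attr(fm, "features") <- feats
  fm
}

.check_dna <- function(x, what, rows = NULL) {
  bad <- !grepl("^[ACGTN]+$", x)
  if (any(bad)) {
    where <- if (is.null(rows)) which(bad)[1] else rows[which(bad)[1]]
    abort(sprintf("Malformed %s allele at row %d: %s", what, where,
                  x[which(bad)[1]]))
  }
  invisible(TRUE)
}

.infer_mtype <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == nchar(alt) ~ "SNV",
    nchar(alt) > nchar(ref) ~ "INS",
    TRUE ~ "DEL"
  )
}

# Labels are handled as character "LB"/"HB" with LB the positive class.
.check_labels <- function(y) {
  if (!all(y %in% c("LB", "HB"))) {
    abort("Labels must be \"LB\" or \"HB\".")
  }
  if (length(unique(y)) < 2) {
    abort("Both LB and HB classes must be present.")
  }
  invisible(TRUE)
}
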