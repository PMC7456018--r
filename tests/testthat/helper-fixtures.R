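# Shared fixtures and independent brute-force oracles. Oracles enumerate or
# count directly and never call the code paths they check.

mk_mut <- function(chrom, pos, ref, alt, donor_id, ...) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    mtype = dplyr::case_when(
      nchar(ref) == nchar(alt) ~ "SNV",
      nchar(alt) > nchar(ref) ~ "INS",
      TRUE ~ "DEL"
    ),
    donor_id = donor_id, ...
  )
}

# Upper-tail hypergeometric probability by enumeration over all C(N, n)
# draws (feasible for N <= 12).
hyper_bruteforce <- function(N, K, n, k) {
  if (n == 0) return(1)
  draws <- utils::combn(N, n)
  in_cat <- draws <= K # categories are items 1..K by symmetry
  mean(colSums(in_cat) >= k)
}

# Per-base capture oracle: a call is captured iff any base of its 1-based
# reference span is covered by any probe (probes 0-based half-open).
capture_bruteforce <- function(calls, probes, genome_len = 20000L) {
  chroms <- unique(c(calls$chrom, probes$chrom))
  covered <- lapply(setNames(chroms, chroms),
                    function(.) logical(genome_len))
  for (i in seq_len(nrow(probes))) {
    b <- (probes$start[i] + 1L):probes$end[i] # 1-based bases
    covered[[probes$chrom[i]]][b] <- TRUE
  }
  vapply(seq_len(nrow(calls)), function(i) {
    span <- calls$pos[i]:(calls$pos[i] + nchar(calls$ref[i]) - 1L)
    any(covered[[calls$chrom[i]]][span])
  }, logical(1))
}

# Small labeled feature matrix with planted signal, via the package
# generator (used where the fixture itself is not under test).
small_fm <- function(n = 400, p = 10, m = 2, effect = 2, seed = 99,
                     lb_fraction = 0.5) {
  simulate_feature_matrix(n = n, n_features = p, n_informative = m,
                          effect_size = effect, lb_fraction = lb_fraction,
                          seed = seed)
}

# cfDNA screening fixtures: five cfDNA calls crossing each filter boundary,
# tumor calls with 1-3 foci per variant, and a germline-bearing normal.
cf_fixture <- function() {
  tibble::tibble(
    patient_id = "P1", focus_id = "cfdna", chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", alt = "T",
    depth = c(2500L, 2500L, 400L, 2500L, 2500L),
    alt_reads = c(20L, 1L, 50L, 100L, 600L),
    allele_fraction = c(0.008, 0.0004, 0.125, 0.04, 0.24)
  )
}

tumor_fixture <- function() {
  # pos 100 in 2 foci; 200 in 2; 300 in 2; 400 in 1; 500 in 3
  tibble::tibble(
    patient_id = "P1",
    focus_id = c("f1", "f2", "f1", "f2", "f2", "f3", "f1", "f1", "f2", "f3"),
    chrom = "chr1",
    pos = c(100L, 100L, 200L, 200L, 300L, 300L, 400L, 500L, 500L, 500L),
    ref = "A", alt = "T",
    depth = 200L, alt_reads = 40L, allele_fraction = 0.2
  )
}

normal_fixture <- function(extra = integer()) {
  tibble::tibble(
    patient_id = "P1", focus_id = "normal", chrom = "chr1",
    pos = c(9000L, extra), ref = "A", alt = "T",
    depth = 200L, alt_reads = 100L, allele_fraction = 0.5
  )
}

write_tmp_lines <- function(lines, ext) {
  f <- tempfile(fileext = ext) # session tempdir; cleaned up on exit
  writeLines(lines, f)
  f
}

tiny_vcf <- function() {
  write_tmp_lines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DONOR,Number=1,Type=String,Description=\"Donor id\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr1", "1000", ".", "A", "T", ".", "PASS", "DONOR=D1", sep = "\t"),
    paste("chr1", "1000", ".", "AT", "A", ".", "PASS", "DONOR=D2", sep = "\t"),
    paste("chr2", "500", ".", "G", "GAA,GA", ".", "PASS", "DONOR=D1",
          sep = "\t")
  ), ".vcf")
}

tiny_maf <- function() {
  hdr <- paste("Hugo_Symbol", "Chromosome", "Start_Position", "End_Position",
               "Variant_Type", "Reference_Allele", "Tumor_Seq_Allele2",
               "Tumor_Sample_Barcode", sep = "\t")
  write_tmp_lines(c(
    hdr,
    paste("TP53", "chr17", "7578406", "7578406", "SNP", "C", "T", "D1",
          sep = "\t"),
    paste("PTEN", "chr10", "89692905", "89692907", "DEL", "GAA", "-", "D1",
          sep = "\t"),
    paste("SPOP", "chr17", "47677742", "47677743", "INS", "-", "AG", "D2",
          sep = "\t")
  ), ".maf")
}
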