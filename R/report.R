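# Report arithmetic: the percentage and protein-length bookkeeping used in
# read-accounting tables and locus reports.

#' One-decimal percentage, rounded half-up
#'
#' `100 * numerator / denominator` rounded half-up to one decimal, the
#' convention used throughout read-accounting tables. A zero denominator
#' yields `NA` (UNDEFINED).
#'
#' @param numerator,denominator Numeric vectors (recycled).
#' @export
compute_percent <- function(numerator, denominator) {
  out <- floor(1000 * numerator / denominator + 0.5) / 10
  out[!is.finite(out) | rep_len(denominator <= 0, length(out))] <- NA_real_
  out
}

#' Protein length implied by a CDS length
#'
#' `cds_len_bp / 3 - 1` amino acids (the terminal stop codon is excluded).
#' Lengths not divisible by 3 are rejected: a genomic, intron-containing
#' length is not a CDS length.
#'
#' @param cds_len_bp Coding-sequence length in bp, divisible by 3.
#' @export
protein_length_from_cds <- function(cds_len_bp) {
  if (any(cds_len_bp %% 3 != 0)) {
    stop("CDS length must be divisible by 3 (a genomic length with introns ",
         "is not a CDS length)")
  }
  cds_len_bp / 3 - 1
}

#' Per-accession read-accounting table
#'
#' Totals count reads (mates); mapped and uniquely mapped counts are read
#' pairs. Trimming is modelled as identity (counts pass through), so
#' trimmed percentages are 100 unless a trimming rate is supplied.
#'
#' @param mappings Named list of `map_result` objects (one per accession).
#' @param trim_frac Fraction of reads surviving trimming (default 1).
#' @return A `read_stats` tibble: `accession`, `total_reads`,
#'   `trimmed_reads`, `trimmed_pct`, `mapped_pairs`, `unique_pairs`,
#'   `unique_pct` (percent of mapped pairs).
#' @export
read_stats <- function(mappings, trim_frac = 1) {
  out <- bind_rows(purrr::imap(mappings, function(m, nm) {
    total <- m$counts$total_reads
    trimmed <- floor(total * trim_frac)
    tibble(accession = nm,
           total_reads = total,
           trimmed_reads = trimmed,
           trimmed_pct = compute_percent(trimmed, total),
           mapped_pairs = m$counts$mapped_pairs,
           unique_pairs = m$counts$unique_pairs,
           unique_pct = compute_percent(m$counts$unique_pairs,
                                        m$counts$mapped_pairs))
  }))
  class(out) <- unique(c("read_stats", class(out)))
  out
}
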