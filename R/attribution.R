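# Donor attribution of reads by best hit against a panel of candidate
# source genomes (recipient reference + donors).
#
# Captured reads that fail to map to the reference often come from alien
# segments that were hybridization-captured but are too diverged to align.
# Classifying each read by its best local match across an explicit panel
# recovers their source: in a carrier accession, the donor fraction among
# unmapped reads exceeds the donor fraction among mapped reads.

#' Classify reads by best hit against a genome panel
#'
#' Each read is scored against every panel member with the word-seeded
#' local-hit engine (see [probe_hits()]); its label is the member with the
#' highest best-hit identity if that identity reaches `min_identity`,
#' `"AMBIGUOUS"` if the top two members lie within `ambiguity_margin` of
#' each other, and `"NO_HIT"` otherwise.
#'
#' @param reads Character vector of read sequences (names become read ids).
#' @param panel Named list (or named character vector) of panel member
#'   sequences; a member may hold several sequences (chromosomes).
#' @param min_identity Minimum best-hit identity (matches / read length).
#' @param ambiguity_margin Identity margin below which the top two panel
#'   members are indistinguishable.
#' @param word_size Seed length for the local-hit engine.
#' @return An `attribution_table` object: `reads` (per-read best label,
#'   best identity, margin over the runner-up) and `summary` (count,
#'   fraction, and one-decimal percent per label; fractions sum to 1).
#' @export
classify_reads <- function(reads, panel, min_identity = 0.80,
                           ambiguity_margin = 0.02, word_size = 11) {
  if (length(panel) == 0) stop("panel must be non-empty")
  if (is.character(panel) && !is.list(panel)) panel <- as.list(panel)
  if (is.null(names(panel)) || anyDuplicated(names(panel))) {
    stop("panel labels must be present and unique")
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))

  ident <- matrix(0, length(reads), length(panel),
                  dimnames = list(names(reads), names(panel)))
  for (m in names(panel)) {
    tseq <- genome_seqs(panel[[m]])
    raw <- cpp_local_hits(unname(reads), unname(tseq), min_identity, 0.80,
                          as.integer(word_size))
    if (nrow(raw) > 0) {
      best <- tapply(raw$matches / nchar(reads)[raw$query_idx],
                     raw$query_idx, max)
      ident[as.integer(names(best)), m] <- best
    }
  }
  if (ncol(ident) > 1) {
    ord <- t(apply(ident, 1, sort, decreasing = TRUE))
    best <- ord[, 1]
    second <- ord[, 2]
  } else {
    best <- ident[, 1]
    second <- rep(0, nrow(ident))
  }
  best_label <- colnames(ident)[max.col(ident, ties.method = "first")]
  label <- ifelse(best < min_identity, "NO_HIT",
                  ifelse(best - second < ambiguity_margin, "AMBIGUOUS",
                         best_label))
  per_read <- tibble(read_id = names(reads), label = unname(label),
                     best_identity = unname(best),
                     margin = unname(best - second))
  lv <- c(names(panel), "AMBIGUOUS", "NO_HIT")
  counts <- table(factor(label, levels = lv))
  summary <- tibble(label = lv, n = as.integer(counts),
                    fraction = as.integer(counts) / length(reads),
                    percent = compute_percent(as.integer(counts),
                                              length(reads)))
  structure(list(reads = per_read, summary = summary),
            class = "attribution_table")
}

#' @export
print.attribution_table <- function(x, ...) {
  cat("<attribution_table> ", nrow(x$reads), " reads\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Fraction of reads attributed to donor panel members
#'
#' @param x An `attribution_table`.
#' @param donors Donor labels; defaults to every panel label except
#'   `"reference"`.
#' @export
donor_fraction <- function(x, donors = NULL) {
  s <- x$summary[!x$summary$label %in% c("NO_HIT", "AMBIGUOUS"), ]
  if (is.null(donors)) donors <- setdiff(s$label, "reference")
  sum(s$fraction[s$label %in% donors])
}
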