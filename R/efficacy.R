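# In-silico probe efficacy (hit counting against candidate assemblies) and
# global-alignment locus comparison for indel diagnosis.
#
# probe_hits() mirrors the in-silico check of scoring a capture probe set
# against the recipient and donor assemblies: more probes hit the closer
# assembly and with higher identity, which predicts where capture (and
# subsequent mapping) will fail. locus_align() is a Needleman-Wunsch
# global aligner with linear gap costs used to diagnose small indels that
# distinguish donor haplotypes from the recipient at a captured locus.

#' Score capture probes against a target assembly
#'
#' A hit is a word-seeded, ungapped full-diagonal placement of the probe on
#' the target (either strand) covering at least `min_cov` of the probe with
#' identity (matches / probe length) at least `min_identity`. Multiple
#' qualifying placements of one probe all count as hits.
#'
#' @param probes A `probe_set` tibble (or named character vector of probe
#'   sequences).
#' @param target Target sequence(s): genome object, named character vector,
#'   or single string.
#' @param min_identity Minimum identity (matches / probe length), default
#'   0.80 -- the widest published capture tolerance.
#' @param min_cov Minimum probe coverage of the placement window.
#' @param word_size Exact-match seed length (default 11).
#' @return A `hit_summary` object: `summary` (one row: `n_probes`,
#'   `n_hits`, `n_probes_with_hit`, `n_single_hit_probes`,
#'   `mean_best_identity`) and `hits` (per-hit table).
#' @export
probe_hits <- function(probes, target, min_identity = 0.80, min_cov = 0.80,
                       word_size = 11) {
  if (is.data.frame(probes)) {
    qseq <- setNames(probes$seq, probes$probe_id)
  } else {
    qseq <- probes
    if (is.null(names(qseq))) names(qseq) <- sprintf("q%05d", seq_along(qseq))
  }
  tseq <- genome_seqs(target)
  if (is.null(names(tseq))) names(tseq) <- sprintf("target%d", seq_along(tseq))
  if (word_size > min(nchar(qseq))) stop("word_size exceeds a probe length")

  raw <- as_tibble(cpp_local_hits(unname(qseq), unname(tseq),
                                  min_identity, min_cov, as.integer(word_size)))
  hits <- tibble(probe_id = names(qseq)[raw$query_idx],
                 target = names(tseq)[raw$target_idx],
                 tstart = raw$tstart,
                 strand = ifelse(raw$strand == 0, "+", "-"),
                 matches = raw$matches, win_len = raw$win_len,
                 identity = raw$matches / nchar(qseq)[raw$query_idx],
                 coverage = raw$win_len / nchar(qseq)[raw$query_idx])
  best <- if (nrow(hits) == 0) {
    tibble(probe_id = character(), n_hits = integer(),
           best_identity = numeric())
  } else {
    hits |>
      group_by(.data$probe_id) |>
      summarise(n_hits = n(), best_identity = max(.data$identity),
                .groups = "drop")
  }
  summary <- tibble(
    n_probes = length(qseq),
    n_hits = nrow(hits),
    n_probes_with_hit = nrow(best),
    n_single_hit_probes = sum(best$n_hits == 1),
    mean_best_identity = if (nrow(best) > 0) 100 * mean(best$best_identity)
                         else NA_real_)
  structure(list(summary = summary, hits = hits, per_probe = best),
            class = "hit_summary")
}

#' @export
print.hit_summary <- function(x, ...) {
  s <- x$summary
  cat("<hit_summary> ", s$n_hits, " hits; ", s$n_probes_with_hit, "/",
      s$n_probes, " probes with a hit (", s$n_single_hit_probes,
      " single-hit); mean best identity ",
      formatC(s$mean_best_identity, format = "f", digits = 1), "%\n",
      sep = "")
  invisible(x)
}

#' Global alignment of two loci with indel extraction
#'
#' Optimal Needleman-Wunsch global alignment under linear gap costs
#' (match +1, mismatch -1, gap -2 by default). Indel events are extracted
#' from gap runs and reported in the frame of `seq_a` (the reference):
#' a gap run in `seq_a` is an insertion (bases present in `seq_b`), a gap
#' run in `seq_b` a deletion, with `ref_pos` the 0-based reference offset
#' at which the event occurs.
#'
#' @param seq_a Reference-side sequence (<= 100 kb).
#' @param seq_b Query-side sequence (<= 100 kb).
#' @param match,mismatch,gap Scoring parameters.
#' @return A `locus_alignment` object: `alignment` (gapped pair),
#'   `score`, `indels` tibble (`ref_pos`, `length`, `kind`, `seq`),
#'   `percent_identity` (matches / alignment columns x 100).
#' @export
locus_align <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  if (nchar(seq_a) > 1e5 || nchar(seq_b) > 1e5) {
    stop("sequences must be <= 100 kb (quadratic algorithm)")
  }
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    a_al <- if (nchar(seq_a) == 0) strrep("-", nchar(seq_b)) else seq_a
    b_al <- if (nchar(seq_b) == 0) strrep("-", nchar(seq_a)) else seq_b
    return(new_locus_alignment(a_al, b_al, match, mismatch, gap))
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = -gap)
  new_locus_alignment(as.character(Biostrings::alignedPattern(pa)),
                      as.character(Biostrings::alignedSubject(pa)),
                      match, mismatch, gap)
}

new_locus_alignment <- function(a_al, b_al, match, mismatch, gap) {
  a_chr <- strsplit(a_al, "")[[1]]
  b_chr <- strsplit(b_al, "")[[1]]
  gap_a <- a_chr == "-"
  gap_b <- b_chr == "-"
  is_match <- !gap_a & !gap_b & a_chr == b_chr
  score <- sum(is_match) * match + sum(!gap_a & !gap_b & !is_match) * mismatch +
    sum(gap_a | gap_b) * gap
  ref_pos_at <- cumsum(!gap_a)  # ref bases consumed up to each column

  extract <- function(gapmask, kind, src_chr) {
    r <- rle(gapmask)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1
    keep <- which(r$values)
    if (length(keep) == 0) {
      return(tibble(ref_pos = numeric(), length = integer(),
                    kind = character(), seq = character()))
    }
    tibble(
      ref_pos = vapply(keep, function(i) {
        if (idx_start[i] == 1) 0 else ref_pos_at[idx_start[i] - 1]
      }, numeric(1)),
      length = r$lengths[keep],
      kind = kind,
      seq = vapply(keep, function(i) {
        paste(src_chr[idx_start[i]:idx_end[i]], collapse = "")
      }, character(1)))
  }
  indels <- bind_rows(extract(gap_a, "insertion", b_chr),
                      extract(gap_b, "deletion", a_chr)) |>
    arrange(.data$ref_pos)
  structure(
    list(alignment = c(a = a_al, b = b_al), score = score, indels = indels,
         matches = sum(is_match), columns = length(a_chr),
         percent_identity = 100 * sum(is_match) / length(a_chr)),
    class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> score ", x$score, ", identity ",
      formatC(x$percent_identity, format = "f", digits = 1), "% (",
      x$matches, "/", x$columns, "), ", nrow(x$indels), " indel event(s)\n",
      sep = "")
  invisible(x)
}

#' Assign a query sequence to its nearest candidate reference
#'
#' Aligns the query globally to each candidate and reports percent identity
#' per candidate; the verdict is the candidate with the highest identity,
#' or `"AMBIGUOUS"` on an exact tie.
#'
#' @param query Query sequence.
#' @param candidates Named character vector of >= 2 candidate sequences.
#' @param ... Passed to [locus_align()].
#' @return A `nearest_reference` object: `table` (per-candidate score and
#'   identity) and `verdict`.
#' @export
assign_nearest_reference <- function(query, candidates, ...) {
  if (length(candidates) < 2) stop("need >= 2 candidate references")
  if (is.null(names(candidates))) {
    names(candidates) <- sprintf("candidate%d", seq_along(candidates))
  }
  tab <- bind_rows(purrr::imap(candidates, function(s, nm) {
    al <- locus_align(s, query, ...)
    tibble(candidate = nm, score = al$score,
           percent_identity = al$percent_identity)
  }))
  best <- max(tab$percent_identity)
  top <- tab$candidate[tab$percent_identity == best]
  structure(list(table = tab,
                 verdict = if (length(top) == 1) top else "AMBIGUOUS"),
            class = "nearest_reference")
}

#' @export
print.nearest_reference <- function(x, ...) {
  cat("<nearest_reference> verdict: ", x$verdict, "\n", sep = "")
  print(x$table)
  invisible(x)
}
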