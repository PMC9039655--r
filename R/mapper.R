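# Seed-and-extend read mapping with an explicit uniqueness criterion.
#
# Reads are placed by exact k-mer seeds and scored by full-length ungapped
# Hamming distance. With disjoint seeds and a mismatch budget smaller than
# the number of seeds, the pigeonhole principle guarantees every locus
# within the budget is found, so the mapper is exactly equivalent to an
# exhaustive all-positions scan. A read is uniquely mapped iff its best
# locus beats the second best by at least `unique_margin` mismatches; only
# uniquely mapped, properly paired reads feed the depth profile. Reads more
# diverged than the budget fall out unmapped -- the mechanism that converts
# alien-segment divergence into coverage drops.

#' Build an exact k-mer seed index over a genome
#'
#' @param reference A [make_reference()] genome (or named character vector).
#' @param k Seed length, between 11 and 31. The pigeonhole guarantee of
#'   exhaustive-equivalent mapping holds when
#'   `floor(max_mismatch_frac * read_len) < floor(read_len / k)`.
#' @return A `seed_index` object.
#' @export
build_index <- function(reference, k = 15) {
  if (k < 11 || k > 31) stop("k must be between 11 and 31")
  seqs <- genome_seqs(reference)
  ptr <- cpp_build_index(unname(seqs), names(seqs), as.integer(k))
  structure(list(ptr = ptr, k = k, chrom = names(seqs),
                 length = setNames(nchar(seqs), names(seqs))),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat("<seed_index> k = ", x$k, ", ", format(info$n_kmers, big.mark = ","),
      " seeds over ", length(x$chrom), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Look up the reference positions of one k-mer
#'
#' @param index A [build_index()] index.
#' @param kmer A k-length string.
#' @return Tibble of `chrom`, `start` (0-based) hits; empty if absent.
#' @export
index_lookup <- function(index, kmer) {
  gpos <- cpp_index_lookup(index$ptr, kmer)
  offs <- cumsum(c(0, unname(index$length)))
  ci <- findInterval(gpos, offs[-length(offs)], rightmost.closed = FALSE)
  tibble(chrom = index$chrom[ci], start = gpos - offs[ci])
}

#' Map a paired read set to the reference
#'
#' Each mate is mapped independently (both strands); a pair is "uniquely
#' mapped, paired" iff both mates are unique, on the same chromosome, in
#' forward/reverse orientation, and the implied fragment is positive and at
#' most `frag_mean + 4 * frag_sd`.
#'
#' @param reads A `read_set` tibble (or tibble with `pair_id`, `mate1`,
#'   `mate2`).
#' @param index A [build_index()] index.
#' @param max_mismatch_frac Mismatch budget as a fraction of read length
#'   (default 0.06 -- between primary-tier and tertiary-tier divergence).
#' @param unique_margin Minimum mismatch gap between best and second-best
#'   locus for a mate to count as unique.
#' @param frag_mean,frag_sd Expected fragment-length distribution used for
#'   the proper-pair bound.
#' @return A `map_result` object: `alignments` (mates of uniquely mapped,
#'   properly paired reads), `mate_status` (per-mate
#'   unmapped/unique/multimapped), `pairs`, and `counts`.
#' @export
map_reads <- function(reads, index, max_mismatch_frac = 0.06,
                      unique_margin = 1, frag_mean = 300, frag_sd = 30) {
  stopifnot(inherits(index, "seed_index"))
  if (nrow(reads) == 0) stop("reads must be non-empty")
  read_len <- nchar(reads$mate1[1])
  if (any(nchar(c(reads$mate1, reads$mate2)) < index$k)) {
    warning("reads shorter than the seed length k are counted unmapped")
  }

  res <- purrr::map(1:2, function(mate) {
    df <- as_tibble(cpp_map_reads(index$ptr, reads[[paste0("mate", mate)]],
                                  max_mismatch_frac, as.integer(unique_margin)))
    df$pair_id <- reads$pair_id
    df$mate <- mate
    df$read_id <- paste0(reads$pair_id, "/", mate)
    df$chrom <- ifelse(is.na(df$chrom_idx), NA_character_,
                       index$chrom[df$chrom_idx])
    df$read_len <- nchar(reads[[paste0("mate", mate)]])
    df
  })
  m1 <- res[[1]]; m2 <- res[[2]]

  both_unique <- m1$status == 1 & m2$status == 1
  same_chrom <- both_unique & m1$chrom == m2$chrom
  opp_strand <- same_chrom & (m1$strand != m2$strand)
  fwd_start <- ifelse(m1$strand == 0, m1$start, m2$start)
  rev_start <- ifelse(m1$strand == 1, m1$start, m2$start)
  rev_len <- ifelse(m1$strand == 1, m1$read_len, m2$read_len)
  frag <- rev_start + rev_len - fwd_start
  proper <- opp_strand & !is.na(frag) & frag > 0 & fwd_start <= rev_start &
    frag <= frag_mean + 4 * frag_sd
  proper[is.na(proper)] <- FALSE

  mate_status <- bind_rows(m1, m2) |>
    mutate(status = c("unmapped", "unique", "multimapped")[.data$status + 1]) |>
    select("read_id", "pair_id", "mate", "status", "chrom", "start",
           "strand", "mismatches", "n_candidates")

  aln <- bind_rows(m1[proper, ], m2[proper, ]) |>
    mutate(end = .data$start + .data$read_len,
           strand = ifelse(.data$strand == 0, "+", "-")) |>
    select("read_id", "pair_id", "mate", "chrom", "start", "end", "strand",
           "mismatches") |>
    arrange(.data$chrom, .data$start)

  both_mapped <- m1$status > 0 & m2$status > 0
  pairs <- tibble(pair_id = reads$pair_id,
                  both_mapped = both_mapped,
                  unique_proper = proper)
  counts <- tibble(total_reads = 2L * nrow(reads),
                   mapped_pairs = sum(both_mapped),
                   unique_pairs = sum(proper))
  structure(list(alignments = aln, mate_status = mate_status, pairs = pairs,
                 counts = counts, read_len = read_len,
                 accession = attr(reads, "accession") %||% NA_character_),
            class = "map_result")
}

#' @export
print.map_result <- function(x, ...) {
  cat("<map_result> ", x$counts$total_reads, " reads; ",
      x$counts$mapped_pairs, " mapped pairs; ", x$counts$unique_pairs,
      " uniquely mapped, properly paired\n", sep = "")
  invisible(x)
}

#' Per-mate id sets partitioning the input reads
#' @param x A `map_result`.
#' @export
read_id_sets <- function(x) {
  split(x$mate_status$read_id, x$mate_status$status)
}

#' Extract unmapped (or mapped) mate sequences for attribution
#'
#' @param x A `map_result`.
#' @param reads The read set that was mapped.
#' @param which `"unmapped"`, `"unique"`, or `"multimapped"`.
#' @return Named character vector of mate sequences.
#' @export
mate_sequences <- function(x, reads, which = "unmapped") {
  ms <- x$mate_status[x$mate_status$status == which, ]
  i <- match(ms$pair_id, reads$pair_id)
  setNames(ifelse(ms$mate == 1, reads$mate1[i], reads$mate2[i]), ms$read_id)
}
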