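# Zero-inclusive binned coverage, cohort normalization, drop calling, and
# overlap annotation against known-introgression intervals.
#
# Depth counts only mates of uniquely mapped, properly paired reads (each
# mate independently). Bin means include zero-coverage bases -- without
# zero inclusion, deletions and uncaptured alien segments simply vanish
# from the profile. Drops are judged cohort-relatively: each accession's
# library-size-scaled bins are divided by the per-bin cohort median, so a
# drop is a region where one accession sits well below the accessions that
# do not carry the alien segment.

#' Per-base depth over one chromosome
#'
#' `depth[i]` is the number of read bases covering position `i` (0-based);
#' overlapping mates of one pair count twice.
#'
#' @param mapping A `map_result` from [map_reads()].
#' @param chrom Chromosome name.
#' @param chrom_len Chromosome length.
#' @return Numeric vector of length `chrom_len`.
#' @export
depth_per_base <- function(mapping, chrom, chrom_len) {
  aln <- mapping$alignments[mapping$alignments$chrom == chrom, ]
  if (nrow(aln) > 0 && any(aln$end > chrom_len)) {
    stop("alignment beyond chromosome end on ", chrom)
  }
  if (nrow(aln) == 0) return(numeric(chrom_len))
  delta <- tabulate(aln$start + 1, nbins = chrom_len + 1) -
    tabulate(aln$end + 1, nbins = chrom_len + 1)
  cumsum(delta)[seq_len(chrom_len)]
}

#' Mean depth over fixed-width bins (zero-inclusive)
#'
#' Bins tile the chromosome; the last bin may be short and its mean uses
#' its true length. `sum(mean_depth * (bin_end - bin_start))` equals
#' `sum(depth)` exactly.
#'
#' @param depth Per-base depth vector.
#' @param bin_width Bin width in bp (>= 1).
#' @return Tibble of `bin_start`, `bin_end`, `mean_depth`.
#' @export
bin_coverage <- function(depth, bin_width) {
  if (bin_width < 1) stop("bin_width must be >= 1")
  n <- length(depth)
  starts <- seq(0, n - 1, by = bin_width)
  ends <- pmin(starts + bin_width, n)
  cs <- c(0, cumsum(depth))
  tibble(bin_start = starts, bin_end = ends,
         mean_depth = (cs[ends + 1] - cs[starts + 1]) / (ends - starts))
}

#' Binned coverage profile for one mapped accession
#'
#' @param mapping A `map_result`.
#' @param lengths Named chromosome lengths (or a genome object).
#' @param bin_width Bin width in bp.
#' @param accession Accession id (defaults to the read set's).
#' @return A coverage tibble: `accession`, `chrom`, `bin_start`, `bin_end`,
#'   `mean_depth`.
#' @export
coverage_profile <- function(mapping, lengths, bin_width,
                             accession = mapping$accession) {
  if (!is.numeric(lengths)) lengths <- nchar(genome_seqs(lengths))
  bind_rows(purrr::imap(lengths, function(len, ch) {
    b <- bin_coverage(depth_per_base(mapping, ch, len), bin_width)
    tibble(accession = accession, chrom = ch, b)
  }))
}

#' Cohort-normalize binned coverage profiles
#'
#' Each accession's bins are first scaled by its genome-wide mean depth
#' (library-size correction), then divided per-bin by the cohort median of
#' the scaled values. Bins whose cohort median is 0 get `NA` ratios
#' (UNDEFINED) and never support a drop call. The median (not the mean) is
#' the baseline so that a drop shared by several carriers does not drag the
#' cohort level down with it.
#'
#' @param profiles Row-bound [coverage_profile()] tibbles for >= 3
#'   accessions with identical binning.
#' @return The input with `scaled` and `ratio` columns added.
#' @export
normalize_profiles <- function(profiles) {
  if (length(unique(profiles$accession)) < 3) {
    stop("cohort normalization needs >= 3 accessions (median baseline)")
  }
  bins_per_acc <- table(profiles$accession)
  if (length(unique(bins_per_acc)) != 1) {
    stop("profiles must share identical binning across accessions")
  }
  out <- profiles |>
    group_by(.data$accession) |>
    mutate(scaled = .data$mean_depth /
             (sum(.data$mean_depth * (.data$bin_end - .data$bin_start)) /
                sum(.data$bin_end - .data$bin_start))) |>
    group_by(.data$chrom, .data$bin_start) |>
    mutate(cohort_median = median(.data$scaled),
           ratio = ifelse(.data$cohort_median > 0,
                          .data$scaled / .data$cohort_median, NA_real_)) |>
    ungroup() |>
    select(-"cohort_median")
  class(out) <- unique(c("coverage_norm", class(out)))
  out
}

#' Call coverage-drop intervals
#'
#' A drop is a maximal run of at least `min_bins` consecutive bins whose
#' normalized ratio is below `alpha`. UNDEFINED (NA) bins break runs.
#'
#' @param normalized A [normalize_profiles()] tibble.
#' @param alpha Ratio threshold (default 0.5).
#' @param min_bins Minimum run length in bins (default 2).
#' @return A `drop_calls` tibble: `accession`, `chrom`, `start`, `end`,
#'   `n_bins`, `mean_ratio`.
#' @export
call_drops <- function(normalized, alpha = 0.5, min_bins = 2) {
  out <- normalized |>
    group_by(.data$accession, .data$chrom) |>
    arrange(.data$bin_start, .by_group = TRUE) |>
    dplyr::reframe(.drop_runs(.data$bin_start, .data$bin_end, .data$ratio,
                              alpha, min_bins))
  class(out) <- unique(c("drop_calls", class(out)))
  out
}

.drop_runs <- function(bin_start, bin_end, ratio, alpha, min_bins) {
  flag <- !is.na(ratio) & ratio < alpha
  r <- rle(flag)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1
  keep <- r$values & r$lengths >= min_bins
  tibble(start = bin_start[idx_start[keep]],
         end = bin_end[idx_end[keep]],
         n_bins = r$lengths[keep],
         mean_ratio = vapply(which(keep), function(i) {
           mean(ratio[idx_start[i]:idx_end[i]])
         }, numeric(1)))
}

#' Annotate drop calls with overlapping known intervals
#'
#' @param calls A [call_drops()] tibble.
#' @param known Known intervals: a tibble (`chrom`, `start`, `end`,
#'   optionally `label`) or a BED path read with [read_bed()].
#' @return One row per (call, overlapping known interval) with the overlap
#'   length and Jaccard index (`|intersection| / |union|`); calls without
#'   any overlap keep one row with NA annotation.
#' @export
annotate_drops <- function(calls, known) {
  if (is.character(known)) known <- read_bed(known)
  calls <- mutate(ungroup(calls), call_id = row_number())
  base <- select(calls, "call_id", "accession", "chrom", "start", "end",
                 "n_bins", "mean_ratio")
  if (nrow(calls) == 0 || is.null(known) || nrow(known) == 0) {
    return(mutate(base, label = NA_character_, known_start = NA_real_,
                  known_end = NA_real_, overlap = NA_real_,
                  jaccard = NA_real_))
  }
  if (!"label" %in% names(known)) known$label <- sprintf("known_%d", seq_len(nrow(known)))
  hits <- bind_rows(purrr::map(unique(calls$chrom), function(ch) {
    ca <- calls[calls$chrom == ch, ]
    kn <- known[known$chrom == ch, ]
    if (nrow(ca) == 0 || nrow(kn) == 0) return(NULL)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(ca$start + 1, ca$end),
      IRanges::IRanges(kn$start + 1, kn$end))
    if (length(ov) == 0) return(NULL)
    ci <- S4Vectors::queryHits(ov); ki <- S4Vectors::subjectHits(ov)
    inter <- pmin(ca$end[ci], kn$end[ki]) - pmax(ca$start[ci], kn$start[ki])
    uni <- pmax(ca$end[ci], kn$end[ki]) - pmin(ca$start[ci], kn$start[ki])
    tibble(call_id = ca$call_id[ci], label = kn$label[ki],
           known_start = kn$start[ki], known_end = kn$end[ki],
           overlap = inter, jaccard = inter / uni)
  }))
  out <- left_join(base, hits, by = "call_id")
  class(out) <- unique(c("drop_annotations", class(out)))
  out
}

#' Jaccard index of two 0-based half-open intervals
#' @param s1,e1,s2,e2 Interval bounds.
#' @export
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  uni <- pmax(e1, e2) - pmin(s1, s2)
  ifelse(uni > 0, inter / uni, NA_real_)
}
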