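# Shared fixtures: small genomes, a miniature cohort configuration, and a
# memoised demo-scale run for the end-to-end checks.

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

mutate_bases_for_test <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  ch[hit] <- vapply(ch[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(ch, collapse = "")
}

rand_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

tiny_ref <- function(lengths = c(chrA = 5e4, chrB = 3e4), fracs = 0.45,
                     seed = 101) {
  make_reference(lengths, fracs, seed = seed)
}

# Miniature cohort: one tertiary whole-segment carrier, one primary-segment
# carrier, one deletion carrier, one plain accession; 5 kb bins.
mini_config <- function(seed = 1) {
  cfg <- demo_config(seed)
  cfg$chrom_lengths <- c(c1 = 3e5, c2 = 35e4, c3 = 25e4)
  cfg$centromere_fracs <- c(0.40, 0.45, 0.45)
  cfg$accessions <- list(
    a1 = tibble::tibble(chrom = "c1", start = 0, end = 1.2e5, donor = "donorT"),
    a2 = tibble::tibble(chrom = "c2", start = 2e5, end = 2.3e5, donor = "donorP"),
    a3 = tibble::tibble(chrom = "c3", start = 1.5e5, end = 2e5, donor = "DELETION"),
    a4 = tibble::tibble(chrom = "c1", start = 0, end = 0, donor = character(0))[0, ])
  cfg$n_probes <- 700
  cfg$gradient_slope <- 1
  cfg$mean_depth <- 15
  cfg$bin_width <- 1e4
  cfg$n_markers <- 400
  cfg$attribution <- list(accession = "a1", chrom = "c1", donor = "donorT",
                          max_reads = 400, min_identity = 0.80,
                          ambiguity_margin = 0.02)
  cfg$efficacy_chrom <- "c1"
  cfg
}

# The demo-scale run is expensive; compute it once per test session.
.run_cache <- new.env(parent = emptyenv())
get_demo_run <- function(seed = 42) {
  key <- paste0("run", seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_pipeline(demo_config(seed), quiet = TRUE)
  }
  .run_cache[[key]]
}

# Jaccard of the union of calls overlapping a truth interval (calls are
# disjoint within an accession).
union_jaccard <- function(calls, start, end) {
  ov <- pmax(0, pmin(calls$end, end) - pmax(calls$start, start))
  keep <- ov > 0
  inter <- sum(ov[keep])
  union <- (end - start) + sum(calls$end[keep] - calls$start[keep]) - inter
  if (union == 0) 0 else inter / union
}

get_mini_run <- function(seed = 1) {
  key <- paste0("mini", seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_pipeline(mini_config(seed), quiet = TRUE)
  }
  .run_cache[[key]]
}
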