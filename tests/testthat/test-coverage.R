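# Depth, zero-inclusive binning, cohort normalization, drop calling,
# and overlap annotation.

fake_mapping <- function(starts, ends, chrom = "chr1") {
  structure(list(
    alignments = tibble::tibble(
      read_id = sprintf("r%d", seq_along(starts)), pair_id = "p", mate = 1L,
      chrom = chrom, start = starts, end = ends, strand = "+",
      mismatches = 0L),
    counts = tibble::tibble(total_reads = length(starts),
                            mapped_pairs = length(starts) %/% 2,
                            unique_pairs = length(starts) %/% 2),
    accession = "fake"), class = "map_result")
}

test_that("per-base depth counts read bases, mates independently", {
  expect_equal(depth_per_base(fake_mapping(numeric(0), numeric(0)),
                              "chr1", 600),
               numeric(600))
  d <- depth_per_base(fake_mapping(c(100, 400), c(250, 550)), "chr1", 600)
  expect_equal(sum(d), 300)
  expect_true(all(d[101:250] == 1) && all(d[401:550] == 1))
  expect_true(all(d[c(1:100, 251:400, 551:600)] == 0))
  expect_error(depth_per_base(fake_mapping(500, 650), "chr1", 600), "beyond")
})

test_that("sum of depth equals mapped mates times read length (simulated)", {
  run <- get_mini_run()
  m <- run$mappings[[1]]
  lens <- nchar(run$reference$seq)
  total <- sum(vapply(names(lens), function(ch) {
    sum(depth_per_base(m, ch, lens[[ch]]))
  }, numeric(1)))
  expect_equal(total, nrow(m$alignments) * m$read_len)
})

test_that("binned means are zero-inclusive and conserve total depth", {
  expect_equal(bin_coverage(numeric(1000), 300)$mean_depth, rep(0, 4))
  b <- bin_coverage(rep(3, 1000), 300)
  expect_equal(b$mean_depth, rep(3, 4))       # short last bin included
  expect_equal(b$bin_end[4], 1000)

  withr::with_seed(5, {
    depth <- rpois(10000, 2)
    b <- bin_coverage(depth, 512)
    expect_equal(sum(b$mean_depth * (b$bin_end - b$bin_start)), sum(depth))
  })
  expect_error(bin_coverage(1:10, 0), ">= 1")
})

cohort_profiles <- function(depths, bin_width = 100) {
  dplyr::bind_rows(purrr::imap(depths, function(d, nm) {
    tibble::tibble(accession = nm, chrom = "c", bin_coverage(d, bin_width))
  }))
}

test_that("cohort normalization is median-based and scale-invariant", {
  base <- rep(c(4, 8, 4, 2), each = 250)
  prof <- cohort_profiles(list(a = base, b = base, c = base))
  norm <- normalize_profiles(prof)
  expect_true(all(abs(norm$ratio - 1) < 1e-12))

  # one accession at half depth in one bin
  half <- base; half[1:100] <- base[1:100] / 2
  prof2 <- cohort_profiles(list(a = base, b = base, c = base, d = half))
  norm2 <- normalize_profiles(prof2)
  r <- norm2$ratio[norm2$accession == "d"][1]
  scale_d <- sum(half) / length(half)
  scale_a <- sum(base) / length(base)
  expect_equal(r, (2 / scale_d) / ((4 / scale_a)), tolerance = 1e-12)

  # ratios invariant to multiplying one accession's raw depths by a constant
  withr::with_seed(8, {
    for (const in runif(5, 0.2, 9)) {
      prof3 <- cohort_profiles(list(a = base, b = base, c = half * const))
      norm3 <- normalize_profiles(prof3)
      ref3 <- normalize_profiles(cohort_profiles(list(a = base, b = base,
                                                      c = half)))
      expect_equal(norm3$ratio, ref3$ratio, tolerance = 1e-9)
    }
  })

  expect_error(normalize_profiles(cohort_profiles(list(a = base, b = base))),
               ">= 3")
})

test_that("drop calling flags runs below alpha and respects UNDEFINED bins", {
  base <- rep(4, 1000)
  low <- base; low[301:600] <- 0.4          # 3 bins at ratio ~0.1
  norm <- normalize_profiles(cohort_profiles(list(a = base, b = base,
                                                  c = base, d = low)))
  expect_equal(nrow(call_drops(norm, alpha = 0)), 0)

  calls <- call_drops(norm, alpha = 0.5, min_bins = 2)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$accession, "d")
  expect_equal(c(calls$start, calls$end), c(300, 600))
  expect_equal(calls$n_bins, 3L)

  flat <- normalize_profiles(cohort_profiles(list(a = base, b = base,
                                                  c = base)))
  expect_equal(nrow(call_drops(flat)), 0)

  # an UNDEFINED (cohort-median-zero) bin breaks a run
  gap <- base; gap[401:500] <- 0            # all accessions zero in bin 5
  lowgap <- gap; lowgap[301:600] <- 0
  norm2 <- normalize_profiles(cohort_profiles(list(a = gap, b = gap, c = gap,
                                                   d = lowgap)))
  calls2 <- call_drops(norm2, alpha = 0.5, min_bins = 1)
  expect_equal(nrow(calls2), 2)  # run split around the undefined bin
})

test_that("annotation overlap and Jaccard match a per-base set oracle", {
  calls <- tibble::tibble(accession = "a", chrom = "c", start = 0, end = 10,
                          n_bins = 2L, mean_ratio = 0.1)
  known <- tibble::tibble(chrom = "c", start = 5, end = 15, label = "k1")
  ann <- annotate_drops(calls, known)
  expect_equal(ann$overlap, 5)
  expect_equal(ann$jaccard, 5 / 15)

  empty <- annotate_drops(calls, known[0, ])
  expect_true(is.na(empty$label))

  withr::with_seed(12, {
    for (i in 1:100) {
      s1 <- sample(0:50, 1); e1 <- s1 + sample(1:30, 1)
      s2 <- sample(0:50, 1); e2 <- s2 + sample(1:30, 1)
      a <- seq(s1, e1 - 1); b <- seq(s2, e2 - 1)
      expect_equal(interval_jaccard(s1, e1, s2, e2),
                   length(intersect(a, b)) / length(union(a, b)))
    }
  })
})

test_that("malformed BED lines are rejected with their line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t0\t100\tok", "c1\t50\tnope"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("c1\t0\t100", "c1\t90\t20"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("# comment", "c1\t0\t100\tlab"), f)
  bed <- read_bed(f)
  expect_equal(bed$label, "lab")
})
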