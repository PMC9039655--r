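# Probe-vs-assembly hit analysis and global-alignment indel diagnosis.

test_that("probes hit their own source genome perfectly", {
  ref <- tiny_ref()
  probes <- design_probes(ref, 80, seed = 41)
  hs <- probe_hits(probes, ref)
  expect_equal(hs$summary$n_probes_with_hit, 80)
  expect_equal(hs$summary$mean_best_identity, 100)
  expect_gte(hs$summary$n_hits, hs$summary$n_probes_with_hit)
  expect_lte(hs$summary$n_single_hit_probes, hs$summary$n_probes_with_hit)

  # at min_identity = 1, one planted mismatch kills the hit
  p1 <- probes$seq[1]
  substr(p1, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                substr(p1, 60, 60))[1]
  hs2 <- probe_hits(setNames(p1, "mut"), ref, min_identity = 1.0)
  expect_equal(hs2$summary$n_probes_with_hit, 0)
  expect_error(probe_hits(probes, ref, word_size = 200), "word_size")
})

test_that("hit sets equal the exhaustive sliding-window oracle", {
  target <- rand_seq(20000, seed = 42)
  withr::with_seed(43, {
    starts <- sample(1:(20000 - 119), 100)
    probes <- substring(target, starts, starts + 119)
    # mutate to a spread of identities around the 0.80 threshold
    nmut <- sample(c(0, 5, 15, 22, 26, 40), 100, replace = TRUE)
    probes <- vapply(seq_len(100), function(i) {
      ch <- strsplit(probes[i], "")[[1]]
      if (nmut[i] > 0) {
        pos <- sample(120, nmut[i])
        ch[pos] <- vapply(ch[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      }
      paste(ch, collapse = "")
    }, character(1))
    flip <- sample(c(TRUE, FALSE), 100, replace = TRUE)
    probes <- ifelse(flip, vapply(probes, rc, character(1)), probes)
  })
  names(probes) <- sprintf("p%03d", 1:100)

  hs <- probe_hits(probes, c(t1 = target))
  for (i in seq_len(100)) {
    o <- oracle_hits(probes[i], target)
    got <- hs$hits[hs$hits$probe_id == names(probes)[i], ]
    got <- got[order(got$tstart, got$strand), ]
    if (is.null(o)) {
      expect_equal(nrow(got), 0)
    } else {
      o <- o[order(o$tstart, o$strand), ]
      expect_equal(got$tstart, o$tstart)
      expect_equal(got$strand, c("+", "-")[o$strand + 1])
      expect_equal(got$matches, o$matches)
      expect_equal(got$win_len, o$win_len)
    }
  }
})

test_that("duplicating a target region converts single-hit to multi-hit", {
  base <- rand_seq(8000, seed = 45)
  ref <- structure(list(seq = c(chr1 = base), centromere = c(chr1 = 4000)),
                   class = "ref_genome")
  probes <- design_probes(ref, 40, seed = 46)
  dup_target <- paste0(base, substr(base, 1, 4000))

  before <- probe_hits(probes, c(t = base))
  after <- probe_hits(probes, c(t = dup_target))
  expect_equal(after$summary$n_probes_with_hit,
               before$summary$n_probes_with_hit)
  # a duplicated-copy placement also counts when clipped at the target end,
  # as long as it keeps >= 80% coverage and identity
  in_dup <- probes$start <= 4000 - ceiling(0.8 * 120)
  expect_equal(after$summary$n_hits,
               before$summary$n_hits + sum(in_dup))
})

test_that("hit counts and identity fall monotonically with divergence", {
  ref <- make_reference(c(chr1 = 1e5), 0.5, seed = 47)
  probes <- design_probes(ref, 150, seed = 48)
  res <- purrr::map_dfr(c(0, 0.015, 0.06, 0.12), function(d) {
    tg <- if (d == 0) ref$seq else {
      make_donor(ref, donor_spec("d", "primary", divergence = d,
                                 seed = 49))$seq
    }
    s <- probe_hits(probes, tg)$summary
    tibble::tibble(d = d, with_hit = s$n_probes_with_hit,
                   ident = s$mean_best_identity)
  })
  expect_true(all(diff(res$with_hit) <= 0))
  expect_true(all(diff(res$ident) < 0))
})

test_that("global alignment scores, tie-breaks, and extracts indels", {
  same <- locus_align("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(same$score, 10)
  expect_equal(nrow(same$indels), 0)
  expect_equal(same$percent_identity, 100)

  ins <- locus_align("AAACCC", "AAATTTCCC")
  expect_equal(nrow(ins$indels), 1)
  expect_equal(ins$indels$kind, "insertion")
  expect_equal(ins$indels$ref_pos, 3)
  expect_equal(ins$indels$length, 3L)
  expect_equal(ins$indels$seq, "TTT")
  expect_equal(ins$score, 6 - 6)

  del <- locus_align("AAATTTCCC", "AAACCC")
  expect_equal(del$indels$kind, "deletion")
  expect_equal(del$indels$ref_pos, 3)
  expect_equal(del$indels$seq, "TTT")

  # removing gaps recovers the inputs
  expect_equal(gsub("-", "", ins$alignment[["a"]]), "AAACCC")
  expect_equal(gsub("-", "", ins$alignment[["b"]]), "AAATTTCCC")

  empty <- locus_align("", "ACGT")
  expect_equal(empty$score, 4 * -2)
  expect_equal(empty$indels$kind, "insertion")

  expect_error(locus_align(strrep("A", 2e5), "ACGT"), "100 kb")
})

test_that("alignment scores equal the independent DP oracle", {
  withr::with_seed(51, {
    for (i in 1:50) {
      a <- rand_seq(60)
      b <- rand_seq(60)
      expect_equal(locus_align(a, b)$score, oracle_nw_score(a, b))
    }
  })
})

test_that("constructed 3 bp and 7 bp insertions are found at exact offsets", {
  withr::with_seed(52, {
    ref_seq <- rand_seq(2000)
    # insert 3 bp at offset 700 and 7 bp at offset 1400 (the two-indel
    # donor-haplotype pattern); pick insert ends that differ from the
    # flanking reference bases so the optimal gap placement is unambiguous
    # a homopolymer insert of a base absent from both flanking positions
    # cannot slide or split in an optimal alignment
    pick <- function(...) setdiff(c("A", "C", "G", "T"), c(...))[1]
    ins3 <- strrep(pick(substr(ref_seq, 700, 700),
                        substr(ref_seq, 701, 701)), 3)
    ins7 <- strrep(pick(substr(ref_seq, 1400, 1400),
                        substr(ref_seq, 1401, 1401)), 7)
    q <- paste0(substr(ref_seq, 1, 700), ins3,
                substr(ref_seq, 701, 1400), ins7,
                substr(ref_seq, 1401, 2000))
    al <- locus_align(ref_seq, q)
    expect_equal(nrow(al$indels), 2)
    expect_equal(al$indels$kind, c("insertion", "insertion"))
    expect_equal(al$indels$ref_pos, c(700, 1400))
    expect_equal(al$indels$length, c(3L, 7L))
  })
})

test_that("nearest-reference assignment votes by identity with tie handling", {
  withr::with_seed(53, {
    c1 <- rand_seq(400)
    c2 <- rand_seq(400)
    res <- assign_nearest_reference(c1, c(one = c1, two = c2))
    expect_equal(res$verdict, "one")
    expect_equal(res$table$percent_identity[res$table$candidate == "one"], 100)

    tie <- assign_nearest_reference(c1, c(one = c1, dup = c1))
    expect_equal(tie$verdict, "AMBIGUOUS")
    expect_error(assign_nearest_reference(c1, c(only = c1)), ">= 2")

    # a light mutant of candidate 2 goes to candidate 2 in >= 19/20 seeds
    wins <- 0
    for (s in 1:20) {
      mut <- mutate_bases_for_test(c2, 0.01)
      r <- assign_nearest_reference(mut, c(one = c1, two = c2))
      wins <- wins + (r$verdict == "two")
    }
    expect_gte(wins, 19)
  })
})
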