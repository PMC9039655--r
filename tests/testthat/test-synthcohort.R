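# Cohort generator: reference, donors, mosaics, probes, genotypes.

test_that("reference generation is seeded, bounded, and compositionally uniform", {
  ref <- make_reference(c(chr1 = 1e5), 0.48, seed = 42)
  expect_equal(unname(ref$centromere), floor(1e5 * 0.48))
  expect_equal(nchar(ref$seq[[1]]), 1e5)

  ref2 <- make_reference(c(chr1 = 1e5), 0.48, seed = 42)
  expect_identical(ref$seq, ref2$seq)

  # base composition of a 1 Mb chromosome within 3 binomial SD of 25%
  big <- make_reference(c(chr1 = 1e6), 0.5, seed = 7)
  counts <- table(strsplit(big$seq[[1]], "")[[1]])
  sd3 <- 3 * sqrt(0.25 * 0.75 / 1e6)
  expect_true(all(abs(counts / 1e6 - 0.25) < sd3))

  expect_error(make_reference(c(chr1 = -5), 0.5), "positive")
  expect_error(make_reference(c(chr1 = 5000), 0.5), "10 kb")
  expect_error(make_reference(c(chr1 = 1e5), 1.2), "inside")
})

test_that("donor divergence is calibrated and indel-free donors keep length", {
  ref <- make_reference(c(chr1 = 1e6), 0.5, seed = 11)

  same <- make_donor(ref, donor_spec("d0", "primary", divergence = 0, seed = 1))
  expect_identical(same$seq, ref$seq)
  expect_equal(nchar(same$seq[[1]]), nchar(ref$seq[[1]]))

  div <- make_donor(ref, donor_spec("d12", "tertiary", divergence = 0.12,
                                    seed = 2))
  mm <- sum(charToRaw(div$seq[[1]]) != charToRaw(ref$seq[[1]]))
  sd3 <- 3 * sqrt(0.12 * 0.88 / 1e6)
  expect_lt(abs(mm / 1e6 - 0.12), sd3)
  expect_equal(nchar(div$seq[[1]]), 1e6)  # indel_rate = 0

  expect_error(donor_spec("bad", "primary", divergence = 1.5), "\\[0, 1\\]")
  expect_error(donor_spec("bad", "primary", indel_rate = -1), ">= 0")
})

test_that("donors with indels record a usable coordinate lift", {
  ref <- make_reference(c(chr1 = 2e4), 0.5, seed = 3)
  d <- make_donor(ref, donor_spec("di", "secondary", divergence = 0,
                                  indel_rate = 5e-4, seed = 4))
  expect_gt(nrow(d$edits$chr1), 0)
  expect_equal(nchar(d$seq[[1]]),
               nchar(ref$seq[[1]]) + sum(d$edits$chr1$delta))
  # lift of the chromosome end equals the donor length
  expect_equal(lift_pos <- introdrop:::donor_lift(d, "chr1", 2e4),
               nchar(d$seq[[1]]))
})

test_that("mosaics splice donors over segments and leave the rest untouched", {
  ref <- tiny_ref()
  dT <- make_donor(ref, donor_spec("dT", "tertiary", seed = 5))
  donors <- list(dT = dT)

  plain <- make_accession(ref, donors, NULL, id = "plain")
  expect_identical(plain$seq, ref$seq)

  segs <- tibble::tibble(chrom = "chrA", start = 10000, end = 25000,
                         donor = "dT")
  mos <- make_accession(ref, donors, segs, id = "m1")
  expect_identical(substr(mos$seq[["chrA"]], 1, 10000),
                   substr(ref$seq[["chrA"]], 1, 10000))
  expect_identical(substr(mos$seq[["chrA"]], 25001, 5e4),
                   substr(ref$seq[["chrA"]], 25001, 5e4))
  expect_identical(substr(mos$seq[["chrA"]], 10001, 25000),
                   substr(dT$seq[["chrA"]], 10001, 25000))
  expect_identical(mos$seq[["chrB"]], ref$seq[["chrB"]])

  overl <- tibble::tibble(chrom = "chrA", start = c(0, 5000),
                          end = c(10000, 15000), donor = "dT")
  expect_error(make_accession(ref, donors, overl), "overlapping")
  expect_error(
    make_accession(ref, donors,
                   tibble::tibble(chrom = "chrA", start = 0, end = 10,
                                  donor = "nope")),
    "unresolvable")
})

test_that("deletion segments are excised with a consistent coordinate lift", {
  ref <- tiny_ref()
  segs <- tibble::tibble(chrom = "chrA", start = 20000, end = 30000,
                         donor = "DELETION")
  mos <- make_accession(ref, list(), segs, id = "del1")
  expect_equal(nchar(mos$seq[["chrA"]]), 5e4 - 10000)
  expect_identical(substr(mos$seq[["chrA"]], 20001, 40000),
                   substr(ref$seq[["chrA"]], 30001, 50000))
  # window over the deletion comes back empty
  expect_identical(introdrop:::mosaic_window(mos, "chrA", 22000, 25000), "")
  # window straddling the deletion stitches flanks together
  win <- introdrop:::mosaic_window(mos, "chrA", 19990, 30010)
  expect_identical(win, paste0(substr(ref$seq[["chrA"]], 19991, 20000),
                               substr(ref$seq[["chrA"]], 30001, 30010)))
})

test_that("probe design honours count, bounds, and the arm gradient", {
  ref <- make_reference(c(chr1 = 2e5), 0.5, seed = 9)
  pr <- design_probes(ref, 500, probe_len = 120, gradient_slope = 0, seed = 42)
  expect_equal(nrow(pr), 500)
  expect_true(all(pr$end - pr$start == 120))
  expect_true(all(pr$start >= 0 & pr$end <= 2e5))
  expect_identical(pr$seq, substring(ref$seq[pr$chrom], pr$start + 1, pr$end))

  # flat slope: uniform positions (chi-square GOF over 10 equal bins)
  obs <- table(cut(pr$start, breaks = seq(0, 2e5, length.out = 11),
                   include.lowest = TRUE))
  expect_gt(chisq.test(obs)$p.value, 0.01)

  # positive slope: distal deciles denser than centromere-flanking deciles
  distal <- numeric(20); proximal <- numeric(20)
  for (s in 1:20) {
    p2 <- design_probes(ref, 500, gradient_slope = 3, seed = s)
    dec <- cut(p2$start, breaks = seq(0, 2e5, length.out = 11), labels = FALSE)
    distal[s] <- sum(dec %in% c(1, 10))
    proximal[s] <- sum(dec %in% c(5, 6))
  }
  expect_gt(mean(distal), mean(proximal))

  expect_error(design_probes(ref, 500, gradient_slope = -2), "-1")
  expect_error(design_probes(ref, 0), ">= 1")
})

test_that("genotype simulation reflects the mosaic truth", {
  ref <- tiny_ref()
  dT <- make_donor(ref, donor_spec("dT", "tertiary", seed = 5))
  donors <- list(dT = dT)
  plain <- make_accession(ref, donors, NULL, id = "plain")
  seg_mos <- make_accession(
    ref, donors,
    tibble::tibble(chrom = "chrA", start = 0, end = 25000, donor = "dT"),
    id = "carrier")
  del_mos <- make_accession(
    ref, donors,
    tibble::tibble(chrom = "chrB", start = 5000, end = 20000,
                   donor = "DELETION"),
    id = "deleted")

  gm <- simulate_genotypes(ref, list(plain, seg_mos, del_mos), 400,
                           err_rate = 0, missing_rate = 0, seed = 77)
  expect_true(all(gm$plain == "HOM_REF"))
  expect_true(all(gm$reference == "HOM_REF"))
  in_seg <- gm$chrom == "chrA" & gm$pos < 25000
  expect_true(all(gm$carrier[in_seg] %in% c("HOM_ALT", "HET")))
  expect_true(all(gm$carrier[!in_seg] == "HOM_REF"))
  in_del <- gm$chrom == "chrB" & gm$pos >= 5000 & gm$pos < 20000
  expect_true(all(gm$deleted[in_del] == "MISSING"))
  # positions strictly increasing within chromosomes
  for (ch in unique(gm$chrom)) {
    expect_true(all(diff(gm$pos[gm$chrom == ch]) > 0))
  }
  expect_error(simulate_genotypes(ref, list(plain), 10, err_rate = 2), "\\[0, 1\\]")
})

test_that("generators are pure functions of their seed", {
  ref <- tiny_ref(seed = 13)
  for (fn in list(
    function(s) make_donor(ref, donor_spec("d", "secondary", seed = s))$seq,
    function(s) design_probes(ref, 100, seed = s),
    function(s) simulate_genotypes(ref, list(), 50, seed = s))) {
    expect_identical(fn(5), fn(5))
    expect_false(identical(fn(5), fn(6)))
  }
})
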