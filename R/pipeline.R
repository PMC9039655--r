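# End-to-end orchestration: synthetic cohort -> capture read simulation ->
# mapping -> coverage drops -> genotype clustering -> probe efficacy ->
# attribution, with a read-accounting table and optional on-disk artifacts.

#' Demo cohort configuration (1:100 scale)
#'
#' The default study conditions: three chromosomes at 1:100 of wheat scale
#' (6/7/5 Mb; 50 kb bins mirror 5 Mb bins at full scale), six accessions
#' carrying the canonical alien-segment geometries -- two carriers of a
#' whole-short-arm tertiary translocation (2.4 Mb, the 240 Mb arm-swap
#' analogue), one secondary-genepool segment (0.85 Mb ~ 85 Mb), one
#' primary-genepool segment (0.3 Mb ~ 25-30 Mb), and a deletion paired
#' with an equal-span tertiary segment -- plus gradient-placed probes at
#' ~112 probes/Mb and a step capture model with 10% tolerance.
#'
#' @param seed Master RNG seed; per-stage seeds derive from it.
#' @export
demo_config <- function(seed = 42) {
  list(
    seed = seed,
    chrom_lengths = c(chr1 = 6e6, chr2 = 7e6, chr3 = 5e6),
    centromere_fracs = c(0.40, 0.45, 0.45),
    donors = list(
      donorP = list(genepool = "primary"),
      donorS = list(genepool = "secondary"),
      donorT = list(genepool = "tertiary")),
    accessions = list(
      acc1 = tibble(chrom = "chr1", start = 0, end = 2.4e6, donor = "donorT"),
      acc2 = tibble(chrom = "chr1", start = 0, end = 2.4e6, donor = "donorT"),
      acc3 = tibble(chrom = "chr2", start = 4.0e6, end = 4.85e6, donor = "donorS"),
      acc4 = tibble(chrom = "chr3", start = 3.0e6, end = 4.0e6, donor = "DELETION"),
      acc5 = tibble(chrom = "chr3", start = 3.0e6, end = 4.0e6, donor = "donorT"),
      acc6 = tibble(chrom = "chr2", start = 1.0e6, end = 1.3e6, donor = "donorP")),
    n_probes = 2016, probe_len = 120, gradient_slope = 3,
    capture = list(tolerance = 0.10, mode = "step", steepness = 80),
    mean_depth = 20, frag_mean = 300, frag_sd = 30, read_len = 150,
    err_rate = 0.001,
    k = 15, max_mismatch_frac = 0.06, unique_margin = 1,
    bin_width = 5e4, alpha = 0.5, min_bins = 2,
    n_markers = 1500, geno_err_rate = 0.01, geno_missing_rate = 0.02,
    attribution = list(accession = "acc3", chrom = "chr2", donor = "donorS",
                       max_reads = 1500, min_identity = 0.80,
                       ambiguity_margin = 0.02),
    efficacy_chrom = "chr1"
  )
}

stage_seed <- function(config, offset) as.integer(config$seed + offset)

#' Run the full pipeline from a configuration
#'
#' Executes cohort simulation, capture read simulation, mapping, coverage
#' binning and cohort-relative drop calling, truth annotation, genotype
#' clustering over the widest called drop, probe-efficacy scoring against
#' the donor panel, donor attribution of unmapped vs mapped reads, and a
#' locus-level nearest-reference diagnosis of the primary-genepool segment.
#' Fully reproducible from `(config, seed)`.
#'
#' @param config A [demo_config()]-style list.
#' @param out_dir Optional directory for on-disk artifacts (FASTA, FASTQ,
#'   BED, TSV, Newick) plus a manifest.
#' @param quiet Suppress progress messages.
#' @return An `introdrop_run` list with every stage's results.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)

  say("synthcohort: reference + donors + mosaics")
  reference <- make_reference(config$chrom_lengths, config$centromere_fracs,
                              seed = stage_seed(config, 0))
  donors <- purrr::imap(config$donors, function(d, nm) {
    make_donor(reference, donor_spec(
      nm, d$genepool, divergence = d$divergence,
      indel_rate = d$indel_rate %||% 0,
      seed = stage_seed(config, 1 + match(nm, names(config$donors)))))
  })
  mosaics <- purrr::imap(config$accessions, function(segs, nm) {
    make_accession(reference, donors, segs, id = nm)
  })
  truth <- bind_rows(purrr::imap(mosaics, function(m, nm) {
    if (nrow(m$truth) == 0) return(NULL)
    mutate(m$truth, label = paste0(nm, ":", .data$donor), accession = nm)
  }))

  say("synthcohort: probes + genotypes")
  probes <- design_probes(reference, config$n_probes, config$probe_len,
                          config$gradient_slope, seed = stage_seed(config, 10))
  genotypes <- simulate_genotypes(reference, mosaics, config$n_markers,
                                  err_rate = config$geno_err_rate,
                                  missing_rate = config$geno_missing_rate,
                                  seed = stage_seed(config, 20))

  say("capture_readsim: paired reads per accession")
  model <- capture_model(config$capture$tolerance, config$capture$mode,
                         config$capture$steepness)
  reads <- purrr::imap(mosaics, function(m, nm) {
    simulate_reads(m, probes, model, config$mean_depth, config$frag_mean,
                   config$frag_sd, config$read_len, config$err_rate,
                   seed = stage_seed(config, 100 + match(nm, names(mosaics))))
  })

  say("mapper: seed-and-extend unique mapping")
  index <- build_index(reference, k = config$k)
  mappings <- purrr::map(reads, function(r) {
    map_reads(r, index, config$max_mismatch_frac, config$unique_margin,
              config$frag_mean, config$frag_sd)
  })
  stats <- read_stats(mappings)

  say("coverage_drops: binned depth, normalization, drop calls")
  coverage <- bind_rows(purrr::map(mappings, function(m) {
    coverage_profile(m, nchar(reference$seq), config$bin_width)
  }))
  normalized <- normalize_profiles(coverage)
  drops <- call_drops(normalized, config$alpha, config$min_bins)
  annotated <- annotate_drops(drops, truth)

  say("genotype_cluster: similarity + UPGMA over the widest drop")
  cluster <- cluster_widest_drop(drops, genotypes)

  say("probe_efficacy: probe set vs donor panel")
  eff_chrom <- config$efficacy_chrom
  eff_probes <- probes[probes$chrom == eff_chrom, ]
  panel_targets <- c(list(reference = setNames(reference$seq[eff_chrom],
                                               eff_chrom)),
                     purrr::map(donors, function(d) {
                       setNames(d$seq[eff_chrom], eff_chrom)
                     }))
  efficacy <- bind_rows(purrr::imap(panel_targets, function(t, nm) {
    hs <- probe_hits(eff_probes, t)
    mutate(hs$summary, target = nm,
           divergence = if (nm == "reference") 0 else donors[[nm]]$divergence,
           .before = 1)
  }))

  say("attribution: unmapped vs mapped reads against the panel")
  attribution <- attribute_carrier_reads(config, reads, mappings, reference,
                                         donors)

  locus <- primary_locus_diagnosis(config, reference, donors, mosaics)

  run <- structure(
    list(config = config, reference = reference, donors = donors,
         mosaics = mosaics, probes = probes, genotypes = genotypes,
         truth = truth, reads = reads, index = index, mappings = mappings,
         read_stats = stats, coverage = coverage, normalized = normalized,
         drops = drops, annotated = annotated, cluster = cluster,
         efficacy = efficacy, attribution = attribution, locus = locus),
    class = "introdrop_run")
  if (!is.null(out_dir)) write_run(run, out_dir, quiet = quiet)
  run
}

# Cluster accessions over the markers spanning the widest called drop, and
# contrast in-drop vs rest-of-chromosome similarity to the reference for
# the accessions that display the drop.
cluster_widest_drop <- function(drops, genotypes) {
  if (nrow(drops) == 0) return(NULL)
  spans <- drops$end - drops$start
  top <- drops[which.max(spans), ]
  interval <- list(chrom = top$chrom, start = top$start, end = top$end)
  carriers <- unique(drops$accession[
    drops$chrom == top$chrom & drops$start < top$end & drops$end > top$start])
  in_drop <- markers_in_interval(genotypes, top$chrom, top$start, top$end)
  rest <- setdiff(genotypes$marker_id[genotypes$chrom == top$chrom], in_drop)
  accs <- setdiff(acc_columns(genotypes), "reference")
  dmat <- genotype_distance(genotypes, accessions = accs, markers = in_drop)
  tree <- upgma_tree(dmat)
  groups <- tree_groups(tree, k = 2)
  sim <- bind_rows(
    genotype_similarity(genotypes, accessions = carriers, markers = in_drop,
                        label = "drop_interval"),
    genotype_similarity(genotypes, accessions = carriers, markers = rest,
                        label = "rest_of_chromosome"))
  list(interval = interval, carriers = carriers, n_markers = length(in_drop),
       distance = dmat, tree = tree, groups = groups, similarity = sim)
}

# Classify a sample of unmapped and of region-mapped reads of the carrier
# accession against a reference-plus-donor panel.
attribute_carrier_reads <- function(config, reads, mappings, reference,
                                    donors) {
  at <- config$attribution
  acc <- at$accession
  m <- mappings[[acc]]
  r <- reads[[acc]]
  unmapped <- mate_sequences(m, r, "unmapped")
  mapped_ms <- m$mate_status[m$mate_status$status == "unique" &
                               m$mate_status$chrom == at$chrom, ]
  i <- match(mapped_ms$pair_id, r$pair_id)
  mapped <- setNames(ifelse(mapped_ms$mate == 1, r$mate1[i], r$mate2[i]),
                     mapped_ms$read_id)
  take <- function(x, n, seed) {
    if (length(x) <= n) return(x)
    with_seed(seed, x[sort(sample.int(length(x), n))])
  }
  unmapped <- take(unmapped, at$max_reads, stage_seed(config, 200))
  mapped <- take(mapped, at$max_reads, stage_seed(config, 201))
  panel <- list(reference = setNames(reference$seq[at$chrom], at$chrom))
  panel[[at$donor]] <- setNames(donors[[at$donor]]$seq[at$chrom], at$chrom)
  classify <- function(x) {
    if (length(x) == 0) return(NULL)
    classify_reads(x, panel, at$min_identity, at$ambiguity_margin)
  }
  un <- classify(unmapped)
  ma <- classify(mapped)
  list(unmapped = un, mapped = ma,
       donor_fraction_unmapped = if (is.null(un)) NA_real_ else
         donor_fraction(un, at$donor),
       donor_fraction_mapped = if (is.null(ma)) NA_real_ else
         donor_fraction(ma, at$donor))
}

# Nearest-reference diagnosis of a 1 kb window at the centre of the first
# primary-genepool truth segment (the captured-but-similar locus case).
primary_locus_diagnosis <- function(config, reference, donors, mosaics) {
  seg <- NULL; acc <- NULL
  for (nm in names(mosaics)) {
    tr <- mosaics[[nm]]$truth
    prim <- tr[tr$donor != DELETION &
                 vapply(tr$donor, function(d) {
                   !is.null(donors[[d]]) && donors[[d]]$genepool == "primary"
                 }, logical(1)), ]
    if (nrow(prim) > 0) { seg <- prim[1, ]; acc <- nm; break }
  }
  if (is.null(seg)) return(NULL)
  mid <- floor((seg$start + seg$end) / 2)
  s <- mid - 500; e <- mid + 500
  query <- mosaic_window(mosaics[[acc]], seg$chrom, s, e)
  d <- donors[[seg$donor]]
  cands <- c(reference = substr(reference$seq[[seg$chrom]], s + 1, e),
             setNames(substr(d$seq[[seg$chrom]],
                             donor_lift(d, seg$chrom, s) + 1,
                             donor_lift(d, seg$chrom, e)), seg$donor))
  res <- assign_nearest_reference(query, cands)
  list(accession = acc, segment = seg, window = c(start = s, end = e),
       result = res)
}

#' @export
print.introdrop_run <- function(x, ...) {
  cat("<introdrop_run> ", length(x$mosaics), " accessions, ",
      nrow(x$probes), " probes, ", nrow(x$drops), " drop call(s)\n", sep = "")
  invisible(x)
}

#' Write pipeline artifacts to a directory with a manifest
#'
#' @param run An `introdrop_run` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param fastq Also write per-accession paired FASTQ (large).
#' @param quiet Suppress messages.
#' @export
write_run <- function(run, out_dir, fastq = TRUE, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  written <- character()
  add <- function(path) written <<- c(written, path)

  add(write_genome_fasta(run$reference, p("reference.fasta")))
  for (nm in names(run$donors)) {
    add(write_genome_fasta(run$donors[[nm]], p(paste0("donor_", nm, ".fasta"))))
  }
  for (nm in names(run$mosaics)) {
    add(write_genome_fasta(run$mosaics[[nm]], p(paste0("mosaic_", nm, ".fasta"))))
  }
  add(write_probe_fasta(run$probes, p("probes.fasta")))
  add(write_bed(run$probes, p("probes.bed"), name = "probe_id"))
  add(write_bed(run$truth, p("truth.bed"), name = "label"))
  if (fastq) {
    for (nm in names(run$reads)) {
      write_reads_fastq(run$reads[[nm]], p(paste0("reads_", nm)))
      add(p(paste0("reads_", nm, "_1.fastq")))
      add(p(paste0("reads_", nm, "_2.fastq")))
    }
  }
  for (nm in names(run$mappings)) {
    readr::write_tsv(run$mappings[[nm]]$alignments,
                     p(paste0("alignments_", nm, ".tsv")))
    add(p(paste0("alignments_", nm, ".tsv")))
    un <- mate_sequences(run$mappings[[nm]], run$reads[[nm]], "unmapped")
    if (length(un) > 0) {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(un),
                                  p(paste0("unmapped_", nm, ".fasta")))
      add(p(paste0("unmapped_", nm, ".fasta")))
    }
  }
  readr::write_tsv(run$read_stats, p("read_stats.tsv")); add(p("read_stats.tsv"))
  readr::write_tsv(run$normalized, p("coverage_binned.tsv"))
  add(p("coverage_binned.tsv"))
  add(write_bed(mutate(ungroup(run$drops),
                       label = paste0(.data$accession, "_drop")),
                p("drops.bed"), name = "label"))
  readr::write_tsv(run$annotated, p("drop_annotations.tsv"))
  add(p("drop_annotations.tsv"))
  add(write_genotypes(run$genotypes, p("genotypes.tsv")))
  if (!is.null(run$cluster)) {
    add(write_newick(run$cluster$tree, p("dendrogram.nwk")))
    readr::write_tsv(run$cluster$similarity, p("similarity.tsv"))
    add(p("similarity.tsv"))
  }
  readr::write_tsv(run$efficacy, p("probe_efficacy.tsv"))
  add(p("probe_efficacy.tsv"))
  for (side in c("unmapped", "mapped")) {
    at <- run$attribution[[side]]
    if (!is.null(at)) {
      readr::write_tsv(at$summary, p(paste0("attribution_", side, ".tsv")))
      add(p(paste0("attribution_", side, ".tsv")))
    }
  }
  manifest <- tibble(file = basename(written),
                     bytes = file.size(written))
  readr::write_tsv(manifest, p("manifest.tsv"))
  if (!quiet) message("wrote ", length(written), " artifacts to ", out_dir)
  invisible(manifest)
}
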