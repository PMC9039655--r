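# Synthetic cohort generator: reference genome, diverged donor genomes,
# mosaic accession genomes, gradient-placed capture probes, and a
# truth-consistent genotype matrix. This is the statistical stand-in for a
# sequenced panel of hexaploid wheat accessions: the defaults emulate a
# 1:100 scale-down of wheat chromosomes, so a whole-arm alien translocation
# of c. 240 Mb becomes a 2.4 Mb segment on a 6 Mb chromosome.

DELETION <- "DELETION"

#' Divergence defaults per genepool tier
#'
#' Expected substitution divergence from the recipient genome for donors of
#' the primary (progenitor), secondary, and tertiary (distant relative,
#' e.g. rye) genepools. The tiers bracket the 10--20% capture tolerance
#' quoted by probe vendors: primary donors sit well inside it, tertiary
#' donors outside it.
#' @export
tier_divergence <- c(primary = 0.015, secondary = 0.06, tertiary = 0.12)

#' Generate a reference genome
#'
#' Chromosome sequences are i.i.d. uniform over A/C/G/T; each chromosome
#' carries a centromere position used by the probe-density gradient.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (>= 10 kb).
#' @param centromere_fracs Centromere position as a fraction of chromosome
#'   length, strictly inside (0, 1); recycled.
#' @param seed Integer RNG seed.
#' @return A `ref_genome` object: list with `seq` (named character vector)
#'   and `centromere` (named numeric vector of 0-based offsets).
#' @export
make_reference <- function(chrom_lengths, centromere_fracs = 0.45, seed = 1) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (any(chrom_lengths < 1e4)) stop("chromosome lengths must be >= 10 kb")
  centromere_fracs <- rep_len(centromere_fracs, length(chrom_lengths))
  if (any(centromere_fracs <= 0 | centromere_fracs >= 1)) {
    stop("centromere_fracs must lie strictly inside (0, 1)")
  }
  nm <- names(chrom_lengths)
  if (is.null(nm)) nm <- paste0("chr", seq_along(chrom_lengths))
  if (anyDuplicated(nm)) stop("chromosome names must be unique")
  seqs <- with_seed(seed, vapply(chrom_lengths, random_dna, character(1)))
  names(seqs) <- nm
  structure(
    list(seq = seqs,
         centromere = setNames(floor(chrom_lengths * centromere_fracs), nm)),
    class = "ref_genome"
  )
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome> ", length(x$seq), " chromosome(s), ",
      format(sum(nchar(x$seq)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

chrom_lengths <- function(genome) {
  if (inherits(genome, c("ref_genome", "donor_genome"))) nchar(genome$seq)
  else if (inherits(genome, "mosaic_genome")) nchar(genome$seq)
  else nchar(genome)
}

#' Specify a donor genome
#'
#' @param name Donor name.
#' @param genepool One of `"primary"`, `"secondary"`, `"tertiary"`.
#' @param divergence Expected substitution fraction per base; defaults to the
#'   tier value in [tier_divergence].
#' @param indel_rate Expected indel events per base (geometric lengths,
#'   mean 2 bp).
#' @param seed Integer RNG seed.
#' @export
donor_spec <- function(name, genepool = c("primary", "secondary", "tertiary"),
                       divergence = NULL, indel_rate = 0, seed = 1) {
  genepool <- match.arg(genepool)
  if (is.null(divergence)) divergence <- unname(tier_divergence[genepool])
  if (divergence < 0 || divergence > 1) stop("divergence must lie in [0, 1]")
  if (indel_rate < 0) stop("indel_rate must be >= 0")
  list(name = name, genepool = genepool, divergence = divergence,
       indel_rate = indel_rate, seed = seed)
}

#' Derive a diverged donor genome from the reference
#'
#' Each base is substituted independently with probability `divergence` (to a
#' uniformly chosen different base); indels are inserted as geometric-length
#' events at `indel_rate` per base. Edit tables are kept so reference
#' coordinates can be lifted into the donor frame (perfect synteny is
#' assumed: a donor's homologous region sits at the same pre-indel
#' coordinates as in the reference).
#'
#' @param reference A [make_reference()] genome.
#' @param spec A [donor_spec()].
#' @return A `donor_genome` object.
#' @export
make_donor <- function(reference, spec) {
  stopifnot(inherits(reference, "ref_genome"))
  with_seed(spec$seed, {
    seqs <- mutate_bases(reference$seq, spec$divergence)
    edits <- vector("list", length(seqs))
    names(edits) <- names(seqs)
    for (i in seq_along(seqs)) {
      res <- apply_indels(seqs[i], spec$indel_rate)
      seqs[i] <- res$seq
      edits[[i]] <- res$edits
    }
    structure(
      list(name = spec$name, genepool = spec$genepool,
           divergence = spec$divergence, indel_rate = spec$indel_rate,
           seq = seqs, edits = edits),
      class = "donor_genome"
    )
  })
}

#' @export
print.donor_genome <- function(x, ...) {
  cat("<donor_genome> ", x$name, " (", x$genepool, ", d = ", x$divergence,
      ")\n", sep = "")
  invisible(x)
}

# Lift a 0-based reference offset on `chrom` into the donor frame.
donor_lift <- function(donor, chrom, x) lift_pos(x, donor$edits[[chrom]])

#' Build a mosaic accession genome
#'
#' Splices donor sequence over each introgression segment (coordinates in
#' the reference frame; the donor's homologous region is taken at the same
#' coordinates, lifted through the donor's indel edits) and removes
#' `"DELETION"` segments, recording the truth annotation and the coordinate
#' correspondence between mosaic and reference frames.
#'
#' @param reference A [make_reference()] genome.
#' @param donors Named list of [make_donor()] genomes.
#' @param segments Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open, reference frame) and `donor` (a donor name or `"DELETION"`).
#' @param id Accession identifier.
#' @return A `mosaic_genome` object.
#' @export
make_accession <- function(reference, donors = list(), segments = NULL,
                           id = "accession") {
  stopifnot(inherits(reference, "ref_genome"))
  if (is.null(segments) || nrow(segments) == 0) {
    segments <- tibble(chrom = character(), start = numeric(),
                       end = numeric(), donor = character())
  }
  if (length(donors) > 0 && is.null(names(donors))) {
    names(donors) <- vapply(donors, function(d) d$name, character(1))
  }
  lens <- nchar(reference$seq)
  bad <- segments$start < 0 | segments$end > lens[segments$chrom] |
    segments$start >= segments$end
  if (any(bad)) stop("segment coordinates out of bounds or empty")
  unresolved <- setdiff(segments$donor, c(names(donors), DELETION))
  if (length(unresolved) > 0) {
    stop("unresolvable donor name(s): ", paste(unresolved, collapse = ", "))
  }
  segments <- arrange(segments, .data$chrom, .data$start)
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping segments on ", ch)
    }
  }

  pieces <- list()
  seqs <- character(length(reference$seq))
  names(seqs) <- names(reference$seq)
  for (ch in names(reference$seq)) {
    segs <- segments[segments$chrom == ch, ]
    bounds <- c(0, as.vector(rbind(segs$start, segs$end)), lens[[ch]])
    src <- rep("reference", length(bounds) - 1)
    if (nrow(segs) > 0) src[seq(2, by = 2, length.out = nrow(segs))] <- segs$donor
    keep <- bounds[-length(bounds)] < bounds[-1]
    pc <- tibble(chrom = ch, ref_start = bounds[-length(bounds)][keep],
                 ref_end = bounds[-1][keep], source = src[keep])
    pseq <- character(nrow(pc))
    for (i in seq_len(nrow(pc))) {
      s <- pc$ref_start[i]; e <- pc$ref_end[i]; so <- pc$source[i]
      pseq[i] <- if (so == "reference") {
        substr(reference$seq[[ch]], s + 1, e)
      } else if (so == DELETION) {
        ""
      } else {
        d <- donors[[so]]
        substr(d$seq[[ch]], donor_lift(d, ch, s) + 1, donor_lift(d, ch, e))
      }
    }
    mlen <- nchar(pseq)
    pc$mosaic_start <- cumsum(c(0, mlen[-length(mlen)]))
    pc$mosaic_end <- pc$mosaic_start + mlen
    seqs[[ch]] <- paste(pseq, collapse = "")
    pieces[[ch]] <- pc
  }
  structure(
    list(id = id, seq = seqs, truth = segments,
         pieces = bind_rows(pieces), donors = donors),
    class = "mosaic_genome"
  )
}

#' @export
print.mosaic_genome <- function(x, ...) {
  cat("<mosaic_genome> ", x$id, ": ", nrow(x$truth), " truth segment(s)\n",
      sep = "")
  invisible(x)
}

# Homologous mosaic sequence for a reference-frame window [start, end) on
# `chrom`. Deleted stretches contribute nothing, so the returned string is
# shorter than the window where deletions intrude (empty if fully deleted).
mosaic_window <- function(mosaic, chrom, start, end) {
  pc <- mosaic$pieces[mosaic$pieces$chrom == chrom, ]
  hit <- pc$ref_end > start & pc$ref_start < end
  out <- character()
  for (i in which(hit)) {
    s <- max(start, pc$ref_start[i]); e <- min(end, pc$ref_end[i])
    so <- pc$source[i]
    if (so == DELETION) next
    if (so == "reference") {
      ms <- pc$mosaic_start[i] + (s - pc$ref_start[i])
      me <- ms + (e - s)
    } else {
      d <- mosaic$donors[[so]]
      ms <- pc$mosaic_start[i] +
        (donor_lift(d, chrom, s) - donor_lift(d, chrom, pc$ref_start[i]))
      me <- pc$mosaic_start[i] +
        (donor_lift(d, chrom, e) - donor_lift(d, chrom, pc$ref_start[i]))
    }
    out <- c(out, substr(mosaic$seq[[chrom]], ms + 1, me))
  }
  paste(out, collapse = "")
}

# Mosaic-frame coordinate of a reference-frame offset (NA inside deletions).
mosaic_coord <- function(mosaic, chrom, pos) {
  pc <- mosaic$pieces[mosaic$pieces$chrom == chrom, ]
  i <- which(pc$ref_start <= pos & pos < pc$ref_end)[1]
  if (is.na(i)) return(NA_real_)
  so <- pc$source[i]
  if (so == DELETION) return(NA_real_)
  if (so == "reference") {
    pc$mosaic_start[i] + (pos - pc$ref_start[i])
  } else {
    d <- mosaic$donors[[so]]
    pc$mosaic_start[i] +
      (donor_lift(d, chrom, pos) - donor_lift(d, chrom, pc$ref_start[i]))
  }
}

# Source label ("reference", donor name, or DELETION) at a mosaic-frame
# coordinate.
mosaic_source_at <- function(mosaic, chrom, mosaic_pos) {
  pc <- mosaic$pieces[mosaic$pieces$chrom == chrom, ]
  i <- findInterval(mosaic_pos, pc$mosaic_start)
  ifelse(i >= 1 & mosaic_pos < pc$mosaic_end[pmax(i, 1)],
         pc$source[pmax(i, 1)], NA_character_)
}

#' Design capture probes with a telomere-to-centromere density gradient
#'
#' Probe start positions are sampled with density proportional to
#' `1 + gradient_slope * u`, where `u` is the normalized distance from the
#' centromere along the arm (0 at the centromere, 1 at the telomere) --
#' emulating the gene-density gradient that shapes real capture designs.
#' Probes are allocated to chromosomes proportionally to length and their
#' sequences copied from the reference.
#'
#' @param reference A [make_reference()] genome.
#' @param n_probes Total number of probes (>= 1).
#' @param probe_len Probe length in bp (constant; default 120).
#' @param gradient_slope Density slope along the arm; must be > -1.
#' @param seed Integer RNG seed.
#' @return A `probe_set` tibble: `probe_id`, `chrom`, `start`, `end`, `seq`.
#' @export
design_probes <- function(reference, n_probes, probe_len = 120,
                          gradient_slope = 0, seed = 1) {
  stopifnot(inherits(reference, "ref_genome"))
  if (n_probes < 1) stop("n_probes must be >= 1")
  if (gradient_slope < -1) stop("gradient_slope must be >= -1")
  lens <- nchar(reference$seq)
  if (probe_len > min(lens)) stop("probe_len exceeds a chromosome length")
  with_seed(seed, {
    chroms <- sample(names(lens), n_probes, replace = TRUE, prob = lens)
    cen <- reference$centromere[chroms]
    len <- lens[chroms]
    left_arm <- runif(n_probes) < cen / len
    arm_len <- ifelse(left_arm, cen, len - cen)
    u <- gradient_quantile(runif(n_probes), gradient_slope)
    pos <- ifelse(left_arm, cen - u * cen, cen + u * (len - cen))
    start <- pmin(pmax(floor(pos), 0), len - probe_len)
    out <- tibble(chrom = chroms, start = start, end = start + probe_len)
    out <- arrange(out, match(.data$chrom, names(lens)), .data$start)
    out$probe_id <- sprintf("probe_%05d", seq_len(n_probes))
    out$seq <- substring(reference$seq[out$chrom], out$start + 1, out$end)
    class(out) <- c("probe_set", class(out))
    out[, c("probe_id", "chrom", "start", "end", "seq")]
  })
}

# Inverse CDF of the arm-position density f(u) = (1 + s*u) / (1 + s/2).
gradient_quantile <- function(p, s) {
  a <- s / 2
  if (abs(a) < 1e-12) return(p)
  (-1 + sqrt(1 + 4 * a * p * (1 + a))) / (2 * a)
}

#' Simulate a biallelic marker genotype matrix for a cohort of mosaics
#'
#' Marker positions are sampled uniformly. For each accession, a marker call
#' is `HOM_REF` over reference-derived sequence; inside an introgressed
#' segment it is `HOM_ALT` with probability `p_alt` (else `HET`); inside a
#' deleted segment it is `MISSING` (no target to hybridize to). Calls are
#' then flipped to a random other genotype state at `err_rate` and masked to
#' `MISSING` at `missing_rate`. A `reference` column carries the recipient
#' genome's own calls (all `HOM_REF` before error/missing).
#'
#' @param reference A [make_reference()] genome.
#' @param mosaics List of [make_accession()] genomes.
#' @param n_markers Number of markers (>= 1).
#' @param err_rate,missing_rate Per-call rates in [0, 1].
#' @param p_alt Probability of a homozygous-alternative call inside an
#'   introgression (default 0.9; the rest are heterozygote calls).
#' @param seed Integer RNG seed.
#' @return A `genotype_matrix` tibble: `marker_id`, `chrom`, `pos`, then one
#'   column per accession with calls in
#'   `{"HOM_REF", "HOM_ALT", "HET", "MISSING"}`.
#' @export
simulate_genotypes <- function(reference, mosaics, n_markers,
                               err_rate = 0, missing_rate = 0, p_alt = 0.9,
                               seed = 1) {
  stopifnot(inherits(reference, "ref_genome"))
  if (n_markers < 1) stop("n_markers must be >= 1")
  if (any(c(err_rate, missing_rate) < 0 | c(err_rate, missing_rate) > 1)) {
    stop("err_rate and missing_rate must lie in [0, 1]")
  }
  lens <- nchar(reference$seq)
  states <- c("HOM_REF", "HOM_ALT", "HET")
  with_seed(seed, {
    n_per <- as.vector(table(factor(
      sample(names(lens), n_markers, replace = TRUE, prob = lens),
      levels = names(lens))))
    mk <- bind_rows(purrr::map2(names(lens), n_per, function(ch, n) {
      if (n == 0) return(NULL)
      tibble(chrom = ch, pos = sort(sample.int(lens[[ch]], n)) - 1)
    }))
    mk$marker_id <- sprintf("marker_%05d", seq_len(nrow(mk)))
    out <- mk[, c("marker_id", "chrom", "pos")]
    accs <- c(list(reference = NULL), setNames(mosaics, vapply(mosaics, `[[`,
                                                               character(1), "id")))
    for (nm in names(accs)) {
      calls <- rep("HOM_REF", nrow(mk))
      mos <- accs[[nm]]
      if (!is.null(mos)) {
        for (i in seq_len(nrow(mos$truth))) {
          seg <- mos$truth[i, ]
          in_seg <- mk$chrom == seg$chrom & mk$pos >= seg$start & mk$pos < seg$end
          if (!any(in_seg)) next
          if (seg$donor == DELETION) {
            calls[in_seg] <- "MISSING"
          } else {
            alt <- runif(sum(in_seg)) < p_alt
            calls[in_seg] <- ifelse(alt, "HOM_ALT", "HET")
          }
        }
      }
      if (err_rate > 0) {
        flip <- runif(nrow(mk)) < err_rate & calls != "MISSING"
        if (any(flip)) {
          calls[flip] <- vapply(calls[flip], function(cc) {
            sample(setdiff(states, cc), 1)
          }, character(1))
        }
      }
      if (missing_rate > 0) {
        calls[runif(nrow(mk)) < missing_rate] <- "MISSING"
      }
      out[[nm]] <- calls
    }
    class(out) <- c("genotype_matrix", class(out))
    out
  })
}
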