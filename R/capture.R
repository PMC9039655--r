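# Divergence-dependent capture model and paired-end read simulation.
#
# Hybridization capture tolerates some probe-target divergence (vendor
# figures: ~10% for one chemistry, ~20% for another). The capture model
# turns probe-target divergence into a capture probability, either as a
# hard threshold (step) or as a smooth logistic fall-off; this is the
# mechanism that converts alien-segment divergence into coverage drops.

#' Define a capture-tolerance model
#'
#' @param tolerance Divergence fraction at which capture fails (0 < T < 1);
#'   default 0.10, the stricter of the published vendor tolerances.
#' @param mode `"step"` (capture iff divergence <= tolerance) or
#'   `"logistic"` (probability `1 / (1 + exp(k * (d - T)))`).
#' @param steepness Logistic steepness `k` (> 0).
#' @export
capture_model <- function(tolerance = 0.10, mode = c("step", "logistic"),
                          steepness = 80) {
  mode <- match.arg(mode)
  if (tolerance <= 0 || tolerance >= 1) stop("tolerance must lie in (0, 1)")
  if (steepness <= 0) stop("steepness must be > 0")
  structure(list(tolerance = tolerance, mode = mode, steepness = steepness),
            class = "capture_model")
}

#' Probability that a probe captures a target at divergence `d`
#'
#' Non-increasing in `d`; the step model returns 1 for `d <= tolerance` and
#' 0 beyond; the logistic model is exactly 0.5 at `d = tolerance`.
#'
#' @param d Divergence fraction(s) in [0, 1].
#' @param model A [capture_model()].
#' @export
capture_probability <- function(d, model) {
  stopifnot(inherits(model, "capture_model"))
  if (any(d < 0 | d > 1)) stop("d must lie in [0, 1]")
  if (model$mode == "step") {
    as.numeric(d <= model$tolerance)
  } else {
    1 / (1 + exp(model$steepness * (d - model$tolerance)))
  }
}

#' Divergence between a probe and its homologous mosaic window
#'
#' Mean per-base mismatch fraction between the probe sequence (reference
#' frame) and the homologous window of the accession genome. Bases missing
#' from the window (deleted sequence) count as mismatches, so a probe whose
#' window is fully deleted returns 1.0.
#'
#' @param probe One-row `probe_set` tibble (or list with `chrom`, `start`,
#'   `end`, `seq`).
#' @param mosaic A [make_accession()] genome.
#' @export
probe_divergence <- function(probe, mosaic) {
  win <- mosaic_window(mosaic, probe$chrom, probe$start, probe$end)
  plen <- nchar(probe$seq)
  n <- min(nchar(win), plen)
  mm <- str_mismatches(substr(probe$seq, 1, n), substr(win, 1, n))
  min(1, (mm + abs(nchar(win) - plen)) / plen)
}

# Expected number of read bases falling on a probe per captured pair, by
# deterministic numeric integration over the fragment-length distribution
# and the uniform placement jitter. Used to calibrate the per-probe Poisson
# rate so realized depth over probe bases matches `mean_depth`.
expected_probe_bases <- function(probe_len, frag_mean, frag_sd, read_len) {
  Ls <- seq(max(read_len, floor(frag_mean - 4 * frag_sd)),
            ceiling(frag_mean + 4 * frag_sd))
  wL <- dnorm(Ls, frag_mean, frag_sd); wL <- wL / sum(wL)
  cs <- seq(0.5, probe_len - 0.5)  # fragment centers across the probe
  tot <- 0
  for (i in seq_along(Ls)) {
    L <- Ls[i]
    m1s <- cs - L / 2; m1e <- m1s + read_len
    m2e <- cs + L / 2; m2s <- m2e - read_len
    ov <- function(s, e) pmax(0, pmin(e, probe_len) - pmax(s, 0))
    # mates are counted independently, so overlapping mates contribute twice
    cov <- ov(m1s, m1e) + ov(m2s, m2e)
    tot <- tot + wL[i] * mean(cov)
  }
  tot
}

#' Simulate capture-enriched paired-end reads for one accession
#'
#' For each probe, the probe-target divergence is computed in the accession
#' genome; the probe captures with [capture_probability()] and, if captured,
#' emits `Poisson(lambda)` read pairs, where `lambda` is calibrated so the
#' realized depth over probe-covered bases matches `mean_depth`. Fragments
#' are Normal(`frag_mean`, `frag_sd`) in length (truncated at `read_len`)
#' and centred on the probe with uniform jitter; mates are `read_len` bases
#' from each fragment end (mate 2 reverse-complemented). Sequencing errors
#' are i.i.d. substitutions at `err_rate`. The true origin of every pair is
#' recorded.
#'
#' @param mosaic A [make_accession()] genome.
#' @param probes A [design_probes()] probe set.
#' @param model A [capture_model()].
#' @param mean_depth Target mean depth over probe-covered bases (> 0).
#' @param frag_mean,frag_sd Fragment-length distribution (bp); defaults
#'   300 +/- 30, the sheared-library geometry the pipeline emulates.
#' @param read_len Read length (bp; default 150, paired 2 x 150).
#' @param err_rate Per-base sequencing error rate.
#' @param seed Integer RNG seed.
#' @return A `read_set` tibble: `pair_id`, `chrom`, `frag_start`, `frag_end`
#'   (mosaic frame, 0-based half-open), `origin` (donor name, `"reference"`,
#'   or boundary label), `mate1`, `mate2`.
#' @export
simulate_reads <- function(mosaic, probes, model, mean_depth,
                           frag_mean = 300, frag_sd = 30, read_len = 150,
                           err_rate = 0.001, seed = 1) {
  stopifnot(inherits(mosaic, "mosaic_genome"))
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  empty <- tibble(pair_id = character(), chrom = character(),
                  frag_start = numeric(), frag_end = numeric(),
                  origin = character(), mate1 = character(),
                  mate2 = character())
  attr(empty, "read_len") <- read_len
  attr(empty, "accession") <- mosaic$id
  class(empty) <- c("read_set", class(empty))
  if (nrow(probes) == 0) return(empty)

  probe_len <- nchar(probes$seq[1])
  lambda <- mean_depth * probe_len /
    expected_probe_bases(probe_len, frag_mean, frag_sd, read_len)
  mos_len <- nchar(mosaic$seq)

  with_seed(seed, {
    d <- vapply(seq_len(nrow(probes)),
                function(i) probe_divergence(probes[i, ], mosaic), numeric(1))
    p <- capture_probability(d, model)
    captured <- runif(nrow(probes)) < p
    npairs <- ifelse(captured, rpois(nrow(probes), lambda), 0L)
    centers <- vapply(seq_len(nrow(probes)), function(i) {
      if (npairs[i] == 0) return(NA_real_)
      mosaic_coord(mosaic, probes$chrom[i],
                   floor((probes$start[i] + probes$end[i]) / 2))
    }, numeric(1))
    npairs[is.na(centers)] <- 0L
    keep <- npairs > 0L
    if (!any(keep)) return(empty)

    chrom <- rep(probes$chrom[keep], npairs[keep])
    cen <- rep(centers[keep], npairs[keep])
    n <- length(cen)
    cj <- cen + runif(n, -probe_len / 2, probe_len / 2)
    L <- pmax(read_len, round(rnorm(n, frag_mean, frag_sd)))
    fs <- round(cj - L / 2)
    fs <- pmax(0, pmin(fs, mos_len[chrom] - L))
    fe <- fs + L
    mate1 <- substring(mosaic$seq[chrom], fs + 1, fs + read_len)
    mate2 <- revcomp(substring(mosaic$seq[chrom], fe - read_len + 1, fe))
    mate1 <- mutate_bases(mate1, err_rate)
    mate2 <- mutate_bases(mate2, err_rate)
    origin <- character(n)
    mid <- floor((fs + fe) / 2)
    for (ch in unique(chrom)) {
      idx <- chrom == ch
      origin[idx] <- mosaic_source_at(mosaic, ch, mid[idx])
    }
    out <- tibble(pair_id = sprintf("%s_p%06d", mosaic$id, seq_len(n)),
                  chrom = unname(chrom), frag_start = unname(fs),
                  frag_end = unname(fe), origin = origin,
                  mate1 = unname(mate1), mate2 = unname(mate2))
    attr(out, "read_len") <- read_len
    attr(out, "accession") <- mosaic$id
    class(out) <- c("read_set", class(out))
    out
  })
}
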