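# Independent oracles: exhaustive scans and textbook dynamic programming,
# written without reference to the package's engines.

# All-positions ungapped Hamming mapping of one read over a one-chromosome
# genome, both strands; returns the same fields as the mapper.
oracle_map_read <- function(genome, read, max_mismatch_frac = 0.06,
                            unique_margin = 1) {
  g <- utf8ToInt(genome)
  rl <- nchar(read)
  thresh <- floor(max_mismatch_frac * rl + 1e-6)
  cand <- NULL
  for (strand in 0:1) {
    q <- utf8ToInt(if (strand == 0) read else rc(read))
    ns <- length(g) - rl + 1
    if (ns < 1) next
    mm <- integer(ns)
    for (i in seq_len(rl)) mm <- mm + (g[i:(i + ns - 1)] != q[i])
    acc <- which(mm <= thresh)
    if (length(acc)) {
      cand <- rbind(cand, data.frame(start = acc - 1, strand = strand,
                                     mm = mm[acc]))
    }
  }
  if (is.null(cand) || nrow(cand) == 0) {
    return(list(status = "unmapped", n = 0L))
  }
  cand <- cand[order(cand$start, cand$strand), ]
  best_i <- which.min(cand$mm)  # first minimum in (start, strand) order
  best <- cand[best_i, ]
  second <- if (nrow(cand) > 1) sort(cand$mm)[2] else NA_integer_
  unique <- nrow(cand) == 1 || (second - best$mm >= unique_margin)
  list(status = if (unique) "unique" else "multimapped",
       start = best$start, strand = best$strand, mm = best$mm,
       n = nrow(cand))
}

# Exhaustive sliding-window local-hit oracle: every diagonal placement of
# the query on the target (both strands, clipped at target bounds) is a hit
# iff it covers >= min_cov of the query, has matches/query_len >=
# min_identity, and contains a run of >= word consecutive matches (the
# exact-seed condition).
oracle_hits <- function(query, target, min_identity = 0.80, min_cov = 0.80,
                        word = 11) {
  tg <- utf8ToInt(target)
  tlen <- length(tg)
  qlen <- nchar(query)
  out <- NULL
  for (strand in 0:1) {
    q <- utf8ToInt(if (strand == 0) query else rc(query))
    for (s in seq(-(qlen - word), tlen - word)) {
      ws <- max(s, 0); we <- min(s + qlen, tlen)
      winlen <- we - ws
      if (winlen + 1e-9 < min_cov * qlen) next
      m <- tg[(ws + 1):we] == q[(ws - s + 1):(we - s)]
      if (sum(m) + 1e-9 < min_identity * qlen) next
      r <- rle(m)
      if (!any(r$values & r$lengths >= word)) next
      out <- rbind(out, data.frame(tstart = ws, strand = strand,
                                   matches = sum(m), win_len = winlen))
    }
  }
  out
}

# Textbook Needleman-Wunsch score with linear gap costs.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- utf8ToInt(a); B <- utf8ToInt(b)
  prev <- seq(0, by = gap, length.out = length(B) + 1)
  for (i in seq_along(A)) {
    cur <- numeric(length(B) + 1)
    cur[1] <- i * gap
    sub <- prev[seq_along(B)] + ifelse(A[i] == B, match, mismatch)
    for (j in seq_along(B)) {
      cur[j + 1] <- max(sub[j], prev[j + 1] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[length(B) + 1]
}

# Plain agglomerative UPGMA returning the cophenetic distance matrix.
oracle_upgma_cophenetic <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  sizes <- rep(1, length(labs))
  coph <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  dm <- d
  while (length(clusters) > 1) {
    n <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (dm[i, j] < best[1]) best <- c(dm[i, j], i, j)
    }
    i <- best[2]; j <- best[3]; h <- best[1]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- h
    }
    newrow <- (sizes[i] * dm[i, ] + sizes[j] * dm[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(n), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  coph
}
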