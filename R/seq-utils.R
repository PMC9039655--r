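# Low-level sequence helpers. Genome sequences are plain character strings
# (one per chromosome) held in small S3 list objects; per-base work goes
# through raw vectors so multi-megabase chromosomes stay cheap.

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` with a locally set RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

random_dna <- function(n) {
  if (n == 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#  Count mismatching positions of two equal-length strings.
str_mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0) return(0L)
  sum(charToRaw(a) != charToRaw(b))
}

# Substitute each base independently with probability `rate` (to a uniformly
# chosen different base). Vectorised over sequences; consumes RNG.
mutate_bases <- function(seqs, rate) {
  if (rate == 0) return(seqs)
  lens <- nchar(seqs)
  nmut <- rbinom(length(seqs), lens, rate)
  todo <- which(nmut > 0L)
  base_raw <- charToRaw(paste(DNA_BASES, collapse = ""))
  for (i in todo) {
    r <- charToRaw(seqs[i])
    pos <- sample.int(lens[i], nmut[i])
    cur_idx <- match(r[pos], base_raw)
    shift <- sample.int(3L, nmut[i], replace = TRUE)
    r[pos] <- base_raw[((cur_idx - 1L + shift) %% 4L) + 1L]
    seqs[i] <- rawToChar(r)
  }
  seqs
}

# Apply random indel events (geometric lengths, mean 2 bp) to one sequence.
# Returns the edited sequence plus an edit table in the original (reference)
# frame: ref_pos is the 0-based offset of the event, delta the signed length
# change. Insertions land before base ref_pos; deletions remove
# [ref_pos, ref_pos - delta).
apply_indels <- function(seq, indel_rate) {
  n <- nchar(seq)
  edits <- tibble(ref_pos = numeric(), delta = numeric())
  if (indel_rate == 0 || n == 0) return(list(seq = seq, edits = edits))
  k <- rbinom(1L, n, indel_rate)
  if (k == 0) return(list(seq = seq, edits = edits))
  pos <- sort(sample.int(n, k)) - 1
  is_ins <- runif(k) < 0.5
  len <- rgeom(k, 0.5) + 1L
  pieces <- character()
  cur <- 0
  for (i in seq_len(k)) {
    p <- pos[i]
    if (p < cur) next  # falls inside an earlier deletion
    pieces <- c(pieces, substr(seq, cur + 1, p))
    if (is_ins[i]) {
      pieces <- c(pieces, random_dna(len[i]))
      edits <- bind_rows(edits, tibble(ref_pos = p, delta = len[i]))
      cur <- p
    } else {
      L <- min(len[i], n - p)
      edits <- bind_rows(edits, tibble(ref_pos = p, delta = -L))
      cur <- p + L
    }
  }
  pieces <- c(pieces, substr(seq, cur + 1, n))
  list(seq = paste(pieces, collapse = ""), edits = edits)
}

# Lift 0-based reference offsets through an edit table into the edited frame.
# Offsets inside a deleted run clamp to the deletion start.
lift_pos <- function(x, edits) {
  res <- as.numeric(x)
  if (nrow(edits) == 0) return(res)
  for (i in seq_len(nrow(edits))) {
    p <- edits$ref_pos[i]
    d <- edits$delta[i]
    if (d > 0) {
      res <- res + d * (x >= p)
    } else {
      res <- res - pmin(pmax(x - p, 0), -d)
    }
  }
  res
}
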