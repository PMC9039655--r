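# Readers and writers for the interchange formats the pipeline emits:
# FASTA genomes and probes, paired FASTQ, BED truth/probe/drop intervals,
# and TSV tables (genotype matrix with AA/BB/AB/NC calls, alignments,
# coverage, reports).

genome_seqs <- function(x) {
  if (inherits(x, c("ref_genome", "donor_genome", "mosaic_genome"))) x$seq
  else if (is.character(x)) x
  else stop("cannot extract sequences from a ", class(x)[1])
}

#' Write a genome (reference, donor, or mosaic) to FASTA
#' @param x Genome object or named character vector.
#' @param path Output file.
#' @export
write_genome_fasta <- function(x, path) {
  s <- Biostrings::DNAStringSet(genome_seqs(x))
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), sub("\\s.*$", "", names(s)))
}

#' Write probe sequences to FASTA
#' @param probes A `probe_set` tibble.
#' @param path Output file.
#' @export
write_probe_fasta <- function(probes, path) {
  s <- Biostrings::DNAStringSet(setNames(probes$seq, probes$probe_id))
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write intervals to BED (0-based half-open)
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally a name column.
#' @param path Output file.
#' @param name Column to use for the BED name field, if present.
#' @export
write_bed <- function(x, path, name = NULL) {
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(name) && name %in% names(x)) cols <- c(cols, list(x[[name]]))
  readr::write_lines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a BED file of known intervals
#'
#' Validates every line; a malformed line raises an error naming its line
#' number. Returns 0-based half-open intervals.
#'
#' @param path BED file (>= 3 columns; column 4, if present, is the label).
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- purrr::imap(parts, function(p, i) {
    if (length(p) < 3) stop("malformed BED line ", i, ": fewer than 3 fields")
    start <- suppressWarnings(as.numeric(p[2]))
    end <- suppressWarnings(as.numeric(p[3]))
    if (is.na(start) || is.na(end) || start < 0 || start >= end) {
      stop("malformed BED line ", i, ": bad interval [", p[2], ", ", p[3], ")")
    }
    tibble(chrom = p[1], start = start, end = end,
           label = if (length(p) >= 4) p[4] else NA_character_)
  })
  bind_rows(out)
}

#' Write a paired-end read set to two FASTQ files
#'
#' Mates go to `<prefix>_1.fastq` and `<prefix>_2.fastq` with `/1` and `/2`
#' read-id suffixes and constant Q30 quality strings.
#'
#' @param reads A `read_set` tibble from [simulate_reads()].
#' @param prefix Output path prefix.
#' @export
write_reads_fastq <- function(reads, prefix) {
  qual <- strrep("?", attr(reads, "read_len") %||% nchar(reads$mate1[1]))
  for (mate in 1:2) {
    seqs <- reads[[paste0("mate", mate)]]
    ids <- paste0("@", reads$pair_id, "/", mate)
    readr::write_lines(as.vector(rbind(ids, seqs, "+", qual)),
                       paste0(prefix, "_", mate, ".fastq"))
  }
  invisible(prefix)
}

#' Read paired FASTQ files back into a read tibble
#' @param prefix Path prefix used by [write_reads_fastq()].
#' @export
read_reads_fastq <- function(prefix) {
  rd <- function(mate) {
    s <- Biostrings::readDNAStringSet(paste0(prefix, "_", mate, ".fastq"),
                                      format = "fastq")
    tibble(pair_id = sub("/[12]$", "", sub("\\s.*$", "", names(s))),
           seq = as.character(s))
  }
  m1 <- rd(1); m2 <- rd(2)
  tibble(pair_id = m1$pair_id, mate1 = m1$seq,
         mate2 = m2$seq[match(m1$pair_id, m2$pair_id)])
}

GENO_TO_TSV <- c(HOM_REF = "AA", HOM_ALT = "BB", HET = "AB", MISSING = "NC")

#' Write a genotype matrix to TSV (AA/BB/AB/NC calls)
#' @param gm A `genotype_matrix` tibble.
#' @param path Output file.
#' @export
write_genotypes <- function(gm, path) {
  out <- gm
  for (col in setdiff(names(out), c("marker_id", "chrom", "pos"))) {
    out[[col]] <- unname(GENO_TO_TSV[out[[col]]])
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a genotype matrix TSV written by [write_genotypes()]
#' @param path TSV file.
#' @export
read_genotypes <- function(path) {
  gm <- readr::read_tsv(path, show_col_types = FALSE)
  from_tsv <- setNames(names(GENO_TO_TSV), GENO_TO_TSV)
  for (col in setdiff(names(gm), c("marker_id", "chrom", "pos"))) {
    gm[[col]] <- unname(from_tsv[gm[[col]]])
  }
  gm <- as_tibble(gm)
  class(gm) <- c("genotype_matrix", class(gm))
  gm
}

#' Write a dendrogram to Newick
#' @param tree An `ape::phylo` tree.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
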