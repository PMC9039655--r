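# Genotype-similarity statistics and UPGMA clustering.
#
# Similarity is identity-by-state over comparable markers (both calls
# non-missing); heterozygote calls are their own category, so HET vs
# HOM_REF counts as a mismatch (configurable). Distances are
# 100 - similarity; clustering is average-linkage agglomeration (UPGMA)
# yielding an ultrametric dendrogram with node heights equal to half the
# merge distance.

acc_columns <- function(gm) setdiff(names(gm), c("marker_id", "chrom", "pos"))

subset_markers <- function(gm, markers = NULL) {
  if (is.null(markers)) return(gm)
  if (is.logical(markers)) gm[markers, ]
  else gm[gm$marker_id %in% markers, ]
}

#' Markers falling inside a genomic interval
#' @param gm A `genotype_matrix` tibble.
#' @param chrom,start,end Interval (0-based half-open).
#' @return Character vector of marker ids.
#' @export
markers_in_interval <- function(gm, chrom, start, end) {
  gm$marker_id[gm$chrom == chrom & gm$pos >= start & gm$pos < end]
}

# Core pairwise similarity: percent of comparable markers with identical
# calls; NA (UNDEFINED) when no marker is comparable.
similarity_calls <- function(a, b, het_is_category = TRUE) {
  if (!het_is_category) {
    a[a == "HET"] <- "HOM_ALT"
    b[b == "HET"] <- "HOM_ALT"
  }
  comp <- a != "MISSING" & b != "MISSING"
  n <- sum(comp)
  list(n_comparable = n,
       percent = if (n == 0) NA_real_ else 100 * sum(a[comp] == b[comp]) / n)
}

#' Percent genotype similarity of accessions to a reference accession
#'
#' @param gm A `genotype_matrix` tibble.
#' @param accessions Accession columns to report (default: all but `ref`).
#' @param ref Reference accession column (default `"reference"`).
#' @param markers Optional marker subset (ids or logical mask).
#' @param label Marker-subset label carried into the report.
#' @param het_is_category If `TRUE` (default) HET is its own category; if
#'   `FALSE` HET is pooled with HOM_ALT.
#' @return A `similarity_report` tibble: `accession`, `subset`,
#'   `n_comparable`, `percent` (NA when no marker is comparable).
#' @export
genotype_similarity <- function(gm, accessions = NULL, ref = "reference",
                                markers = NULL, label = "all",
                                het_is_category = TRUE) {
  gm <- subset_markers(gm, markers)
  if (is.null(accessions)) accessions <- setdiff(acc_columns(gm), ref)
  out <- bind_rows(purrr::map(accessions, function(acc) {
    s <- similarity_calls(gm[[acc]], gm[[ref]], het_is_category)
    tibble(accession = acc, subset = label,
           n_comparable = s$n_comparable, percent = s$percent)
  }))
  class(out) <- unique(c("similarity_report", class(out)))
  out
}

#' All-pairs genotype distance matrix
#'
#' `d(a, b) = 100 - similarity(a, b)`; symmetric with a zero diagonal.
#' Pairs with no comparable marker get `NA` (refused by [upgma_tree()]).
#'
#' @inheritParams genotype_similarity
#' @return A symmetric numeric matrix with accession dimnames.
#' @export
genotype_distance <- function(gm, accessions = NULL, markers = NULL,
                              het_is_category = TRUE) {
  gm <- subset_markers(gm, markers)
  if (is.null(accessions)) accessions <- acc_columns(gm)
  if (length(accessions) < 2) stop("need >= 2 accessions")
  n <- length(accessions)
  d <- matrix(0, n, n, dimnames = list(accessions, accessions))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- similarity_calls(gm[[accessions[i]]], gm[[accessions[j]]],
                            het_is_category)
      d[i, j] <- d[j, i] <- if (is.na(s$percent)) NA_real_ else 100 - s$percent
    }
  }
  d
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration; node heights are half the merge distance,
#' so the tree is ultrametric and its cophenetic distances reproduce any
#' ultrametric input exactly.
#'
#' @param d Complete symmetric distance matrix (no NA).
#' @return An `ape::phylo` rooted ultrametric tree.
#' @export
upgma_tree <- function(d) {
  if (is.matrix(d)) {
    if (any(is.na(d))) stop("distance matrix has undefined entries")
    if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
    d <- as.dist(d)
  }
  if (any(is.na(d))) stop("distance matrix has undefined entries")
  ape::as.phylo(hclust(d, method = "average"))
}

#' Cut a dendrogram into k groups
#'
#' @param tree An ultrametric `phylo` tree from [upgma_tree()].
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
tree_groups <- function(tree, k = 2) {
  stats::cutree(ape::as.hclust.phylo(tree), k = k)
}
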