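# broom-style tidiers for the fitted/compound result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.map_result <- function(x, ...) x$alignments

#' @export
glance.map_result <- function(x, ...) {
  mutate(x$counts,
         unique_pct = compute_percent(.data$unique_pairs,
                                      .data$mapped_pairs))
}

#' @export
tidy.hit_summary <- function(x, ...) x$hits

#' @export
glance.hit_summary <- function(x, ...) x$summary

#' @export
tidy.locus_alignment <- function(x, ...) x$indels

#' @export
glance.locus_alignment <- function(x, ...) {
  tibble(score = x$score, matches = x$matches, columns = x$columns,
         percent_identity = x$percent_identity, n_indels = nrow(x$indels))
}

#' @export
tidy.attribution_table <- function(x, ...) x$reads

#' @export
glance.attribution_table <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("label", "fraction")],
                     names_from = "label", values_from = "fraction")
}

#' @export
glance.introdrop_run <- function(x, ...) {
  tibble(n_accessions = length(x$mosaics),
         n_probes = nrow(x$probes),
         total_read_pairs = sum(vapply(x$reads, nrow, numeric(1))),
         n_drop_calls = nrow(x$drops),
         donor_fraction_unmapped = x$attribution$donor_fraction_unmapped,
         donor_fraction_mapped = x$attribution$donor_fraction_mapped)
}
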