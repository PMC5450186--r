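#' Run the full reads-to-markers pipeline
#'
#' Chains the standard stages: deterministic-order digital
#' normalization, pooled support counting, support-bound filtering,
#' reference deduplication, lenient re-assignment to the retained
#' reference, pileup genotyping, CP-marker encoding, and the premapping
#' filter cascade.
#'
#' @param reads Read table (`read_id`, `individual_id`, `bases`).
#' @param parents The two parent individual IDs (parent 1 first).
#' @param dnr [dnr_params()]. Remember to scale `max_support` to the
#'   expected pooled per-locus depth of the design.
#' @param caller [caller_params()].
#' @param filters [filter_params()].
#' @return List with `alleles` (all putative alleles, flagged),
#'   `reference` (the retained alleles), `sites` (`variant_sites`),
#'   `markers_raw` (all informative CP markers), `markers` (cascade
#'   survivors) and `report` (the stage accounting).
#' @export
run_pipeline <- function(reads, parents = c("P1", "P2"),
                         dnr = dnr_params(), caller = caller_params(),
                         filters = filter_params()) {
  stopifnot(all(parents %in% reads$individual_id))
  reads <- .order_reads(reads)
  alleles <- build_dnr(reads, dnr)
  alleles <- count_support(reads, alleles, dnr)
  # consolidate near-identical catalog entries before the coverage
  # bounds, so error-derived twins (including twins of the plastid-like
  # sequence) are judged by their merged support
  alleles <- dedup_reference(alleles, dnr)
  alleles <- filter_support(alleles, dnr)
  ref <- retained_alleles(alleles)
  assign <- assign_reads(reads, ref, dnr)
  samples <- c(parents, sort(setdiff(unique(reads$individual_id), parents)))
  sites <- pileup_call(reads, ref, assign, caller, samples = samples)
  markers_raw <- markers_from_sites(sites, parents)
  casc <- run_cascade(markers_raw, filters)
  list(alleles = alleles, reference = ref, sites = sites,
       markers_raw = markers_raw, markers = casc$markers,
       report = casc$report)
}

#' Read and write CP marker tables as TSV
#'
#' Plain-text interchange format: the `info` columns (`marker_id`,
#' `seg_type`, `allele_id`, `position`) followed by one column per
#' individual holding the CP codes (`--` missing).
#'
#' @param markers A `cp_markers` object.
#' @param path TSV path.
#' @return `write_markers_tsv()` returns `path` invisibly;
#'   `read_markers_tsv()` returns a `cp_markers`.
#' @export
write_markers_tsv <- function(markers, path) {
  df <- cbind(markers$info, as.data.frame(markers$codes,
                                          stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers_tsv
#' @export
read_markers_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- intersect(c("marker_id", "seg_type", "allele_id", "position"),
                    names(df))
  codes <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  cp_markers(df[, meta, drop = FALSE], codes)
}
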