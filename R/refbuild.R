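#' Parameters for de novo reference construction
#'
#' Controls the streaming digital-normalization rule (a read becomes a
#' putative allele iff at least `novelty_fraction` of its distinct
#' k-mers are absent from all previously saved alleles), the support
#' bounds used to discard error singletons and very-high-copy
#' (plastid-like) sequences, and the lenient matcher tolerance.
#'
#' The support bounds default to the published rule: alleles with four
#' or fewer supporting reads are dropped as low-support, alleles with
#' more than 500 as high-copy. The upper bound must sit well above the
#' expected pooled per-locus read depth of the design; raise it when
#' simulating or sequencing deeper than the depths those defaults were
#' calibrated for.
#'
#' @param k K-mer size (default 15).
#' @param novelty_fraction Minimum novel fraction of a read's distinct
#'   k-mers for it to be saved (default 0.5, i.e. at least half).
#' @param min_support Alleles with support <= this are removed
#'   (default 4, "four or fewer").
#' @param max_support Alleles with support > this are removed
#'   (default 500).
#' @param max_mismatches Lenient matcher tolerance (default 8
#'   substitutions over the end-gap-free overlap).
#' @return A validated `dnr_params` list.
#' @export
dnr_params <- function(k = 15L, novelty_fraction = 0.5, min_support = 4L,
                       max_support = 500L, max_mismatches = 8L) {
  stopifnot(k >= 1, k <= 31,
            novelty_fraction > 0, novelty_fraction <= 1,
            min_support >= 0, min_support < max_support,
            max_mismatches >= 0)
  structure(list(k = as.integer(k), novelty_fraction = novelty_fraction,
                 min_support = as.integer(min_support),
                 max_support = as.integer(max_support),
                 max_mismatches = as.integer(max_mismatches)),
            class = "dnr_params")
}

.read_seqs <- function(reads) {
  if (is.data.frame(reads)) reads$bases else as.character(reads)
}

# canonical stream order: lexicographic by (individual_id, read_id);
# the C locale collation makes the order platform-independent
.order_reads <- function(reads) {
  if (!is.data.frame(reads)) return(reads)
  if (all(c("individual_id", "read_id") %in% names(reads))) {
    o <- order(reads$individual_id, reads$read_id, method = "radix")
    reads[o, , drop = FALSE]
  } else reads
}

#' Build a digital-normalization reference (DNR)
#'
#' Streams reads in a deterministic order (lexicographic by individual
#' then read ID) and saves a read as a new putative allele iff at least
#' `novelty_fraction` of its distinct k-mers are novel, i.e. not found
#' in any previously saved allele. Saving a read adds all its k-mers to
#' the index. K-mers are counted as distinct forward-strand strings (a
#' k-mer occurring twice in a read counts once; no reverse-complement
#' canonicalization, as only forward reads are used).
#'
#' @param reads Read table (`individual_id`, `read_id`, `bases`) or a
#'   character vector of sequences (then processed as given).
#' @param params [dnr_params()].
#' @return A `ref_alleles` data frame (`allele_id`, `sequence`,
#'   `support`, `source`, `copy_flag`), in saving order, with the number
#'   of too-short skipped reads in `attr(, "n_skipped")` and the final
#'   k-mer index size in `attr(, "kmer_index_size")`.
#' @export
build_dnr <- function(reads, params = dnr_params()) {
  reads <- .order_reads(reads)
  seqs <- .read_seqs(reads)
  res <- dnr_stream_cpp(seqs, params$k, params$novelty_fraction)
  saved <- res$saved
  n_skipped <- sum(is.na(saved))
  if (n_skipped > 0)
    warning(n_skipped, " read(s) shorter than k = ", params$k, " skipped")
  keep <- which(!is.na(saved) & saved)
  out <- data.frame(
    allele_id = sprintf("A%06d", seq_along(keep)),
    sequence = seqs[keep],
    support = NA_integer_,
    source = "DNR",
    copy_flag = NA_character_,
    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "kmer_index_size") <- res$index_size
  class(out) <- c("ref_alleles", "data.frame")
  out
}

#' Lenient read-to-allele assignment
#'
#' A seeded, end-gap-free, substitution-only matcher standing in for a
#' permissive short-read aligner: candidate alleles share at least one
#' exact k-mer with the read, and the best hit is the candidate with the
#' fewest mismatches over the common prefix (reads are restriction-site
#' anchored, so offset 0 is the only alignment considered). Hits with
#' more than `max_mismatches` substitutions are discarded; ties break to
#' the lowest `allele_id`.
#'
#' @param reads Read table or character vector of sequences.
#' @param alleles A `ref_alleles` table.
#' @param params [dnr_params()] (uses `k` and `max_mismatches`).
#' @return Integer vector: row index into `alleles` of each read's best
#'   hit, NA when no allele is within tolerance; mismatch counts in
#'   `attr(, "mismatches")`.
#' @export
assign_reads <- function(reads, alleles, params = dnr_params()) {
  o <- order(alleles$allele_id, method = "radix")
  stopifnot(!is.unsorted(o))  # alleles are kept sorted by allele_id
  res <- match_reads_cpp(.read_seqs(reads), alleles$sequence,
                         params$k, params$max_mismatches)
  out <- res$allele
  attr(out, "mismatches") <- res$mismatches
  out
}

#' @rdname assign_reads
#' @param read,max_mismatches Single-read convenience form: returns the
#'   best-hit `allele_id` or `NA_character_`.
#' @export
lenient_match <- function(read, alleles, max_mismatches = 8L) {
  p <- dnr_params(max_mismatches = max_mismatches)
  i <- assign_reads(read, alleles, p)
  if (is.na(i[1])) NA_character_ else alleles$allele_id[i[1]]
}

#' Count read support per putative allele
#'
#' Support is the number of reads (parents and progeny pooled) whose
#' best lenient match is the allele.
#'
#' @inheritParams assign_reads
#' @return `alleles` with the `support` column filled in.
#' @export
count_support <- function(reads, alleles, params = dnr_params()) {
  a <- assign_reads(reads, alleles, params)
  alleles$support <- tabulate(a, nbins = nrow(alleles))
  alleles
}

#' Apply the support bounds to putative alleles
#'
#' Retains alleles with `min_support < support <= max_support`; removed
#' alleles are flagged `low_support` (<= 4 by default, "four or fewer
#' alignments") or `high_copy` (> 500 by default, the plastid-like tail).
#'
#' @param alleles `ref_alleles` with support counted.
#' @param params [dnr_params()].
#' @return `alleles` with `copy_flag` set; subset on
#'   `copy_flag == "retained"` for the working reference.
#' @export
filter_support <- function(alleles, params = dnr_params()) {
  stopifnot(!anyNA(alleles$support))
  alleles$copy_flag <- ifelse(
    alleles$support <= params$min_support, "low_support",
    ifelse(alleles$support > params$max_support, "high_copy", "retained"))
  alleles
}

#' @rdname filter_support
#' @export
retained_alleles <- function(alleles) {
  out <- alleles[!is.na(alleles$copy_flag) &
                   alleles$copy_flag == "retained", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse near-identical reference alleles
#'
#' Allelic variants of one locus (and occasionally a haplotype saved
#' separately because the first-saved read carried sequencing errors)
#' can yield several reference entries within the matcher tolerance of
#' each other. Reads then split across them and the locus's SNP never
#' surfaces in any single pileup. This step maps every retained allele
#' onto its closest already-kept neighbour within `max_mismatches`
#' (greedy, in decreasing support order, ties by lowest `allele_id`),
#' keeping one representative per near-identical cluster; merged
#' supports are summed. Diverged paralog copies collapse here as well,
#' which is intended: their sites become multi-SNP sequences that the
#' F1 filter removes.
#'
#' @param alleles `ref_alleles` with support counted (applied to the
#'   full putative set before the support bounds, so merged twins are
#'   judged by their pooled support).
#' @param params [dnr_params()] (uses `k` and `max_mismatches`).
#' @return The deduplicated `ref_alleles`, with the number of merged
#'   entries in `attr(, "n_merged")`.
#' @export
dedup_reference <- function(alleles, params = dnr_params()) {
  if (nrow(alleles) <= 1) return(alleles)
  keeper <- dedup_alleles_cpp(alleles$sequence,
                              as.numeric(alleles$support),
                              params$k, params$max_mismatches)
  out <- alleles[sort(unique(keeper)), , drop = FALSE]
  merged_support <- tapply(alleles$support, keeper, sum)
  out$support <- as.integer(merged_support[as.character(sort(unique(keeper)))])
  attr(out, "n_merged") <- nrow(alleles) - nrow(out)
  rownames(out) <- NULL
  out
}

#' Build a center-star reference (CSR)
#'
#' Clusters progeny reads by their best lenient match to a parental
#' allele set (typically [build_dnr()] on parent reads only), then emits
#' per cluster the sequence minimizing the total Hamming distance to all
#' other cluster members (the center of the star), ties broken by the
#' lexicographically smallest sequence. Size-1 clusters are emitted with
#' a `singleton` flag.
#'
#' @param parent_alleles `ref_alleles` built from parent reads.
#' @param progeny_reads Read table or sequence vector of progeny reads.
#' @param params [dnr_params()].
#' @return A `ref_alleles` table with `source = "CSR"`, cluster sizes in
#'   `n_members`, and `copy_flag = "singleton"` for size-1 clusters.
#' @export
build_csr <- function(parent_alleles, progeny_reads,
                      params = dnr_params()) {
  seqs <- .read_seqs(progeny_reads)
  a <- assign_reads(progeny_reads, parent_alleles, params)
  keep <- !is.na(a)
  seqs <- seqs[keep]; a <- a[keep]
  out <- lapply(sort(unique(a)), function(ai) {
    s <- seqs[a == ai]
    tab <- table(s)
    u <- names(tab)
    ctr <- csr_center_cpp(u, as.numeric(tab))
    data.frame(allele_id = paste0("CSR_", parent_alleles$allele_id[ai]),
               sequence = u[ctr$index],
               support = length(s),
               source = "CSR",
               copy_flag = if (length(s) == 1) "singleton" else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("ref_alleles", "data.frame")
  out
}

#' Write a reference allele set as FASTA
#'
#' @param alleles `ref_alleles` table.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_ref_fasta <- function(alleles, path) {
  x <- Biostrings::DNAStringSet(alleles$sequence)
  names(x) <- alleles$allele_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Import read-to-allele assignments from a SAM file
#'
#' For users who run a real aligner for the support-counting and pileup
#' step instead of the internal matcher. Primary alignments are taken
#' as-is; the reference name must be an `allele_id`.
#'
#' @param path SAM file path.
#' @param alleles `ref_alleles` table the SAM was aligned against.
#' @return Data frame with `read_id` and the matched allele row index
#'   `allele` (NA for unmapped records).
#' @export
import_sam <- function(path, alleles) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required for SAM import", call. = FALSE)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  b <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("qname", "rname")))[[1]]
  data.frame(read_id = b$qname,
             allele = match(as.character(b$rname), alleles$allele_id),
             stringsAsFactors = FALSE)
}
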