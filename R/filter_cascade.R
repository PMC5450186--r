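#' Parameters for the premapping filter cascade
#'
#' Defaults follow the published final criteria: one SNP per sequence,
#' SNP position at least 10 (the first 9 bases are artifact-prone),
#' missing-data fraction strictly below 5%, chi-square test statistic
#' for deviation from Mendelian expectation strictly below 20
#' (`chi2_mode = "statistic"`; alternatively `"pvalue"` retains markers
#' with p >= the cutoff, e.g. a genome-wide 0.025 applied per marker
#' with no multiplicity correction), individuals with more than 90%
#' missing data excluded, and markers with genotype similarity >= 0.945
#' deduplicated.
#'
#' @param max_snps_per_sequence Maximum called SNPs a reference sequence
#'   may carry for its sites to survive F1 (default 1).
#' @param min_position Minimum 1-based SNP position (default 10, i.e.
#'   positions 1..9 are dropped).
#' @param missing_threshold Marker-level missing-data bound; markers
#'   survive when missing fraction < threshold (0 means no missing
#'   allowed). The published sweep used 0--0.30, final 0.05.
#' @param chi2_mode `"statistic"` or `"pvalue"`.
#' @param chi2_cutoff Statistic bound (sweep 10--50, final 20) in
#'   statistic mode, or alpha (0.025) in pvalue mode.
#' @param similarity_threshold Pairs at or above this genotype
#'   similarity are collapsed to one representative (default 0.945).
#' @param individual_missing_threshold Individuals with missing fraction
#'   strictly above this are excluded (default 0.90).
#' @return A validated `filter_params` list.
#' @export
filter_params <- function(max_snps_per_sequence = 1L, min_position = 10L,
                          missing_threshold = 0.05,
                          chi2_mode = c("statistic", "pvalue"),
                          chi2_cutoff = NULL,
                          similarity_threshold = 0.945,
                          individual_missing_threshold = 0.90) {
  chi2_mode <- match.arg(chi2_mode)
  if (is.null(chi2_cutoff))
    chi2_cutoff <- if (chi2_mode == "statistic") 20 else 0.025
  stopifnot(max_snps_per_sequence >= 1, min_position >= 1,
            missing_threshold >= 0, missing_threshold <= 1,
            chi2_cutoff > 0,
            similarity_threshold > 0, similarity_threshold <= 1,
            individual_missing_threshold >= 0,
            individual_missing_threshold <= 1)
  if (chi2_mode == "pvalue" && chi2_cutoff >= 1)
    stop("pvalue-mode chi2_cutoff must be an alpha below 1", call. = FALSE)
  structure(list(max_snps_per_sequence = as.integer(max_snps_per_sequence),
                 min_position = as.integer(min_position),
                 missing_threshold = missing_threshold,
                 chi2_mode = chi2_mode, chi2_cutoff = chi2_cutoff,
                 similarity_threshold = similarity_threshold,
                 individual_missing_threshold = individual_missing_threshold),
            class = "filter_params")
}

#' F1: drop markers on multi-SNP sequences
#'
#' A marker survives iff its reference sequence carries exactly one
#' called SNP (more precisely, at most `max_snps_per_sequence`).
#' Collapsed paralogs -- near-identical repeat copies absorbed into one
#' reference allele -- manifest as sequences with several SNPs and are
#' the main driver of map inflation, so their sites are removed
#' wholesale.
#'
#' @param markers A `cp_markers` object.
#' @param max_snps_per_sequence Default 1.
#' @return The retained `cp_markers`.
#' @export
f1_multi_snp <- function(markers, max_snps_per_sequence = 1L) {
  # per-sequence SNP counts are fixed at call time (n_snps_sequence,
  # recorded by markers_from_sites); removing a site elsewhere in the
  # cascade must not turn a multi-SNP sequence into a single-SNP one
  n <- markers$info$n_snps_sequence
  if (is.null(n)) {
    tab <- table(markers$info$allele_id)
    n <- as.integer(tab[markers$info$allele_id])
  }
  markers[which(n <= max_snps_per_sequence)]
}

#' F2: drop markers with SNPs near the restriction site
#'
#' Survives iff the 1-based SNP position is at least `min_position`
#' (default 10): SNPs in the first 9 bases of the marker sequence are
#' artifact-prone.
#'
#' @param markers A `cp_markers` object.
#' @param min_position Default 10.
#' @return The retained `cp_markers`.
#' @export
f2_position <- function(markers, min_position = 10L) {
  markers[which(markers$info$position >= min_position)]
}

#' F3: drop markers with too much missing data
#'
#' The missing fraction is computed over the currently retained
#' individuals (the code columns present). With `threshold > 0` a
#' marker survives iff its missing fraction is strictly below the
#' threshold (the published final criterion is "< 5% missing data");
#' with `threshold = 0` no missing data is allowed.
#'
#' @param markers A `cp_markers` object.
#' @param threshold Missing-data bound in `[0, 1]`.
#' @return The retained `cp_markers`.
#' @export
f3_missing <- function(markers, threshold = 0.05) {
  mf <- rowMeans(markers$codes == "--")
  keep <- if (threshold > 0) mf < threshold else mf == 0
  markers[which(keep)]
}

#' Chi-square test for deviation from Mendelian expectation
#'
#' Pearson chi-square of the non-missing code counts against the
#' expected segregation ratio: 1:1 for lm x ll / nn x np (df 1), 1:2:1
#' for hk x hk (df 2), 1:1:1:1 for ef x eg / ab x cd (df 3).
#'
#' @param codes Character vector of CP codes for one marker (`"--"`
#'   missing).
#' @param seg_type The marker's segregation type.
#' @return List with `statistic`, `df`, `p.value`, and the observed
#'   `counts`; all NA (marker flagged) when no individuals are scored.
#' @export
chi2_segregation <- function(codes, seg_type) {
  classes <- legal_cp_codes(seg_type)
  ratio <- if (seg_type == "hkxhk") c(1, 2, 1) else rep(1, length(classes))
  obs <- table(factor(codes[codes != "--"], levels = classes))
  n <- sum(obs)
  if (n == 0)
    return(list(statistic = NA_real_, df = NA_integer_, p.value = NA_real_,
                counts = obs))
  e <- n * ratio / sum(ratio)
  stat <- sum((obs - e)^2 / e)
  df <- length(classes) - 1L
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE), counts = obs)
}

#' F4: segregation-distortion screen
#'
#' In statistic mode a marker survives iff its chi-square statistic is
#' strictly below the cutoff; in pvalue mode iff its p-value is at
#' least alpha. Markers with no scored individuals are removed and
#' counted in `attr(, "n_undefined")`.
#'
#' @param markers A `cp_markers` object.
#' @param params [filter_params()] (uses `chi2_mode`, `chi2_cutoff`).
#' @return The retained `cp_markers`.
#' @export
f4_chi2_filter <- function(markers, params = filter_params()) {
  res <- lapply(seq_len(nrow(markers$info)), function(i)
    chi2_segregation(markers$codes[i, ], markers$info$seg_type[i]))
  stat <- vapply(res, `[[`, numeric(1), "statistic")
  pval <- vapply(res, `[[`, numeric(1), "p.value")
  keep <- if (params$chi2_mode == "statistic")
    !is.na(stat) & stat < params$chi2_cutoff
  else !is.na(pval) & pval >= params$chi2_cutoff
  out <- markers[which(keep)]
  attr(out, "n_undefined") <- sum(is.na(stat))
  out
}

#' Exclude individuals with excessive missing data
#'
#' Individuals whose missing fraction across the current markers is
#' strictly above the threshold are removed from all markers.
#'
#' @param markers A `cp_markers` object.
#' @param threshold Default 0.90 ("more than 90% missing data").
#' @return `cp_markers` over the retained individuals; the dropped IDs
#'   are in `attr(, "dropped_individuals")`.
#' @export
drop_individuals <- function(markers, threshold = 0.90) {
  mf <- colMeans(markers$codes == "--")
  dropped <- colnames(markers$codes)[mf > threshold]
  out <- markers[, which(mf <= threshold)]
  attr(out, "dropped_individuals") <- dropped
  out
}

#' Genotype similarity between two markers
#'
#' Fraction of individuals, among those non-missing in both markers,
#' with identical codes; NA when no individual is scored in both.
#'
#' @param a,b Character code vectors of equal length (`"--"` missing).
#' @return Similarity in `[0, 1]`, or NA.
#' @export
similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- a != "--" & b != "--"
  if (!any(ok)) return(NA_real_)
  mean(a[ok] == b[ok])
}

#' Deduplicate markers with near-identical genotypes
#'
#' Single-linkage clusters over marker pairs with similarity at or
#' above the threshold; one representative is kept per cluster -- the
#' marker with the least missing data, ties broken by lexicographic
#' marker ID. Pairs with no shared scored individual are never linked.
#'
#' @param markers A `cp_markers` object.
#' @param threshold Default 0.945.
#' @return The representative `cp_markers`.
#' @export
similarity_dedup <- function(markers, threshold = 0.945) {
  m <- nrow(markers$info)
  if (m <= 1) return(markers)
  sim <- pairwise_similarity_cpp(.codes_int(markers))
  link <- !is.na(sim) & !is.nan(sim) & sim >= threshold
  comp <- .components(link)
  miss <- rowMeans(markers$codes == "--")
  ids <- markers$info$marker_id
  reps <- vapply(split(seq_len(m), comp), function(i) {
    i[order(miss[i], ids[i], method = "radix")][1]
  }, integer(1))
  markers[sort(unname(reps))]
}

# integer-coded genotype matrix (0 = missing) shared by the pairwise
# similarity and LOD kernels
.codes_int <- function(markers) {
  lv <- setdiff(sort(unique(as.vector(markers$codes))), "--")
  mat <- matrix(match(markers$codes, lv, nomatch = 0L),
                nrow = nrow(markers$codes))
  attr(mat, "levels") <- lv
  mat
}

# connected components of a logical adjacency matrix (single linkage)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (!length(nb)) next
      m <- min(comp[i], comp[nb])
      if (any(c(comp[i], comp[nb]) != m)) {
        comp[c(i, nb)] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Run the full premapping filter cascade
#'
#' Applies, in order: F1 (multi-SNP sequences), F2 (SNP position), F3
#' (marker missing data), F4 (segregation-distortion chi-square), then
#' the final-map preparation steps: exclusion of individuals with
#' excessive missing data and similarity deduplication. Emits a
#' stage-by-stage accounting of surviving marker counts.
#'
#' @param markers A `cp_markers` object (the informative SNP calls).
#' @param params [filter_params()].
#' @return List with `markers` (the survivors) and `report` (a
#'   `cascade_report` data frame of stage names, marker counts and
#'   individual counts).
#' @export
run_cascade <- function(markers, params = filter_params()) {
  stages <- list()
  note <- function(stage, m) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, n_markers = nrow(m$info), n_individuals = ncol(m$codes),
      stringsAsFactors = FALSE)
  }
  note("input", markers)
  markers <- f1_multi_snp(markers, params$max_snps_per_sequence)
  note("f1_multi_snp", markers)
  markers <- f2_position(markers, params$min_position)
  note("f2_position", markers)
  markers <- f3_missing(markers, params$missing_threshold)
  note(sprintf("f3_missing(%g)", params$missing_threshold), markers)
  markers <- f4_chi2_filter(markers, params)
  note(sprintf("f4_chi2(%s %g)", params$chi2_mode, params$chi2_cutoff),
       markers)
  markers <- drop_individuals(markers, params$individual_missing_threshold)
  dropped <- attr(markers, "dropped_individuals")
  note("individuals_dropped", markers)
  markers <- similarity_dedup(markers, params$similarity_threshold)
  note(sprintf("similarity_dedup(%g)", params$similarity_threshold), markers)
  report <- do.call(rbind, stages)
  class(report) <- c("cascade_report", "data.frame")
  attr(report, "dropped_individuals") <- dropped
  list(markers = markers, report = report)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Sequential filtration\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-28s %8d markers  %5d individuals\n",
                x$stage[i], x$n_markers[i], x$n_individuals[i]))
  invisible(x)
}
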