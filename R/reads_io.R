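#' Read a FASTQ file into a read table
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] (gzip
#' transparent). The full header line (identifier plus any comment, e.g.
#' the Illumina `1:N:0:<index>` field) is kept in `read_id`.
#'
#' @param path FASTQ file (optionally gzipped).
#' @return Data frame with `read_id`, `bases`, `qualities`.
#' @export
read_fastq <- function(path) {
  tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    data.frame(read_id = unname(names(x)),
               bases = unname(as.character(x)),
               qualities = unname(as.character(S4Vectors::mcols(x)$qualities)),
               stringsAsFactors = FALSE)
  }, error = function(e) stop("malformed FASTQ in '", path, "': ",
                              conditionMessage(e), call. = FALSE))
}

#' Write a read table to FASTQ
#'
#' @param reads Data frame with `read_id`, `bases` and optionally
#'   `qualities` (constant Q40 is written when absent).
#' @param path Output path; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "bases") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  q <- if ("qualities" %in% names(reads)) reads$qualities
       else strrep("I", nchar(reads$bases))
  tryCatch(
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                compress = grepl("\\.gz$", path),
                                qualities = Biostrings::BStringSet(q)),
    error = function(e) stop("cannot write FASTQ to '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Write a simulated read set as per-individual and lane FASTQ files
#'
#' Per-individual files are named `<individual>.fastq`; the pooled lane
#' file `lane.fastq` carries each read's index tag in an Illumina-style
#' header comment (`1:N:0:<tag>`).
#'
#' @param reads Read table from [emit_reads()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_read_set <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inds <- unique(reads$individual_id)
  files <- character(0)
  for (ind in inds) {
    p <- file.path(dir, paste0(ind, ".fastq"))
    write_fastq(reads[reads$individual_id == ind, , drop = FALSE], p)
    files[ind] <- p
  }
  lane <- reads
  lane$read_id <- paste0(lane$read_id, " 1:N:0:", lane$index_tag)
  lp <- file.path(dir, "lane.fastq")
  write_fastq(lane, lp)
  files["lane"] <- lp
  files
}

#' Demultiplex a lane FASTQ by index tag
#'
#' Reads are assigned to individuals by exact match of the index tag in
#' the header comment (the field after the final `:`); reads with absent
#' or unmapped tags go to the unmatched bin. Headers are renamed to
#' `<individual>:<original id>` so downstream files identify the
#' individual unambiguously.
#'
#' @param lane FASTQ path, or a read table as returned by [read_fastq()].
#' @param index_map Two-column data frame (`index_tag`, `individual_id`)
#'   or a named character vector `tag -> individual`.
#' @param out_dir Optional directory; per-individual FASTQ files plus
#'   `unmatched.fastq` are written there.
#' @return Read table with `individual_id` (NA for unmatched) and
#'   `index_tag` columns; per-individual counts (including `unmatched`)
#'   in `attr(, "counts")`.
#' @export
demultiplex <- function(lane, index_map, out_dir = NULL) {
  if (is.character(lane) && length(lane) == 1) lane <- read_fastq(lane)
  if (is.data.frame(index_map)) {
    stopifnot(all(c("index_tag", "individual_id") %in% names(index_map)))
    map <- setNames(index_map$individual_id, index_map$index_tag)
  } else map <- index_map
  if (anyDuplicated(names(map)))
    stop("duplicate index tags in map: ",
         paste(unique(names(map)[duplicated(names(map))]), collapse = ", "),
         call. = FALSE)
  hdr <- lane$read_id
  has_comment <- grepl("[ \t].*:", hdr)
  tag <- ifelse(has_comment, sub(".*:", "", hdr), NA_character_)
  ind <- unname(map[tag])
  id_part <- sub("[ \t].*$", "", hdr)
  out <- data.frame(
    read_id = ifelse(is.na(ind), id_part, paste0(ind, ":", id_part)),
    individual_id = ind,
    bases = lane$bases,
    qualities = lane$qualities,
    index_tag = tag,
    stringsAsFactors = FALSE)
  counts <- c(table(factor(ind, levels = unique(unname(map)))),
              unmatched = sum(is.na(ind)))
  attr(out, "counts") <- counts
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in unique(unname(map))) {
      write_fastq(out[!is.na(out$individual_id) & out$individual_id == i,
                      , drop = FALSE],
                  file.path(out_dir, paste0(i, ".fastq")))
    }
    write_fastq(out[is.na(out$individual_id), , drop = FALSE],
                file.path(out_dir, "unmatched.fastq"))
  }
  out
}

#' Downsample reads to an exact fraction
#'
#' Retains exactly `round(fraction * n)` reads (half-up rounding, so 52%
#' of 50 reads keeps 26), sampled uniformly without replacement; original
#' read order is preserved. The same input, fraction and seed always
#' return the same subset.
#'
#' @param reads Read table (any data frame with one row per read).
#' @param fraction Proportion in (0, 1].
#' @param seed Integer RNG seed.
#' @return The retained subset of `reads`.
#' @export
downsample_reads <- function(reads, fraction, seed = 1L) {
  stopifnot(is.numeric(fraction), fraction > 0, fraction <= 1)
  n <- nrow(reads)
  if (n == 0) {
    warning("downsampling an empty read set")
    return(reads)
  }
  keep_n <- floor(fraction * n + 0.5)
  set.seed(seed)
  keep <- sort(sample.int(n, keep_n))
  reads[keep, , drop = FALSE]
}

#' @rdname downsample_reads
#' @param input,output FASTQ paths for the file-level variant.
#' @return `downsample_fastq()` returns `output` invisibly.
#' @export
downsample_fastq <- function(input, output, fraction, seed = 1L) {
  write_fastq(downsample_reads(read_fastq(input), fraction, seed), output)
}

#' Depth-design downsampling experiments
#'
#' Emulates running more samples per sequencing lane by random read
#' subsetting. `Exp1` keeps the parents intact and retains 52% of each
#' progeny's reads (50 vs 96 progeny per lane); `Exp2` additionally
#' retains 64% of each parent's reads (32/50 of a lane per parent).
#'
#' @param reads Read table with an `individual_id` column.
#' @param experiment `"Exp1"` or `"Exp2"`.
#' @param parents Individual IDs of the two parents.
#' @param seed Integer RNG seed; per-individual subsets are drawn from
#'   one stream over individuals in sorted order, so results are
#'   reproducible.
#' @return The downsampled read table.
#' @export
exp_harness <- function(reads, experiment = c("Exp1", "Exp2"),
                        parents = c("P1", "P2"), seed = 1L) {
  experiment <- match.arg(experiment)
  stopifnot("individual_id" %in% names(reads))
  frac_progeny <- 0.52
  frac_parent <- if (experiment == "Exp2") 0.64 else 1
  inds <- sort(unique(reads$individual_id))
  set.seed(seed)
  kept <- lapply(inds, function(ind) {
    i <- which(reads$individual_id == ind)
    f <- if (ind %in% parents) frac_parent else frac_progeny
    if (f >= 1) return(i)
    i[sort(sample.int(length(i), floor(f * length(i) + 0.5)))]
  })
  reads[sort(unlist(kept)), , drop = FALSE]
}
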