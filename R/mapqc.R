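#' Write a JoinMap CP-format locus file
#'
#' Emits the standard `.loc` layout for an F1 population of two
#' outcrossing parents: a header (`name`, `popt = CP`, `nloc`, `nind`),
#' then one record per marker with its segregation-type tag (e.g.
#' `<lmxll>`) and the per-individual codes, `--` for missing. Phase is
#' never written (it is not inferred). Output is byte-stable for a
#' fixed input.
#'
#' @param markers A `cp_markers` object.
#' @param path Output path.
#' @param name Population name for the header.
#' @return `path`, invisibly.
#' @export
write_loc <- function(markers, path, name = "pop") {
  info <- markers$info
  codes <- markers$codes
  for (t in unique(info$seg_type)) {
    legal <- c(legal_cp_codes(t), "--")
    rows <- which(info$seg_type == t)
    bad <- which(!(codes[rows, , drop = FALSE] %in% legal))
    if (length(bad)) {
      mk <- info$marker_id[rows[(bad[1] - 1) %% length(rows) + 1]]
      stop("refusing to write illegal code for marker ", mk, call. = FALSE)
    }
  }
  con <- file(path, "wb")  # binary mode: fixed \n line endings
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con, sep = "\n")
  wl(c(paste("name =", name), "popt = CP",
       paste("nloc =", nrow(info)), paste("nind =", ncol(codes)), ""))
  for (i in seq_len(nrow(info))) {
    wl(paste0(info$marker_id[i], " <", info$seg_type[i], ">"))
    wl(paste(codes[i, ], collapse = " "))
  }
  invisible(path)
}

#' Parse a JoinMap CP-format locus file written by [write_loc()]
#'
#' @param path `.loc` path.
#' @return A `cp_markers` object (individuals named `ind1..indN` --
#'   the format does not carry individual names).
#' @export
read_loc <- function(path) {
  lines <- readLines(path)
  nloc <- as.integer(sub("nloc *= *", "", grep("^nloc", lines, value = TRUE)))
  nind <- as.integer(sub("nind *= *", "", grep("^nind", lines, value = TRUE)))
  body <- lines[-seq_len(grep("^nind", lines)[1])]
  body <- body[nzchar(trimws(body))]
  stopifnot(length(body) == 2 * nloc)
  hdr <- body[seq(1, length(body), by = 2)]
  rows <- body[seq(2, length(body), by = 2)]
  marker_id <- sub(" .*$", "", hdr)
  seg_type <- sub("^.*<(.*)>.*$", "\\1", hdr)
  codes <- t(vapply(strsplit(trimws(rows), "[ \t]+"),
                    identity, character(nind)))
  colnames(codes) <- paste0("ind", seq_len(nind))
  cp_markers(data.frame(marker_id = marker_id, seg_type = seg_type,
                        stringsAsFactors = FALSE), codes)
}

#' Write and read fixed framework orders
#'
#' One ordered marker list per linkage group; the order is fixed, not
#' the distances. Markers listed for a group must exist in the marker
#' table (when one is supplied) and may not repeat.
#'
#' @param orders Named list: group ID -> character vector of marker IDs
#'   in fixed order.
#' @param path Output path.
#' @param markers Optional `cp_markers`; membership is validated.
#' @return `path` invisibly; `read_fixed_order()` returns the list.
#' @export
write_fixed_order <- function(orders, path, markers = NULL) {
  stopifnot(is.list(orders), !is.null(names(orders)))
  for (g in names(orders)) {
    ids <- orders[[g]]
    if (anyDuplicated(ids))
      stop("duplicate marker in fixed order for group ", g, ": ",
           ids[duplicated(ids)][1], call. = FALSE)
    if (!is.null(markers)) {
      absent <- setdiff(ids, markers$info$marker_id)
      if (length(absent))
        stop("fixed-order marker absent from table: ", absent[1],
             call. = FALSE)
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  for (g in names(orders))
    writeLines(c(paste("group", g), orders[[g]], ""), con = con, sep = "\n")
  invisible(path)
}

#' @rdname write_fixed_order
#' @export
read_fixed_order <- function(path) {
  lines <- readLines(path)
  out <- list()
  g <- NULL
  for (l in trimws(lines)) {
    if (!nzchar(l)) next
    if (startsWith(l, "group ")) {
      g <- sub("^group ", "", l)
      out[[g]] <- character(0)
    } else out[[g]] <- c(out[[g]], l)
  }
  out
}

#' Independence LOD between two markers
#'
#' G-test of independence on the contingency table of the two markers'
#' codes over shared non-missing individuals, expressed as
#' `LOD = G / (2 ln 10)`. This is the phase-free grouping statistic:
#' it needs no linkage-phase assumption, only association between
#' genotype classes. Zero-count cells contribute nothing; degenerate
#' tables (a single observed row or column) give LOD 0.
#'
#' @param a,b Character code vectors (`"--"` missing) of equal length.
#' @return The LOD score (>= 0).
#' @export
independence_lod <- function(a, b) {
  ok <- a != "--" & b != "--"
  if (sum(ok) < 2) return(0)
  tab <- table(a[ok], b[ok])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  o <- as.vector(tab); e <- as.vector(e)
  g <- 2 * sum(ifelse(o > 0, o * log(o / e), 0))
  max(g, 0) / (2 * log(10))
}

#' Pairwise independence LOD matrix
#'
#' @param markers A `cp_markers` object.
#' @return Symmetric matrix of LOD scores (diagonal 0).
#' @export
pairwise_lod <- function(markers) {
  ci <- .codes_int(markers)
  m <- pairwise_lod_cpp(ci, length(attr(ci, "levels")))
  dimnames(m) <- list(markers$info$marker_id, markers$info$marker_id)
  m
}

#' Group markers by independence LOD
#'
#' Single-linkage transitive closure over marker pairs whose
#' independence LOD is at or above the threshold. The published
#' thresholds are 20 for the framework map and 30 for the final map
#' (both with 217 individuals; scale the threshold to the family size,
#' since the maximal LOD between perfectly associated 1:1 markers is
#' about 0.3 x n).
#'
#' @param markers A `cp_markers` object.
#' @param lod_threshold Grouping threshold (> 0).
#' @return List with `groups` (list of marker-ID vectors, each sorted,
#'   ordered by first member; size >= 2) and `singletons`.
#' @export
group_markers <- function(markers, lod_threshold = 30) {
  stopifnot(lod_threshold > 0)
  lod <- pairwise_lod(markers)
  adj <- lod >= lod_threshold
  diag(adj) <- FALSE
  comp <- .components(adj)
  ids <- markers$info$marker_id
  parts <- lapply(split(ids, comp), sort)
  sizes <- lengths(parts)
  groups <- parts[sizes >= 2]
  groups <- groups[order(vapply(groups, `[`, character(1), 1))]
  names(groups) <- NULL
  list(groups = groups,
       singletons = sort(unlist(parts[sizes == 1], use.names = FALSE)))
}

#' Two-point recombination fraction
#'
#' Direct-count estimate over unambiguous meioses for a pair of markers
#' informative in a common parent. For two 1:1 markers (lm x ll with
#' lm x ll, or nn x np with nn x np) the discordance fraction of the
#' shared scored individuals estimates r up to phase, so
#' `min(d, 1 - d)` is returned. For hk x hk pairs only the doubly
#' homozygous individuals are unambiguous; the opposite-homozygote
#' fraction f estimates `r^2 / (r^2 + (1-r)^2)` under coupling, which
#' is inverted to r (then folded for phase).
#'
#' @param a,b Code vectors.
#' @param type_a,type_b Segregation types of the two markers.
#' @return List with `rf`, `n_informative` and `lod`
#'   (the independence LOD of the pair).
#' @export
two_point_rf <- function(a, b, type_a, type_b) {
  if (type_a != type_b || !type_a %in% c("lmxll", "nnxnp", "hkxhk"))
    stop("two-point rf requires a pair informative in a common parent (",
         type_a, " vs ", type_b, ")", call. = FALSE)
  if (type_a %in% c("lmxll", "nnxnp")) {
    ok <- a != "--" & b != "--"
    n <- sum(ok)
    if (n == 0) stop("no shared informative meioses", call. = FALSE)
    d <- mean(a[ok] != b[ok])
    rf <- min(d, 1 - d)
  } else {
    hom <- c("hh", "kk")
    ok <- a %in% hom & b %in% hom
    n <- sum(ok)
    if (n == 0) stop("no shared informative meioses", call. = FALSE)
    f <- mean(a[ok] != b[ok])
    if (f >= 1) f <- 1 - 1e-9
    s <- sqrt(f / (1 - f))
    r <- s / (1 + s)
    rf <- min(r, 1 - r)
  }
  list(rf = rf, n_informative = n, lod = independence_lod(a, b))
}

#' Kosambi map distance
#'
#' `d = 25 ln((1 + 2r) / (1 - 2r))` centimorgans, the map function
#' allowing partial crossover interference.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Distance(s) in cM.
#' @export
kosambi_cM <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must be in [0, 0.5)", call. = FALSE)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cM
#' @param d_cM Map distance(s) in cM.
#' @return `inverse_kosambi()` returns the recombination fraction.
#' @export
inverse_kosambi <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  0.5 * tanh(d_cM / 50)
}

#' Map length of an ordered marker sequence
#'
#' Sum of Kosambi distances over adjacent two-point recombination
#' fractions for a given order.
#'
#' @param order Character vector of marker IDs in map order.
#' @param markers A `cp_markers` containing them.
#' @return Length in cM (0 for a single marker).
#' @export
map_length <- function(order, markers) {
  i <- match(order, markers$info$marker_id)
  if (anyNA(i))
    stop("marker absent from table: ", order[which(is.na(i))[1]],
         call. = FALSE)
  if (length(i) < 2) return(0)
  total <- 0
  for (k in seq_len(length(i) - 1)) {
    a <- i[k]; b <- i[k + 1]
    tp <- tryCatch(
      two_point_rf(markers$codes[a, ], markers$codes[b, ],
                   markers$info$seg_type[a], markers$info$seg_type[b]),
      error = function(e)
        stop("adjacent pair ", order[k], " / ", order[k + 1],
             " has no defined rf: ", conditionMessage(e), call. = FALSE))
    r <- min(tp$rf, 0.5 - 1e-9)
    total <- total + kosambi_cM(r)
  }
  total
}

#' Map-inflation ratio between two orderings of one group
#'
#' Ratio of the maximum-likelihood map length to the (round two)
#' regression map length for the same linkage group; values near 1
#' indicate a clean map, values far above 1 indicate inflation from
#' genotyping errors, missing data or collapsed paralogs.
#'
#' @param map_ml,map_reg Data frames with `marker_id` and
#'   `position_cM` (as exported by external mapping software), or bare
#'   numeric lengths in cM.
#' @return `length(ml) / length(reg)`.
#' @export
inflation_ratio <- function(map_ml, map_reg) {
  len <- function(m) {
    if (is.numeric(m) && length(m) == 1) return(m)
    stopifnot(is.data.frame(m), "position_cM" %in% names(m))
    max(m$position_cM) - min(m$position_cM)
  }
  l_reg <- len(map_reg)
  if (l_reg <= 0) stop("zero-length regression map", call. = FALSE)
  len(map_ml) / l_reg
}

#' Framework-order concordance of a map
#'
#' Restricts the map order to the framework markers and scores
#' `1 - inversions / choose(n, 2)` against the fixed framework order:
#' 1 when the fixed order is fully preserved (regardless of interleaved
#' SNP markers), 0 when fully reversed.
#'
#' @param map_order Character vector: the map's marker IDs in order.
#' @param framework_order Character vector: the fixed framework order.
#' @return Concordance in `[0, 1]`.
#' @export
order_concordance <- function(map_order, framework_order) {
  sub <- map_order[map_order %in% framework_order]
  n <- length(sub)
  if (n < 2)
    stop("fewer than 2 shared framework markers; concordance undefined",
         call. = FALSE)
  pos <- match(sub, framework_order)
  inv <- 0L
  for (i in seq_len(n - 1))
    inv <- inv + sum(pos[i] > pos[(i + 1):n])
  1 - inv / choose(n, 2)
}

#' Per-linkage-group map summary
#'
#' One row per group: locus count, framework (EST-SSR) marker count,
#' map length, and marker spacing in cM per marker
#' (`length / n_loci`, truncated to 2 decimals -- the convention of the
#' published summary table), plus a totals row summing counts and
#' lengths.
#'
#' @param maps Data frame with `group`, `marker_id`, `position_cM`.
#' @param framework_ids Marker IDs counted as framework EST-SSRs.
#' @return A `data.frame` with one row per group and a `Total` row.
#' @export
summarize_map <- function(maps, framework_ids = character(0)) {
  stopifnot(all(c("group", "marker_id", "position_cM") %in% names(maps)))
  rows <- lapply(split(maps, maps$group), function(m) {
    len <- max(m$position_cM) - min(m$position_cM)
    data.frame(group = m$group[1], n_loci = nrow(m),
               n_est_ssr = sum(m$marker_id %in% framework_ids),
               length_cM = len,
               spacing = trunc(100 * len / nrow(m)) / 100,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  total <- data.frame(group = "Total", n_loci = sum(out$n_loci),
                      n_est_ssr = sum(out$n_est_ssr),
                      length_cM = sum(out$length_cM), spacing = NA_real_,
                      stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Totals and spacing for a per-group summary table
#'
#' Bookkeeping on an already-summarized per-linkage-group table (loci,
#' framework SSR and length columns): recomputes the spacing column
#' (cM per marker, truncated to 2 decimals) and appends the totals row.
#'
#' @param lg Data frame with `n_loci`, `n_est_ssr`, `length_cM` (one
#'   row per linkage group).
#' @return The table with `spacing` recomputed and a `Total` row.
#' @export
lg_summary_totals <- function(lg) {
  stopifnot(all(c("n_loci", "n_est_ssr", "length_cM") %in% names(lg)))
  lg$spacing <- trunc(100 * lg$length_cM / lg$n_loci) / 100
  total <- lg[1, ]
  total[1, ] <- NA
  if ("group" %in% names(lg)) total$group <- "Total"
  total$n_loci <- sum(lg$n_loci)
  total$n_est_ssr <- sum(lg$n_est_ssr)
  total$length_cM <- sum(lg$length_cM)
  total$spacing <- NA_real_
  out <- rbind(lg, total)
  rownames(out) <- NULL
  out
}

#' Published red-oak map summary (printed per-group values)
#'
#' The per-linkage-group locus counts, framework EST-SSR counts, map
#' lengths and printed marker-spacing values of the reference red-oak
#' (Quercus rubra) ddRADseq map, shipped as a plain-text table for
#' bookkeeping checks.
#'
#' @return Data frame with `group`, `n_loci`, `n_est_ssr`, `length_cM`,
#'   `density_printed`.
#' @export
qrubra_map_summary <- function() {
  read.delim(system.file("extdata", "qrubra_map_summary.tsv",
                         package = "raddmap"),
             stringsAsFactors = FALSE)
}
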