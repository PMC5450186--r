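#' Parameters for the minimal pileup genotyper
#'
#' @param min_depth Minimum reads for a genotype call (default 5;
#'   shallower samples are set missing).
#' @param het_min_fraction Minimum minor-allele read fraction to call a
#'   heterozygote (default 0.2, tolerant at ~15x progeny depth while
#'   suppressing error bases).
#' @return A validated `caller_params` list.
#' @export
caller_params <- function(min_depth = 5L, het_min_fraction = 0.2) {
  stopifnot(min_depth >= 1,
            het_min_fraction > 0, het_min_fraction <= 0.5)
  structure(list(min_depth = as.integer(min_depth),
                 het_min_fraction = het_min_fraction),
            class = "caller_params")
}

#' Biallelic SNP sites from a read pileup
#'
#' Genotypes every sample at every reference position from the reads
#' assigned to each allele (reads are restriction-anchored, so read
#' position i is reference position i). Per sample: missing below
#' `min_depth`; heterozygous when the second base reaches
#' `het_min_fraction` of the sample depth; otherwise homozygous for the
#' majority base. A position becomes a site when exactly two bases occur
#' across the called genotypes; positions with three or more are dropped
#' and counted as triallelic.
#'
#' @param reads Read table with `individual_id` and `bases`.
#' @param alleles `ref_alleles` table (the retained reference).
#' @param assignments Integer vector from [assign_reads()] (computed
#'   here when NULL).
#' @param params [caller_params()].
#' @param samples Sample ordering; defaults to sorted unique
#'   `individual_id`.
#' @param dnr [dnr_params()] used if `assignments` is NULL.
#' @return A `variant_sites` object: `$sites` (site table with
#'   `site_id`, `allele_id`, `position`, `ref`, `alt`), `$gt`
#'   (site x sample alternate-allele dosage, NA = missing), `$dp`
#'   (site x sample read depth), `$samples`, `$n_triallelic`.
#' @export
pileup_call <- function(reads, alleles, assignments = NULL,
                        params = caller_params(), samples = NULL,
                        dnr = dnr_params()) {
  if (is.null(assignments)) assignments <- assign_reads(reads, alleles, dnr)
  if (is.null(samples)) samples <- sort(unique(reads$individual_id))
  smp <- match(reads$individual_id, samples)
  stopifnot(!anyNA(smp))
  res <- pileup_call_cpp(reads$bases, assignments, smp,
                         nrow(alleles), length(samples),
                         nchar(alleles$sequence),
                         params$min_depth, params$het_min_fraction)
  ns <- length(res$allele)
  gt <- matrix(c(NA_integer_, 0L, 1L, 2L)[res$gt + 1L], nrow = ns)
  dp <- res$dp
  sites <- data.frame(
    site_id = if (ns) paste0(alleles$allele_id[res$allele], "_", res$pos)
              else character(0),
    allele_id = alleles$allele_id[res$allele],
    position = res$pos,
    ref = res$ref, alt = res$alt,
    stringsAsFactors = FALSE)
  dimnames(gt) <- dimnames(dp) <- list(sites$site_id, samples)
  variant_sites(sites, gt, dp, n_triallelic = res$n_triallelic)
}

#' Container for biallelic variant sites
#'
#' @param sites Site table (`site_id`, `allele_id`, `position`, `ref`,
#'   `alt`); positions are 1-based within the reference sequence.
#' @param gt Integer matrix of alternate-allele dosages (0/1/2, NA
#'   missing), sites x samples.
#' @param dp Optional integer matrix of read depths, same shape.
#' @param n_triallelic Count of positions dropped as triallelic.
#' @return A `variant_sites` object.
#' @export
variant_sites <- function(sites, gt, dp = NULL, n_triallelic = 0L) {
  stopifnot(nrow(sites) == nrow(gt), all(sites$position >= 1))
  structure(list(sites = sites, gt = gt, dp = dp,
                 samples = colnames(gt),
                 n_triallelic = as.integer(n_triallelic)),
            class = "variant_sites")
}

#' @export
print.variant_sites <- function(x, ...) {
  cat(sprintf("variant_sites: %d biallelic sites x %d samples (%d triallelic dropped)\n",
              nrow(x$sites), length(x$samples), x$n_triallelic))
  invisible(x)
}

#' Import biallelic SNPs from a VCF
#'
#' Reads a VCF (plain or bgzipped) with [vcfR::read.vcfR()], keeps
#' biallelic SNP records only (others are skipped and counted), and
#' converts genotypes to alternate-allele dosage. CHROM becomes the
#' reference allele ID and POS the 1-based position.
#'
#' @param path VCF path.
#' @param parents Character vector of the two parent sample names; both
#'   must be present in the VCF.
#' @return A `variant_sites` object (parents first in the sample order),
#'   with skipped-record count in `$n_skipped`.
#' @export
read_vcf <- function(path, parents = c("P1", "P2")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_raw)
  missing_parents <- setdiff(parents, samples)
  if (length(missing_parents))
    stop("parent sample(s) missing from VCF: ",
         paste(missing_parents, collapse = ", "), call. = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt)
  n_skipped <- sum(!snp)
  gt_raw <- gt_raw[snp, , drop = FALSE]
  dose <- function(g) {
    g <- sub("\\|", "/", g)
    ifelse(is.na(g) | g %in% c("./.", "."), NA_integer_,
           ifelse(g == "0/0", 0L, ifelse(g %in% c("0/1", "1/0"), 1L,
                  ifelse(g == "1/1", 2L, NA_integer_))))
  }
  gt <- apply(gt_raw, 2, dose)
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = sum(snp),
                                   dimnames = list(NULL, samples))
  ord <- c(parents, setdiff(samples, parents))
  gt <- gt[, ord, drop = FALSE]
  sites <- data.frame(
    site_id = paste0(fix[snp, "CHROM"], "_", fix[snp, "POS"]),
    allele_id = fix[snp, "CHROM"],
    position = as.integer(fix[snp, "POS"]),
    ref = ref[snp], alt = alt[snp], stringsAsFactors = FALSE)
  rownames(gt) <- sites$site_id
  out <- variant_sites(sites, gt)
  out$n_skipped <- n_skipped
  out
}

#' Export variant sites as VCF
#'
#' Writes a minimal VCF 4.2 with GT (and DP when present) fields via
#' [vcfR::write.vcf()]; the output is bgzipped (`.vcf.gz`).
#'
#' @param x `variant_sites`.
#' @param path Output path (conventionally ending in `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  ns <- nrow(x$sites)
  fix <- cbind(CHROM = x$sites$allele_id,
               POS = as.character(x$sites$position),
               ID = x$sites$site_id, REF = x$sites$ref,
               ALT = x$sites$alt, QUAL = rep(".", ns),
               FILTER = rep("PASS", ns), INFO = rep(".", ns))
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[x$gt + 1L], nrow = ns)
  gt_chr[is.na(x$gt)] <- "./."
  if (!is.null(x$dp)) {
    gt_chr <- matrix(paste0(gt_chr, ":", x$dp), nrow = ns)
    fmt <- "GT:DP"
  } else fmt <- "GT"
  gt <- cbind(FORMAT = rep(fmt, ns), gt_chr)
  colnames(gt) <- c("FORMAT", x$samples)
  v <- new("vcfR",
           meta = c("##fileformat=VCFv4.2",
                    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                    if (!is.null(x$dp))
                      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"),
           fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Classify a parental genotype pair into a CP segregation type
#'
#' The five configurations informative for mapping in the F1 of two
#' outcrossing parents: het x hom gives `lmxll` (heterozygous parent 1)
#' or `nnxnp` (heterozygous parent 2); het x het with the same two
#' alleles gives `hkxhk`; three distinct alleles `efxeg`; four distinct
#' `abxcd`. Hom x hom is non-informative. For biallelic SNPs only the
#' first three are realizable; `efxeg`/`abxcd` arise for multi-allelic
#' (SSR-type) input.
#'
#' @param parent1_gt,parent2_gt Genotype strings `"A/C"` (any allele
#'   labels); NA or `"./."` is treated as missing.
#' @return The segregation type, or `"non_informative"` with a
#'   `"reason"` attribute (`"parent_missing"` or `"hom_x_hom"`).
#' @export
classify_configuration <- function(parent1_gt, parent2_gt) {
  parse <- function(g) {
    if (is.na(g) || g %in% c("./.", ".", "")) return(NULL)
    a <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (length(a) != 2 || any(a %in% c(".", ""))) return(NULL)
    a
  }
  a1 <- parse(parent1_gt); a2 <- parse(parent2_gt)
  if (is.null(a1) || is.null(a2))
    return(structure("non_informative", reason = "parent_missing"))
  h1 <- a1[1] != a1[2]; h2 <- a2[1] != a2[2]
  if (!h1 && !h2) return(structure("non_informative", reason = "hom_x_hom"))
  if (h1 && !h2) return("lmxll")
  if (!h1 && h2) return("nnxnp")
  if (setequal(a1, a2)) return("hkxhk")
  if (length(intersect(a1, a2)) == 1) return("efxeg")
  "abxcd"
}

#' Legal JoinMap codes per CP segregation type
#'
#' @param seg_type One of `lmxll`, `nnxnp`, `hkxhk`, `efxeg`, `abxcd`.
#' @return Character vector of legal progeny codes (excluding `"--"`).
#' @export
legal_cp_codes <- function(seg_type) {
  switch(seg_type,
         lmxll = c("ll", "lm"),
         nnxnp = c("nn", "np"),
         hkxhk = c("hh", "hk", "kk"),
         efxeg = c("ee", "ef", "eg", "fg"),
         abxcd = c("ac", "ad", "bc", "bd"),
         stop("unknown segregation type: ", seg_type, call. = FALSE))
}

#' Encode progeny genotypes as JoinMap CP codes
#'
#' Maps each progeny genotype to its code under the parental
#' configuration. Progeny genotypes impossible under the parents (e.g.
#' alternate homozygotes under lm x ll) are set to `"--"` and counted as
#' Mendelian inconsistencies rather than raising an error; a marker with
#' systematic problems is caught later by the chi-square screen. Phase
#' is never inferred.
#'
#' @param parent1_gt,parent2_gt Parental genotype strings `"X/Y"`.
#' @param progeny_gts Character vector of progeny genotype strings.
#' @return List with `seg_type`, `codes` (one per progeny, `"--"` for
#'   missing or inconsistent) and `mendel_inconsistencies`.
#' @export
encode_cp <- function(parent1_gt, parent2_gt, progeny_gts) {
  seg <- classify_configuration(parent1_gt, parent2_gt)
  if (seg == "non_informative")
    stop("parental pair is not CP-informative (",
         attr(seg, "reason"), ")", call. = FALSE)
  a1 <- sort(strsplit(parent1_gt, "/", fixed = TRUE)[[1]])
  a2 <- sort(strsplit(parent2_gt, "/", fixed = TRUE)[[1]])
  key <- function(x, y) paste(sort(c(x, y)), collapse = "/")
  map <- switch(seg,
    lmxll = {
      l <- a2[1]; m <- setdiff(a1, l)
      if (length(m) != 1)
        stop("het x hom pair without a shared allele is not CP-codable",
             call. = FALSE)
      setNames(c("ll", "lm"), c(key(l, l), key(l, m)))
    },
    nnxnp = {
      n <- a1[1]; p <- setdiff(a2, n)
      if (length(p) != 1)
        stop("het x hom pair without a shared allele is not CP-codable",
             call. = FALSE)
      setNames(c("nn", "np"), c(key(n, n), key(n, p)))
    },
    hkxhk = {
      h <- a1[1]; k <- a1[2]
      setNames(c("hh", "hk", "kk"), c(key(h, h), key(h, k), key(k, k)))
    },
    efxeg = {
      e <- intersect(a1, a2); f <- setdiff(a1, e); g <- setdiff(a2, e)
      setNames(c("ee", "ef", "eg", "fg"),
               c(key(e, e), key(e, f), key(e, g), key(f, g)))
    },
    abxcd = {
      a <- a1[1]; b <- a1[2]; c_ <- a2[1]; d <- a2[2]
      setNames(c("ac", "ad", "bc", "bd"),
               c(key(a, c_), key(a, d), key(b, c_), key(b, d)))
    })
  norm <- vapply(progeny_gts, function(g) {
    if (is.na(g) || g %in% c("./.", ".", "")) return(NA_character_)
    p <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (length(p) != 2 || any(p %in% c(".", ""))) return(NA_character_)
    paste(sort(p), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
  codes <- unname(map[norm])
  inconsistent <- !is.na(norm) & is.na(codes)
  codes[is.na(codes)] <- "--"
  list(seg_type = seg, codes = codes,
       mendel_inconsistencies = sum(inconsistent))
}

#' Construct a CP marker set
#'
#' @param info Data frame with `marker_id`, `seg_type` and optionally
#'   `allele_id`, `position` (source sequence and 1-based SNP offset).
#' @param codes Character matrix of progeny codes (markers x
#'   individuals, `"--"` for missing); every code must be legal for its
#'   marker's segregation type.
#' @return A `cp_markers` object.
#' @export
cp_markers <- function(info, codes) {
  stopifnot(is.data.frame(info), nrow(info) == nrow(codes),
            all(c("marker_id", "seg_type") %in% names(info)),
            !anyDuplicated(info$marker_id))
  if (!"allele_id" %in% names(info)) info$allele_id <- info$marker_id
  if (!"position" %in% names(info))
    info$position <- rep(NA_integer_, nrow(info))
  for (t in unique(info$seg_type)) {
    legal <- c(legal_cp_codes(t), "--")
    bad <- codes[info$seg_type == t, , drop = FALSE]
    bad <- setdiff(unique(as.vector(bad)), legal)
    if (length(bad))
      stop("illegal ", t, " code(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  rownames(codes) <- info$marker_id
  structure(list(info = info, codes = codes),
            class = "cp_markers")
}

#' @export
print.cp_markers <- function(x, ...) {
  tt <- table(x$info$seg_type)
  cat(sprintf("cp_markers: %d markers x %d individuals (%s)\n",
              nrow(x$info), ncol(x$codes),
              paste(names(tt), tt, sep = ":", collapse = ", ")))
  invisible(x)
}

#' @export
`[.cp_markers` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$info))
  if (missing(j)) j <- seq_len(ncol(x$codes))
  if (is.character(i)) i <- match(i, x$info$marker_id)
  cp_markers(x$info[i, , drop = FALSE],
             x$codes[i, j, drop = FALSE])
}

#' CP markers from called variant sites
#'
#' Classifies every biallelic site by its parental genotypes and encodes
#' the informative ones as JoinMap CP markers. Sites with a missing
#' parent genotype or a hom x hom configuration are dropped and counted.
#'
#' @param x `variant_sites`.
#' @param parents The two parent sample names (parent 1 first).
#' @return A `cp_markers` object over the non-parent samples, with
#'   counts in `attr(, "n_non_informative")` and
#'   `attr(, "mendel_inconsistencies")`.
#' @export
markers_from_sites <- function(x, parents = c("P1", "P2")) {
  stopifnot(inherits(x, "variant_sites"),
            all(parents %in% x$samples))
  prog <- setdiff(x$samples, parents)
  g1 <- x$gt[, parents[1]]
  g2 <- x$gt[, parents[2]]
  pg <- x$gt[, prog, drop = FALSE]
  seg <- rep(NA_character_, nrow(x$sites))
  ok1 <- !is.na(g1) & !is.na(g2)
  seg[ok1 & g1 == 1 & g2 != 1] <- "lmxll"
  seg[ok1 & g1 != 1 & g2 == 1] <- "nnxnp"
  seg[ok1 & g1 == 1 & g2 == 1] <- "hkxhk"
  keep <- which(!is.na(seg))
  n_mendel <- 0L
  codes <- matrix("--", length(keep), length(prog),
                  dimnames = list(x$sites$site_id[keep], prog))
  for (r in seq_along(keep)) {
    i <- keep[r]
    d <- pg[i, ]
    cc <- switch(seg[i],
      lmxll = {
        # l is parent 2's homozygous allele
        lookup <- if (g2[i] == 0) c("ll", "lm", NA) else c(NA, "lm", "ll")
        lookup[d + 1L]
      },
      nnxnp = {
        lookup <- if (g1[i] == 0) c("nn", "np", NA) else c(NA, "np", "nn")
        lookup[d + 1L]
      },
      hkxhk = c("hh", "hk", "kk")[d + 1L])
    n_mendel <- n_mendel + sum(!is.na(d) & is.na(cc))
    cc[is.na(cc)] <- "--"
    codes[r, ] <- cc
  }
  info <- data.frame(marker_id = x$sites$site_id[keep],
                     seg_type = seg[keep],
                     allele_id = x$sites$allele_id[keep],
                     position = x$sites$position[keep],
                     stringsAsFactors = FALSE)
  tab <- table(info$allele_id)
  info$n_snps_sequence <- as.integer(tab[info$allele_id])
  out <- cp_markers(info, codes)
  attr(out, "n_non_informative") <- nrow(x$sites) - length(keep)
  attr(out, "mendel_inconsistencies") <- n_mendel
  out
}
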