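# shared fixtures, built once per test run

.fix <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fix)) assign(name, force(expr), envir = .fix)
  get(name, envir = .fix)
}

# pooled per-locus depth of a design, and support bounds scaled to it
pooled_depth <- function(cfg) {
  2 * cfg$depth_parent + cfg$n_progeny * cfg$depth_progeny
}

scaled_dnr <- function(cfg) {
  D <- pooled_depth(cfg)
  dnr_params(min_support = ceiling(0.02 * D), max_support = 4 * D)
}

small_config <- function() {
  sim_config(n_chromosomes = 3, n_loci = 60, n_progeny = 20,
             depth_parent = 40, depth_progeny = 12, error_rate = 0.005,
             het_rate = 0.6,
             repeat_families = list(list(copies = 3, divergence = 0.02)),
             chrom_length_cM = 80, seed = 101)
}

small_family <- function() fixture("small_family", simulate_family(small_config()))

small_pipeline <- function() fixture("small_pipeline", {
  fam <- small_family()
  run_pipeline(fam$reads, dnr = scaled_dnr(small_config()))
})

# study-condition simulation: 500 single-copy loci, 50 progeny,
# 248x parents / 15x progeny, 0.5% error, plus repeat families and the
# plastid-like sequence
acc_config <- function() {
  sim_config(n_loci = 500, n_progeny = 50, depth_parent = 248,
             depth_progeny = 15, error_rate = 0.005, het_rate = 0.3,
             repeat_families = list(list(copies = 3, divergence = 0.02),
                                    list(copies = 2, divergence = 0.02)),
             chrom_length_cM = 100, seed = 42)
}

acc_family <- function() fixture("acc_family", simulate_family(acc_config()))

acc_pipeline <- function() fixture("acc_pipeline",
  run_pipeline(acc_family()$reads, dnr = scaled_dnr(acc_config())))

# fraction of informative single-copy loci whose SNP genotypes are
# recovered, per progeny, against the simulation truth (missing or
# uncalled counts as wrong; the denominator is every informative locus)
genotype_recovery <- function(fam, res) {
  truth <- fam$truth
  inf <- which(truth$loci$copy_class == "single" &
                 (truth$loci$p1_het | truth$loci$p2_het))
  prog <- truth$progeny_ids
  tg <- truth_genotypes(truth)
  pref <- substr(truth$haps[inf, 1], 1, 101)
  hit <- assign_reads(pref, res$reference)
  total <- length(inf) * length(prog)
  correct <- 0L
  for (j in seq_along(inf)) {
    l <- inf[j]
    if (is.na(hit[j])) next
    aid <- res$reference$allele_id[hit[j]]
    srow <- which(res$sites$sites$allele_id == aid &
                    res$sites$sites$position == truth$loci$snp_pos[l])
    if (length(srow) != 1) next
    site <- res$sites$sites[srow, ]
    if (!setequal(c(site$ref, site$alt),
                  c(truth$loci$ref_base[l], truth$loci$alt_base[l]))) next
    d_called <- res$sites$gt[srow, prog]
    d_truth <- tg[l, prog]
    if (site$ref != truth$loci$ref_base[l]) d_called <- 2L - d_called
    correct <- correct + sum(!is.na(d_called) & d_called == d_truth)
  }
  correct / total
}

# retained reference rows onto which reads from more than one distinct
# true locus collapse (the paralog-collapse alleles)
collapsed_allele_ids <- function(fam, res) {
  truth <- fam$truth
  win <- substr(truth$haps[, 1], 1, 101)
  keep <- !duplicated(win)
  hit <- assign_reads(win[keep], res$reference)
  locus <- truth$loci$locus_id[keep]
  ok <- !is.na(hit)
  tab <- tapply(locus[ok], hit[ok], function(x) length(unique(x)))
  res$reference$allele_id[as.integer(names(tab)[tab >= 2])]
}

# a hand-buildable truth skeleton for transmission-only experiments:
# loci at given cM on one chromosome, heterozygosity flags per parent
manual_truth <- function(cfg, cM, p1_het = TRUE, p2_het = FALSE) {
  nl <- length(cM)
  seqs <- vapply(seq_len(nl), function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""),
    character(1))
  loci <- data.frame(
    locus_id = sprintf("M%02d", seq_len(nl)), chrom = 1L, cM = cM,
    length_bp = 300L, copy_class = "single", family = NA_integer_,
    snp_pos = 1L, ref_base = substr(seqs, 1, 1), alt_base = "N",
    p1_het = rep(p1_het, length.out = nl),
    p2_het = rep(p2_het, length.out = nl), stringsAsFactors = FALSE)
  haps <- matrix(rep(seqs, 4), ncol = 4,
                 dimnames = list(NULL, c("p1_h1", "p1_h2", "p2_h1", "p2_h2")))
  ac <- matrix(FALSE, nl, 4, dimnames = dimnames(haps))
  ac[loci$p1_het, 2] <- TRUE   # alternate allele on hap 2 of each het parent
  ac[loci$p2_het, 4] <- TRUE
  structure(list(config = cfg, loci = loci, haps = haps, alt_carrier = ac),
            class = "rad_truth")
}

# independent streaming-normalization oracle (plain R, set semantics)
r_dnr_oracle <- function(seqs, k = 15, frac = 0.5) {
  index <- character(0)
  saved <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    km <- unique(substring(seqs[i], 1:(n - k + 1), k:n))
    novel <- sum(!(km %in% index))
    if (novel + 1e-9 >= frac * length(km)) {
      saved[i] <- TRUE
      index <- union(index, km)
    }
  }
  saved
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# cp_markers with constant-ratio codes, for filter unit tests
make_markers <- function(codes_list, seg_types, allele_ids = NULL,
                         positions = NULL) {
  n <- length(codes_list)
  ids <- sprintf("mk%03d", seq_len(n))
  codes <- do.call(rbind, codes_list)
  colnames(codes) <- sprintf("ind%03d", seq_len(ncol(codes)))
  rownames(codes) <- ids
  aid <- if (is.null(allele_ids)) ids else allele_ids
  tab <- table(aid)
  info <- data.frame(marker_id = ids, seg_type = seg_types,
                     allele_id = aid,
                     position = if (is.null(positions)) 50L else positions,
                     n_snps_sequence = as.integer(tab[aid]),
                     stringsAsFactors = FALSE)
  cp_markers(info, codes)
}
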