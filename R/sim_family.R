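#' @title Synthetic outbred F1 family with ground truth
#' @description
#' `simulate_parents()` draws the genomic truth for two heterozygous
#' parents: single-copy restriction loci placed on chromosomes, one
#' candidate segregating site per locus inside the sequenced window,
#' repeat families of near-identical multi-copy loci, and one
#' plastid-like sequence. `simulate_progeny()` transmits haplotypes to
#' the F1 with Poisson (no-interference) crossovers. `emit_reads()`
#' produces restriction-anchored single-end reads with per-base error.
#' `simulate_family()` chains the three.
#'
#' Each stage reseeds deterministically from `config$seed` (seed,
#' seed + 1, seed + 2), so the same config always yields byte-identical
#' output regardless of which stages are rerun.
#'
#' @param config A [sim_config()] object.
#' @return `simulate_parents()` returns a `rad_truth` object: `$loci`
#'   (locus table with chromosome, cM, copy class, true site and alleles),
#'   `$haps` (locus x 4 haplotype sequences: P1 hap1/2, P2 hap1/2) and
#'   `$alt_carrier` (which haplotypes carry the alternate allele).
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rf <- config$repeat_families
  n_rep <- if (length(rf)) sum(vapply(rf, function(f) f$copies, 0)) else 0L
  n_mapped <- config$n_loci + n_rep
  nl <- n_mapped + 1L  # + plastid

  chrom <- sort(rep_len(seq_len(config$n_chromosomes), n_mapped))
  cm <- runif(n_mapped, 0, config$chrom_length_cM)
  ord <- order(chrom, cm)
  chrom <- chrom[ord]; cm <- cm[ord]
  # strictly increasing within chromosome (duplicates have measure zero,
  # but guard anyway; a zero-length chromosome degenerates to all-zero
  # positions, where ties are unavoidable and harmless)
  for (c_ in unique(chrom)) {
    i <- which(chrom == c_)
    if (config$chrom_length_cM > 0)
      while (anyDuplicated(cm[i]))
        cm[i] <- runif(length(i), 0, config$chrom_length_cM)
    cm[i] <- sort(cm[i])
  }

  # which mapped slots are repeat copies: take the last n_rep slots of a
  # random permutation so repeats land at arbitrary genomic positions
  slot_perm <- sample.int(n_mapped)
  rep_slots <- if (n_rep > 0) slot_perm[seq_len(n_rep)] else integer(0)

  copy_class <- rep("single", nl)
  family <- rep(NA_integer_, nl)
  len_bp <- sample(seq(config$locus_length_bp[1], config$locus_length_bp[2]),
                   nl, replace = TRUE)
  seqs <- vapply(len_bp, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))

  if (n_rep > 0) {
    # divergence between copies is applied inside the sequenced window
    # (the only part ddRAD observes), as an exact per-copy substitution
    # count so a family's collapse signature is well defined
    k <- 1L
    for (fi in seq_along(rf)) {
      fam <- rf[[fi]]
      base <- seqs[[rep_slots[k]]]
      k_div <- max(1L, as.integer(round(fam$divergence * config$read_length_bp)))
      for (ci in seq_len(fam$copies)) {
        slot <- rep_slots[k]
        copy_class[slot] <- "repeat"
        family[slot] <- fi
        len_bp[slot] <- nchar(base)
        s <- base
        if (ci > 1) {
          at <- sample.int(config$read_length_bp, k_div)
          for (p in at) {
            b <- substr(s, p, p)
            substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }
        }
        seqs[slot] <- s
        k <- k + 1L
      }
    }
  }
  copy_class[nl] <- "plastid"
  chrom <- c(chrom, NA_integer_); cm <- c(cm, NA_real_)

  # one candidate site per single-copy locus, inside the sequenced window
  snp_pos <- ifelse(copy_class == "single",
                    sample.int(config$read_length_bp, nl, replace = TRUE),
                    NA_integer_)
  ref_base <- ifelse(is.na(snp_pos), NA_character_,
                     substr(seqs, snp_pos, snp_pos))
  alt_base <- vapply(ref_base, function(b) {
    if (is.na(b)) return(NA_character_)
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1), USE.NAMES = FALSE)
  p1_het <- copy_class == "single" & runif(nl) < config$het_rate
  p2_het <- copy_class == "single" & runif(nl) < config$het_rate

  haps <- matrix(rep(seqs, 4), ncol = 4,
                 dimnames = list(NULL, c("p1_h1", "p1_h2", "p2_h1", "p2_h2")))
  alt_carrier <- matrix(FALSE, nl, 4, dimnames = dimnames(haps))
  put_alt <- function(s, pos, alt) {
    substr(s, pos, pos) <- alt
    s
  }
  for (l in which(p1_het | p2_het)) {
    if (p1_het[l]) {
      h <- sample(1:2, 1)
      haps[l, h] <- put_alt(haps[l, h], snp_pos[l], alt_base[l])
      alt_carrier[l, h] <- TRUE
    }
    if (p2_het[l]) {
      h <- 2L + sample(1:2, 1)
      haps[l, h] <- put_alt(haps[l, h], snp_pos[l], alt_base[l])
      alt_carrier[l, h] <- TRUE
    }
  }

  locus_id <- c(sprintf("L%04d", seq_len(n_mapped)), "PLASTID")
  loci <- data.frame(
    locus_id = locus_id, chrom = chrom, cM = cm, length_bp = len_bp,
    copy_class = copy_class, family = family, snp_pos = snp_pos,
    ref_base = ref_base, alt_base = alt_base,
    p1_het = p1_het, p2_het = p2_het, stringsAsFactors = FALSE)
  structure(list(config = config, loci = loci, haps = haps,
                 alt_carrier = alt_carrier),
            class = "rad_truth")
}

#' @rdname simulate_parents
#' @param truth A `rad_truth` object from [simulate_parents()].
#' @return `simulate_progeny()` returns the truth with `$inherit_p1` and
#'   `$inherit_p2` (locus x progeny haplotype labels in `{1, 2}`) and
#'   `$progeny_ids` added. Unplaced (plastid-like) loci are transmitted
#'   uniparentally as haplotype 1.
#' @export
simulate_progeny <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "rad_truth"))
  set.seed(config$seed + 1L)
  loci <- truth$loci
  nl <- nrow(loci)
  np <- config$n_progeny
  inh1 <- matrix(1L, nl, np)
  inh2 <- matrix(1L, nl, np)
  chroms <- unique(loci$chrom[!is.na(loci$chrom)])
  len_M <- config$chrom_length_cM / 100  # Morgans
  for (p in seq_len(np)) {
    for (par in 1:2) {
      for (c_ in chroms) {
        i <- which(!is.na(loci$chrom) & loci$chrom == c_)
        start <- sample(1:2, 1)
        nx <- rpois(1, len_M)
        hap <- rep(start, length(i))
        if (nx > 0) {
          xpos <- sort(runif(nx, 0, config$chrom_length_cM))
          flips <- vapply(loci$cM[i], function(p_) sum(xpos < p_), 0)
          hap <- 1L + (start - 1L + flips) %% 2L
        }
        if (par == 1) inh1[i, p] <- hap else inh2[i, p] <- hap
      }
    }
  }
  truth$inherit_p1 <- inh1
  truth$inherit_p2 <- inh2
  truth$progeny_ids <- sprintf("F%03d", seq_len(np))
  truth
}

#' @rdname simulate_parents
#' @param out_dir Optional directory; when given, per-individual FASTQ
#'   files and a pooled lane FASTQ (index tag in the Illumina-style
#'   header comment) are written there.
#' @return `emit_reads()` returns a data frame of reads (`read_id`,
#'   `individual_id`, `locus_id`, `bases`, `qualities`, `index_tag`),
#'   invisibly carrying the file paths in `attr(, "files")` when
#'   `out_dir` is used.
#' @export
emit_reads <- function(truth, config = truth$config, out_dir = NULL) {
  stopifnot(inherits(truth, "rad_truth"), !is.null(truth$inherit_p1))
  set.seed(config$seed + 2L)
  loci <- truth$loci
  nl <- nrow(loci)
  rl <- config$read_length_bp
  prefix <- substr(truth$haps, 1L, rl)
  dim(prefix) <- dim(truth$haps)
  individuals <- c("P1", "P2", truth$progeny_ids)
  tags <- index_tags(length(individuals))
  names(tags) <- individuals
  depth_mult <- ifelse(loci$copy_class == "plastid",
                       config$plastid_copy_factor, 1)
  out <- vector("list", length(individuals))
  for (ii in seq_along(individuals)) {
    ind <- individuals[ii]
    lambda <- depth_mult *
      if (ind %in% c("P1", "P2")) config$depth_parent else config$depth_progeny
    counts <- rpois(nl, lambda)
    locus_r <- rep.int(seq_len(nl), counts)
    nr <- length(locus_r)
    if (ind == "P1") {
      hap_col <- sample(1:2, nr, replace = TRUE)
    } else if (ind == "P2") {
      hap_col <- 2L + sample(1:2, nr, replace = TRUE)
    } else {
      p <- ii - 2L
      from_p1 <- sample(c(TRUE, FALSE), nr, replace = TRUE)
      hap_col <- ifelse(from_p1, truth$inherit_p1[cbind(locus_r, p)],
                        2L + truth$inherit_p2[cbind(locus_r, p)])
    }
    bases <- as.character(
      perturb_reads_cpp(prefix[cbind(locus_r, hap_col)], config$error_rate))
    out[[ii]] <- data.frame(
      read_id = sprintf("%s:r%06d", ind, seq_len(nr)),
      individual_id = ind,
      locus_id = loci$locus_id[locus_r],
      bases = bases,
      qualities = strrep("I", nchar(bases)),
      index_tag = tags[[ind]],
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  if (!is.null(out_dir)) {
    files <- write_read_set(reads, out_dir)
    attr(reads, "files") <- files
  }
  reads
}

#' @rdname simulate_parents
#' @return `simulate_family()` returns `list(truth =, reads =)`.
#' @export
simulate_family <- function(config, out_dir = NULL) {
  truth <- simulate_progeny(simulate_parents(config), config)
  reads <- emit_reads(truth, config, out_dir = out_dir)
  list(truth = truth, reads = reads)
}

#' Deterministic per-individual index tags
#'
#' Enumerates 6-mer tags in a fixed order so a given number of
#' individuals always receives the same tags.
#'
#' @param n Number of tags needed (at most 4096).
#' @return Character vector of distinct 6-mer tags.
#' @export
index_tags <- function(n) {
  stopifnot(n >= 1, n <= 4096)
  b <- c("A", "C", "G", "T")
  i <- seq_len(n) - 1L
  paste0(b[i %/% 1024 %% 4 + 1], b[i %/% 256 %% 4 + 1],
         b[i %/% 64 %% 4 + 1], b[i %/% 16 %% 4 + 1],
         b[i %/% 4 %% 4 + 1], b[i %% 4 + 1])
}

#' True genotype dosages from a simulated family
#'
#' Alternate-allele dosage (0/1/2) at each single-copy locus for the two
#' parents and every progeny, derived exactly from the inherited
#' haplotype labels. Loci without a segregating site are NA.
#'
#' @param truth A `rad_truth` with progeny simulated.
#' @return Integer matrix, loci x individuals (P1, P2, progeny).
#' @export
truth_genotypes <- function(truth) {
  stopifnot(inherits(truth, "rad_truth"), !is.null(truth$inherit_p1))
  nl <- nrow(truth$loci)
  np <- length(truth$progeny_ids)
  ac <- truth$alt_carrier
  g <- matrix(NA_integer_, nl, 2L + np,
              dimnames = list(truth$loci$locus_id,
                              c("P1", "P2", truth$progeny_ids)))
  single <- truth$loci$copy_class == "single" &
    (truth$loci$p1_het | truth$loci$p2_het)
  g[single, "P1"] <- ac[single, 1] + ac[single, 2]
  g[single, "P2"] <- ac[single, 3] + ac[single, 4]
  for (p in seq_len(np)) {
    i1 <- truth$inherit_p1[, p]
    i2 <- truth$inherit_p2[, p]
    d <- ac[cbind(seq_len(nl), i1)] + ac[cbind(seq_len(nl), 2L + i2)]
    g[single, 2L + p] <- d[single]
  }
  g
}

#' CP marker codes derived directly from simulation truth
#'
#' Bypasses sequencing entirely: converts true dosages at informative
#' single-copy loci into JoinMap CP codes. Useful as the error-free
#' reference point for genotyping and mapping checks.
#'
#' @param truth A `rad_truth` with progeny simulated.
#' @return A [cp_markers] object.
#' @export
truth_marker_codes <- function(truth) {
  g <- truth_genotypes(truth)
  loci <- truth$loci
  inf <- which(loci$copy_class == "single" & (loci$p1_het | loci$p2_het))
  seg <- ifelse(loci$p1_het[inf] & loci$p2_het[inf], "hkxhk",
                ifelse(loci$p1_het[inf], "lmxll", "nnxnp"))
  prog <- g[inf, -(1:2), drop = FALSE]
  codes <- matrix("--", length(inf), ncol(prog),
                  dimnames = list(loci$locus_id[inf], colnames(prog)))
  for (r in seq_along(inf)) {
    codes[r, ] <- switch(seg[r],
      lmxll = c("ll", "lm")[prog[r, ] + 1L],
      nnxnp = c("nn", "np")[prog[r, ] + 1L],
      hkxhk = c("hh", "hk", "kk")[prog[r, ] + 1L])
  }
  cp_markers(
    info = data.frame(marker_id = loci$locus_id[inf], seg_type = seg,
                      allele_id = loci$locus_id[inf],
                      position = loci$snp_pos[inf], stringsAsFactors = FALSE),
    codes = codes)
}
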