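#' Simulation configuration for a synthetic ddRADseq F1 family
#'
#' Bundles and validates every knob of the family simulator: two outbred
#' heterozygous parents, F1 progeny with Mendelian transmission and
#' Poisson (no-interference) crossovers, restriction-anchored single-end
#' reads, repeat families that collapse into multi-SNP loci, and one
#' plastid-like very-high-copy sequence.
#'
#' Depth defaults mirror a design that devotes a full lane to the two
#' parents and multiplexes ~50 progeny per lane: parents at 248 reads per
#' locus, progeny at 15. Restriction fragments are size-selected to
#' 300--500 bp but only a single 101 bp forward read anchored at the
#' restriction site is observed, so segregating sites are placed within
#' the sequenced window (positions 1..`read_length_bp`).
#'
#' @param n_chromosomes Number of chromosomes (haploid number; default 12).
#' @param n_loci Number of single-copy restriction loci.
#' @param locus_length_bp Integer range (min, max) of fragment lengths.
#' @param read_length_bp Read length in bp (default 101).
#' @param n_progeny Number of F1 progeny.
#' @param depth_parent Mean reads per locus per parent (default 248).
#' @param depth_progeny Mean reads per locus per progeny (default 15).
#' @param error_rate Per-base substitution probability, in `[0, 1)`.
#' @param het_rate Probability that a locus is heterozygous in a given
#'   parent (drawn independently per parent; a locus heterozygous in both
#'   parents shares the same site and alleles, i.e. segregates hk x hk).
#' @param repeat_families List of `list(copies =, divergence =)` entries;
#'   each family is a set of near-identical loci placed at distinct
#'   genomic positions (the substrate for paralog collapse).
#' @param plastid_copy_factor Depth multiplier for the plastid-like
#'   sequence (default 20, i.e. hundreds-fold combined support).
#' @param chrom_length_cM Map length of each chromosome in centimorgans.
#' @param seed Integer RNG seed; stage seeds are derived from it, so keep
#'   it below `2^31 - 10`.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_loci = 20, n_progeny = 6, seed = 7)
sim_config <- function(n_chromosomes = 12L, n_loci = 200L,
                       locus_length_bp = c(300L, 500L),
                       read_length_bp = 101L, n_progeny = 50L,
                       depth_parent = 248, depth_progeny = 15,
                       error_rate = 0.005, het_rate = 0.3,
                       repeat_families = list(),
                       plastid_copy_factor = 20,
                       chrom_length_cM = 100, seed = 1L) {
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid sim_config: `", field, "` ", what, call. = FALSE)
  }
  chk(is.numeric(n_chromosomes) && n_chromosomes >= 1, "n_chromosomes",
      "must be a positive count")
  chk(is.numeric(n_loci) && n_loci >= 1, "n_loci", "must be a positive count")
  chk(is.numeric(locus_length_bp) && length(locus_length_bp) == 2 &&
        all(locus_length_bp >= 1) &&
        locus_length_bp[1] <= locus_length_bp[2],
      "locus_length_bp", "must be an increasing positive range")
  chk(is.numeric(read_length_bp) && read_length_bp >= 1, "read_length_bp",
      "must be a positive count")
  chk(read_length_bp <= locus_length_bp[1], "read_length_bp",
      "must not exceed the minimum locus length")
  chk(is.numeric(n_progeny) && n_progeny >= 1, "n_progeny",
      "must be a positive count")
  chk(is.numeric(depth_parent) && depth_parent > 0, "depth_parent",
      "must be positive")
  chk(is.numeric(depth_progeny) && depth_progeny > 0, "depth_progeny",
      "must be positive")
  chk(is.numeric(error_rate) && error_rate >= 0 && error_rate < 1,
      "error_rate", "must be in [0, 1)")
  chk(is.numeric(het_rate) && het_rate >= 0 && het_rate <= 1, "het_rate",
      "must be in [0, 1]")
  chk(is.list(repeat_families), "repeat_families", "must be a list")
  for (f in repeat_families)
    chk(is.list(f) && is.numeric(f$copies) && f$copies >= 2 &&
          is.numeric(f$divergence) && f$divergence >= 0 && f$divergence < 1,
        "repeat_families",
        "entries need copies >= 2 and divergence in [0, 1)")
  chk(is.numeric(plastid_copy_factor) && plastid_copy_factor > 0,
      "plastid_copy_factor", "must be positive")
  chk(is.numeric(chrom_length_cM) && chrom_length_cM >= 0, "chrom_length_cM",
      "must be non-negative")
  chk(is.numeric(seed) && seed == floor(seed) && seed >= 0 &&
        seed < 2^31 - 10, "seed", "must be an integer below 2^31 - 10")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes), n_loci = as.integer(n_loci),
    locus_length_bp = as.integer(locus_length_bp),
    read_length_bp = as.integer(read_length_bp),
    n_progeny = as.integer(n_progeny),
    depth_parent = depth_parent, depth_progeny = depth_progeny,
    error_rate = error_rate, het_rate = het_rate,
    repeat_families = repeat_families,
    plastid_copy_factor = plastid_copy_factor,
    chrom_length_cM = chrom_length_cM, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("ddRADseq family simulation config\n")
  cat(sprintf("  %d loci on %d chromosomes (%g cM each), %d progeny\n",
              x$n_loci, x$n_chromosomes, x$chrom_length_cM, x$n_progeny))
  cat(sprintf("  depth %gx parents / %gx progeny, error %g, het rate %g\n",
              x$depth_parent, x$depth_progeny, x$error_rate, x$het_rate))
  cat(sprintf("  %d repeat famil%s, plastid factor %g, seed %d\n",
              length(x$repeat_families),
              if (length(x$repeat_families) == 1) "y" else "ies",
              x$plastid_copy_factor, x$seed))
  invisible(x)
}
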