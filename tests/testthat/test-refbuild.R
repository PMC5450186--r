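test_that("normalization matches an independent streaming oracle", {
  fam <- small_family()
  set.seed(6)
  seqs <- fam$reads$bases[sample.int(nrow(fam$reads), 300)]
  got <- build_dnr(seqs)
  expect_identical(got$sequence, seqs[r_dnr_oracle(seqs)])
})

test_that("the first read is always saved and exact duplicates never are", {
  set.seed(7)
  a <- random_seq(101)
  out <- build_dnr(c(a, a, a))
  expect_equal(nrow(out), 1L)
  expect_equal(out$sequence, a)
})

test_that("the at-least-half novelty rule sits at the right integer boundary", {
  # a 101 bp read has 87 15-mers; half of 87 rounds up to 44
  set.seed(8)
  repeat {
    a <- random_seq(101)
    s44 <- paste0(substr(a, 1, 57), random_seq(44))  # shares 43 k-mers
    s43 <- paste0(substr(a, 1, 58), random_seq(43))  # shares 44 k-mers
    km <- function(s) substring(s, 1:87, 15:101)
    all_distinct <- function(s) !anyDuplicated(km(s))
    if (all_distinct(a) && all_distinct(s44) && all_distinct(s43) &&
        sum(km(s44) %in% km(a)) == 43 && sum(km(s43) %in% km(a)) == 44)
      break
  }
  expect_equal(nrow(build_dnr(c(a, s44))), 2L)  # 44 novel: saved
  expect_equal(nrow(build_dnr(c(a, s43))), 1L)  # 43 novel: not saved
})

test_that("the k-mer index equals the union of saved-allele k-mers", {
  fam <- small_family()
  set.seed(9)
  seqs <- fam$reads$bases[sample.int(nrow(fam$reads), 400)]
  out <- build_dnr(seqs)
  km <- unique(unlist(lapply(out$sequence,
                             function(s) substring(s, 1:87, 15:101))))
  expect_equal(attr(out, "kmer_index_size"), length(km))
})

test_that("normalization is deterministic and order-canonical", {
  fam <- small_family()
  sub <- fam$reads[fam$reads$locus_id %in%
                     sprintf("L%04d", 1:15), , drop = FALSE]
  a <- build_dnr(sub)
  b <- build_dnr(sub)
  expect_identical(a, b)
  # shuffled input is re-ordered to the canonical stream before saving
  set.seed(10)
  shuf <- sub[sample.int(nrow(sub)), , drop = FALSE]
  expect_identical(build_dnr(shuf), a)
})

test_that("lenient matching honors the mismatch tolerance and prefers exact hits", {
  set.seed(11)
  alleles <- build_dnr(c(random_seq(120), random_seq(120)))
  read <- substr(alleles$sequence[2], 1, 101)
  expect_equal(lenient_match(read, alleles), alleles$allele_id[2])
  i <- assign_reads(read, alleles)
  expect_equal(attr(i, "mismatches")[1], 0L)
  # 9 clustered substitutions exceed the tolerance of 8 but leave
  # intact k-mer seeds (widely spread mismatches would also defeat the
  # seeding, which is the documented matcher limitation)
  bad <- read
  for (p in 1:9) {
    b <- substr(bad, p, p)
    substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  expect_true(is.na(lenient_match(bad, alleles, max_mismatches = 8)))
  expect_equal(lenient_match(bad, alleles, max_mismatches = 9),
               alleles$allele_id[2])
})

test_that("simulated reads assign back to their true source locus", {
  cfg <- sim_config(n_loci = 60, n_progeny = 10, depth_parent = 20,
                    depth_progeny = 8, error_rate = 0.01, het_rate = 0.5,
                    seed = 12)
  fam <- simulate_family(cfg)
  single <- fam$truth$loci$copy_class == "single"
  truth_alleles <- data.frame(
    allele_id = fam$truth$loci$locus_id[single],
    sequence = substr(fam$truth$haps[single, 1], 1, 101),
    stringsAsFactors = FALSE)
  reads <- fam$reads[fam$reads$locus_id %in% truth_alleles$allele_id, ]
  hit <- assign_reads(reads, truth_alleles)
  ok <- !is.na(hit) & truth_alleles$allele_id[hit] == reads$locus_id
  expect_gte(mean(ok), 0.99)
})

test_that("support counting and bounds behave at the documented boundaries", {
  set.seed(13)
  a <- random_seq(101); b <- random_seq(101)
  alleles <- build_dnr(c(a, b))
  alleles <- count_support(c(a, b, b), alleles)
  expect_equal(alleles$support, c(1L, 2L))  # a supports only itself

  flags <- data.frame(allele_id = sprintf("A%02d", 1:4),
                      sequence = strrep("A", 20),
                      support = c(4L, 5L, 500L, 501L),
                      source = "DNR", copy_flag = NA_character_)
  out <- filter_support(flags, dnr_params())
  expect_equal(out$copy_flag,
               c("low_support", "retained", "retained", "high_copy"))
})

test_that("single-copy support is Poisson around the pooled depth", {
  res <- small_pipeline()
  fam <- small_family()
  cfg <- small_config()
  D <- pooled_depth(cfg)
  single <- fam$truth$loci$copy_class == "single"
  pref <- substr(fam$truth$haps[single, 1], 1, 101)
  hit <- assign_reads(pref, res$reference)
  sup <- res$reference$support[hit[!is.na(hit)]]
  # individual loci within 4 SD (loose, per-locus), mean within 3 SD
  expect_gt(mean(sup > D - 4 * sqrt(D) & sup < D + 4 * sqrt(D)), 0.9)
  expect_lt(abs(mean(sup) - D), 3 * sqrt(D / length(sup)))
})

test_that("the plastid-like allele is removed as high-copy", {
  res <- small_pipeline()
  fam <- small_family()
  plastid_pref <- substr(fam$truth$haps[fam$truth$loci$copy_class ==
                                          "plastid", 1], 1, 101)
  all_alleles <- res$alleles
  hit <- assign_reads(plastid_pref, all_alleles)
  expect_false(is.na(hit[1]))
  expect_equal(all_alleles$copy_flag[hit[1]], "high_copy")
  # and it never reaches the retained reference
  expect_true(is.na(assign_reads(plastid_pref, res$reference)[1]))
})

test_that("repeat families collapse to fewer alleles than true copies", {
  res <- small_pipeline()
  fam <- small_family()
  rep_rows <- fam$truth$loci$copy_class == "repeat"
  pref <- unique(substr(fam$truth$haps[rep_rows, 1], 1, 101))
  hit <- assign_reads(pref, res$reference)
  expect_lt(length(unique(hit[!is.na(hit)])), sum(rep_rows))
})

test_that("center-star selection minimizes total distance", {
  set.seed(14)
  s <- random_seq(101)
  s_err <- s
  substr(s_err, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, 50, 50))[1]
  parent <- build_dnr(s)
  # cluster of identical reads: that sequence, singleton flag handling
  csr1 <- build_csr(parent, c(s, s, s))
  expect_equal(csr1$sequence, s)
  expect_true(is.na(csr1$copy_flag))
  # {S, S, S+1 error}: S is the center of the star
  csr2 <- build_csr(parent, c(s_err, s, s))
  expect_equal(csr2$sequence, s)
  # singleton cluster is emitted flagged
  csr3 <- build_csr(parent, s_err)
  expect_equal(csr3$copy_flag, "singleton")
})

test_that("center-star recovers no more double-het loci than normalization", {
  cfg <- sim_config(n_loci = 50, n_progeny = 10, depth_parent = 30,
                    depth_progeny = 10, error_rate = 0.005, het_rate = 0.7,
                    seed = 15)
  fam <- simulate_family(cfg)
  dnr <- dnr_params(min_support = 3,
                    max_support = 4 * pooled_depth(cfg))
  parents_reads <- fam$reads[fam$reads$individual_id %in% c("P1", "P2"), ]
  prog_reads <- fam$reads[!fam$reads$individual_id %in% c("P1", "P2"), ]

  n_hk <- function(reference) {
    assign <- assign_reads(fam$reads, reference, dnr)
    sites <- pileup_call(fam$reads, reference, assign,
                         samples = c("P1", "P2",
                                     sort(unique(prog_reads$individual_id))))
    mk <- markers_from_sites(sites)
    sum(mk$info$seg_type == "hkxhk")
  }
  dnr_ref <- retained_alleles(filter_support(
    count_support(fam$reads, build_dnr(fam$reads, dnr), dnr), dnr))
  csr_ref <- build_csr(build_dnr(parents_reads, dnr), prog_reads, dnr)
  expect_lte(n_hk(csr_ref), n_hk(dnr_ref))
})

test_that("SAM import recovers assignments for aligned reads", {
  skip_if_not_installed("Rsamtools")
  set.seed(16)
  alleles <- build_dnr(c(random_seq(101), random_seq(101)))
  sam <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:101", alleles$allele_id),
           paste("r1", 0, alleles$allele_id[2], 1, 60, "101M", "*", 0, 0,
                 alleles$sequence[2], strrep("I", 101), sep = "\t"),
           paste("r2", 4, "*", 0, 0, "*", "*", 0, 0,
                 substr(alleles$sequence[1], 1, 50), strrep("I", 50),
                 sep = "\t"))
  p <- file.path(tempdir(), "toy.sam")
  writeLines(sam, p)
  got <- import_sam(p, alleles)
  expect_equal(got$allele[got$read_id == "r1"], 2L)
  expect_true(is.na(got$allele[got$read_id == "r2"]))
})
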