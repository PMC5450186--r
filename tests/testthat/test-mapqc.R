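test_that("the locus file writes a valid header and round-trips", {
  mk <- make_markers(list(c("lm", "ll"), c("hh", "hk")),
                     c("lmxll", "hkxhk"))
  p <- file.path(tempdir(), "pop.loc")
  write_loc(mk, p, name = "fam1")
  lines <- readLines(p)
  expect_true("popt = CP" %in% lines)
  expect_true("nloc = 2" %in% lines)
  expect_true("nind = 2" %in% lines)
  expect_true(any(grepl("<hkxhk>", lines)))
  back <- read_loc(p)
  expect_equal(back$info$marker_id, mk$info$marker_id)
  expect_equal(back$info$seg_type, mk$info$seg_type)
  expect_equal(unname(back$codes), unname(mk$codes))
  # byte-stable output
  p2 <- file.path(tempdir(), "pop2.loc")
  write_loc(mk, p2, name = "fam1")
  expect_identical(readLines(p), readLines(p2))
  # illegal codes are refused with the marker named
  bad <- mk
  bad$codes[2, 1] <- "lm"
  expect_error(write_loc(bad, p), "mk002")
})

test_that("fixed orders validate, write and read back", {
  mk <- make_markers(rep(list(c("lm", "ll")), 3), rep("lmxll", 3))
  ord <- list(LG1 = c("mk002", "mk001"), LG2 = "mk003")
  p <- file.path(tempdir(), "fixed.txt")
  write_fixed_order(ord, p, markers = mk)
  expect_equal(read_fixed_order(p), ord)
  expect_error(write_fixed_order(list(LG1 = c("mk001", "mk001")), p),
               "duplicate")
  expect_error(write_fixed_order(list(LG1 = "zz"), p, markers = mk),
               "absent")
})

test_that("independence LOD matches the closed-form G on association tables", {
  a <- rep(c("ll", "lm"), each = 100)
  expect_equal(independence_lod(a, a), 400 * log(2) / (2 * log(10)),
               tolerance = 1e-9)
  # marker against itself is the maximum over reshufflings of itself
  set.seed(22)
  shuffled <- sample(a)
  expect_lte(independence_lod(a, shuffled), independence_lod(a, a))
  # degenerate: one observed class
  expect_equal(independence_lod(rep("ll", 50), a[1:50]), 0)
  # independent 1:1 markers sit near zero
  b <- sample(rep(c("nn", "np"), each = 100))
  expect_lt(independence_lod(a, b), 3)
})

test_that("the pairwise LOD kernel agrees with the scalar definition", {
  res <- small_pipeline()
  mk <- res$markers
  lod <- pairwise_lod(mk)
  set.seed(23)
  idx <- cbind(sample(nrow(mk$info), 25, replace = TRUE),
               sample(nrow(mk$info), 25, replace = TRUE))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (i == j) next
    expect_equal(lod[i, j],
                 independence_lod(mk$codes[i, ], mk$codes[j, ]),
                 tolerance = 1e-9)
  }
})

test_that("grouping is order-invariant and monotone in the threshold", {
  fam <- small_family()
  mk <- truth_marker_codes(fam$truth)
  g1 <- group_markers(mk, 6)
  set.seed(24)
  perm <- sample(nrow(mk$info))
  g2 <- group_markers(mk[perm], 6)
  expect_equal(g1, g2)
  # all singletons above the maximal pairwise LOD
  g3 <- group_markers(mk, 1e6)
  expect_equal(length(g3$groups), 0L)
  expect_equal(sort(g3$singletons), sort(mk$info$marker_id))
  # raising the threshold only refines the partition
  g_lo <- group_markers(mk, 4)
  g_hi <- group_markers(mk, 12)
  memb <- function(g) {
    out <- c(unlist(lapply(seq_along(g$groups), function(i)
      setNames(rep(i, length(g$groups[[i]])), g$groups[[i]]))),
      setNames(seq_along(g$singletons) + length(g$groups), g$singletons))
    out
  }
  lo <- memb(g_lo); hi <- memb(g_hi)
  ids <- names(hi)
  for (grp in split(ids, hi[ids]))
    expect_equal(length(unique(lo[grp])), 1L)
})

test_that("two-point recombination fractions behave at the extremes", {
  a <- rep(c("ll", "lm"), each = 50)
  expect_equal(two_point_rf(a, a, "lmxll", "lmxll")$rf, 0)
  set.seed(25)
  b <- sample(a)
  expect_lt(abs(two_point_rf(a, b, "lmxll", "lmxll")$rf - 0.5), 0.15)
  expect_error(two_point_rf(a, a, "lmxll", "nnxnp"), "common parent")
  expect_error(two_point_rf(c("ll", "--"), c("--", "ll"),
                            "lmxll", "lmxll"), "no shared")
})

test_that("simulated marker pairs recover their map distance", {
  cfg <- sim_config(n_loci = 2, n_progeny = 2000, chrom_length_cM = 100,
                    n_chromosomes = 1, seed = 26)
  set.seed(26)
  tr <- simulate_progeny(manual_truth(cfg, cM = c(40, 50)), cfg)
  mk <- truth_marker_codes(tr)
  expect_equal(mk$info$seg_type, c("lmxll", "lmxll"))
  tp <- two_point_rf(mk$codes[1, ], mk$codes[2, ], "lmxll", "lmxll")
  r_exp <- inverse_kosambi(10)
  expect_lt(abs(tp$rf - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / 2000))

  # hk x hk pair via the unambiguous double-homozygote inversion
  set.seed(27)
  tr2 <- simulate_progeny(manual_truth(cfg, cM = c(40, 50),
                                       p1_het = TRUE, p2_het = TRUE), cfg)
  mk2 <- truth_marker_codes(tr2)
  expect_equal(mk2$info$seg_type, c("hkxhk", "hkxhk"))
  tp2 <- two_point_rf(mk2$codes[1, ], mk2$codes[2, ], "hkxhk", "hkxhk")
  # only ~n/4 double-homozygote individuals are informative and the
  # estimate passes through the opposite-homozygote inversion, so its
  # 3 SD band is several times wider than the 1:1 direct count's
  expect_lt(abs(tp2$rf - r_exp), 0.06)

  # unlinked chromosomes give rf near 0.5
  cfg2 <- sim_config(n_loci = 2, n_progeny = 2000, chrom_length_cM = 100,
                     n_chromosomes = 2, seed = 28)
  set.seed(28)
  tr3 <- manual_truth(cfg2, cM = c(20, 20))
  tr3$loci$chrom <- c(1L, 2L)
  tr3 <- simulate_progeny(tr3, cfg2)
  mk3 <- truth_marker_codes(tr3)
  tp3 <- two_point_rf(mk3$codes[1, ], mk3$codes[2, ], "lmxll", "lmxll")
  expect_lt(abs(tp3$rf - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("the Kosambi function matches its closed form and inverse", {
  expect_equal(kosambi_cM(0), 0)
  expect_equal(kosambi_cM(0.25), 25 * log(3), tolerance = 1e-12)
  expect_equal(kosambi_cM(0.25), 27.46531, tolerance = 1e-6)
  expect_equal(kosambi_cM(0.1), 10.13663, tolerance = 1e-6)
  expect_error(kosambi_cM(0.5), "0.5")
  r <- seq(0, 0.49, by = 0.01)
  expect_equal(inverse_kosambi(kosambi_cM(r)), r, tolerance = 1e-12)
  expect_true(all(diff(kosambi_cM(r)) > 0))
  # small-distance limit: d in cM approaches 100 r
  expect_equal(kosambi_cM(1e-4) / 100, 1e-4, tolerance = 1e-6)
})

test_that("map length sums adjacent Kosambi distances", {
  a <- rep(c("ll", "lm"), each = 50)
  flip <- function(x, i) {
    x[i] <- ifelse(x[i] == "lm", "ll", "lm")
    x
  }
  b <- flip(a, 1:10)    # rf 0.1 to a
  c_ <- flip(b, 91:100) # rf 0.1 to b
  mk <- make_markers(list(a, b, c_), rep("lmxll", 3))
  expect_equal(map_length("mk001", mk), 0)
  expect_equal(map_length(c("mk001", "mk002", "mk003"), mk),
               2 * kosambi_cM(0.1), tolerance = 1e-9)
  expect_equal(2 * kosambi_cM(0.1), 20.27326, tolerance = 1e-5)
  expect_error(map_length(c("mk001", "zz"), mk), "zz")
})

test_that("inflation diagnostics compare map lengths", {
  reg <- data.frame(marker_id = c("a", "b"), position_cM = c(0, 100))
  ml <- data.frame(marker_id = c("a", "b"), position_cM = c(0, 1000))
  expect_equal(inflation_ratio(reg, reg), 1.0)
  expect_equal(inflation_ratio(ml, reg), 10.0)
  expect_error(inflation_ratio(ml, data.frame(marker_id = "a",
                                              position_cM = 5)),
               "zero-length")
  # genotyping errors inflate a naive-order map length
  set.seed(29)
  a <- rep(c("ll", "lm"), 50)
  chain <- list(a)
  for (i in 2:6) {
    prev <- chain[[i - 1]]
    flip <- sample(100, 5)
    nxt <- prev
    nxt[flip] <- ifelse(prev[flip] == "lm", "ll", "lm")
    chain[[i]] <- nxt
  }
  clean <- make_markers(chain, rep("lmxll", 6))
  noisy_codes <- lapply(chain, function(x) {
    e <- sample(100, 5)
    x[e] <- ifelse(x[e] == "lm", "ll", "lm")
    x
  })
  noisy <- make_markers(noisy_codes, rep("lmxll", 6))
  ord <- sprintf("mk%03d", 1:6)
  expect_gt(map_length(ord, noisy), map_length(ord, clean))
})

test_that("framework-order concordance counts pairwise inversions", {
  fw <- sprintf("f%d", 1:5)
  expect_equal(order_concordance(fw, fw), 1.0)
  expect_equal(order_concordance(rev(fw), fw), 0.0)
  swap <- fw[c(1, 3, 2, 4, 5)]
  expect_equal(order_concordance(swap, fw), 0.9)
  # interleaved SNP markers do not affect a preserved order
  mixed <- c("s1", "f1", "s2", "f2", "f3", "s3", "f4", "f5")
  expect_equal(order_concordance(mixed, fw), 1.0)
  expect_error(order_concordance("f1", fw), "undefined")
})

test_that("map summaries conserve totals", {
  maps <- data.frame(
    group = rep(c("LG1", "LG2"), c(3, 2)),
    marker_id = c("f1", "s1", "s2", "f2", "s3"),
    position_cM = c(0, 10, 25, 0, 40))
  s <- summarize_map(maps, framework_ids = c("f1", "f2"))
  expect_equal(s$n_loci, c(3L, 2L, 5L))
  expect_equal(s$n_est_ssr, c(1L, 1L, 2L))
  expect_equal(s$length_cM, c(25, 40, 65))
  expect_equal(s$spacing[1:2], trunc(100 * c(25 / 3, 40 / 2)) / 100)
  expect_equal(s$group[3], "Total")
})
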