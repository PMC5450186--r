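lm_codes <- function(n_lm, n_ll, n_miss = 0)
  c(rep("lm", n_lm), rep("ll", n_ll), rep("--", n_miss))

test_that("multi-SNP sequences are removed wholesale", {
  mk <- make_markers(list(lm_codes(5, 5), lm_codes(5, 5), lm_codes(5, 5)),
                     rep("lmxll", 3),
                     allele_ids = c("s1", "s2", "s2"),
                     positions = c(20L, 15L, 70L))
  out <- f1_multi_snp(mk)
  expect_equal(out$info$allele_id, "s1")
  # markers on single-SNP sequences are never removed
  expect_equal(nrow(f1_multi_snp(out)$info), 1L)
})

test_that("position filtering drops the first nine bases only", {
  mk <- make_markers(rep(list(lm_codes(5, 5)), 3), rep("lmxll", 3),
                     positions = c(9L, 10L, 50L))
  out <- f2_position(mk)
  expect_equal(out$info$position, c(10L, 50L))
  # all-at-position-50 input is untouched
  mk50 <- make_markers(rep(list(lm_codes(5, 5)), 2), rep("lmxll", 2),
                       positions = c(50L, 50L))
  expect_equal(nrow(f2_position(mk50)$info), 2L)
})

test_that("missing-data filtering uses the retained-individual denominator", {
  mk <- make_markers(list(lm_codes(100, 106, 11),   # 11/217 = 5.07%
                          lm_codes(100, 107, 10)),  # 10/217 = 4.61%
                     rep("lmxll", 2))
  expect_equal(f3_missing(mk, 0.05)$info$marker_id, "mk002")
  expect_equal(nrow(f3_missing(mk, 0)$info), 0L)
  complete <- make_markers(list(lm_codes(5, 5)), "lmxll")
  expect_equal(nrow(f3_missing(complete, 0.30)$info), 1L)
  expect_equal(nrow(f3_missing(make_markers(list(lm_codes(5, 4, 1)),
                                            "lmxll"), 0)$info), 0L)
})

test_that("the segregation chi-square matches direct computation", {
  perfect <- c(rep("hh", 50), rep("hk", 100), rep("kk", 50))
  expect_equal(chi2_segregation(perfect, "hkxhk")$statistic, 0)
  skewed <- c(rep("hh", 60), rep("hk", 100), rep("kk", 40))
  r <- chi2_segregation(skewed, "hkxhk")
  expect_equal(r$statistic, 4.0)
  expect_equal(r$df, 2L)
  r2 <- chi2_segregation(lm_codes(120, 80), "lmxll")
  expect_equal(r2$statistic, 8.0)
  expect_equal(r2$df, 1L)
  expect_equal(r2$p.value, pchisq(8, 1, lower.tail = FALSE))
  und <- chi2_segregation(rep("--", 10), "lmxll")
  expect_true(is.na(und$statistic))
})

test_that("the distortion screen is strict at its cutoff", {
  # (120, 60): chi2 = 60^2/180 * ... = exactly 20; (119, 61): 18.69
  at20 <- make_markers(list(lm_codes(120, 60), lm_codes(119, 61)),
                       rep("lmxll", 2))
  out <- f4_chi2_filter(at20, filter_params(chi2_cutoff = 20))
  expect_equal(out$info$marker_id, "mk002")
  # a 3:1-distorted 1:1 marker at n = 217 is far beyond the cutoff
  distorted <- make_markers(list(lm_codes(163, 54)), "lmxll")
  expect_equal(chi2_segregation(lm_codes(163, 54), "lmxll")$statistic,
               (163 - 108.5)^2 / 108.5 * 2)
  expect_equal(nrow(f4_chi2_filter(distorted,
                                   filter_params(chi2_cutoff = 20))$info), 0L)
  # pvalue mode: (110, 90) has chi2 = 2, p = 0.157 >= 0.025, retained;
  # (140, 60) has chi2 = 32, p = 1.6e-8, removed
  pv_mk <- make_markers(list(lm_codes(110, 90), lm_codes(140, 60)),
                        rep("lmxll", 2))
  pv <- f4_chi2_filter(pv_mk, filter_params(chi2_mode = "pvalue",
                                            chi2_cutoff = 0.025))
  expect_equal(pv$info$marker_id, "mk001")
  # undefined markers are removed and counted
  und <- make_markers(list(lm_codes(0, 0, 10), lm_codes(5, 5)),
                      rep("lmxll", 2))
  kept <- f4_chi2_filter(und, filter_params())
  expect_equal(kept$info$marker_id, "mk002")
  expect_equal(attr(kept, "n_undefined"), 1L)
})

test_that("individual exclusion is strict above the threshold", {
  codes <- matrix("lm", 20, 10,
                  dimnames = list(NULL, sprintf("i%02d", 1:10)))
  codes[1:19, 1] <- "--"   # 95% missing: dropped
  codes[1:18, 2] <- "--"   # 90% exactly: kept
  mk <- cp_markers(data.frame(marker_id = sprintf("m%02d", 1:20),
                              seg_type = "lmxll"), codes)
  out <- drop_individuals(mk, 0.90)
  expect_equal(attr(out, "dropped_individuals"), "i01")
  expect_equal(ncol(out$codes), 9L)
  # complete data drops nobody
  full <- make_markers(list(lm_codes(5, 5)), "lmxll")
  expect_equal(length(attr(drop_individuals(full),
                           "dropped_individuals")), 0L)
})

test_that("similarity is the matched fraction over shared scored individuals", {
  a <- lm_codes(100, 100)
  expect_equal(similarity(a, a), 1.0)
  b <- a; b[1:10] <- ifelse(a[1:10] == "lm", "ll", "lm")
  expect_equal(similarity(a, b), 190 / 200)
  comp <- ifelse(a == "lm", "ll", "lm")
  expect_equal(similarity(a, comp), 0.0)
  expect_true(is.na(similarity(c("lm", "--"), c("--", "ll"))))
  # missing positions are excluded from the denominator
  a2 <- a; a2[1:20] <- "--"
  expect_equal(similarity(a, a2), 1.0)
})

test_that("similarity deduplication keeps one representative per cluster", {
  a <- lm_codes(100, 100)
  b <- a; b[1] <- ifelse(a[1] == "lm", "ll", "lm")    # sim 0.995
  c_ <- a; c_[2] <- ifelse(a[2] == "lm", "ll", "lm")  # sim 0.995 to a
  mk <- make_markers(list(a, b, c_), rep("lmxll", 3))
  out <- similarity_dedup(mk, 0.945)
  expect_equal(nrow(out$info), 1L)
  expect_equal(out$info$marker_id, "mk001")  # tie on missing: lexicographic
  # independent markers are all kept
  set.seed(20)
  rand <- replicate(12, sample(c("lm", "ll"), 100, replace = TRUE),
                    simplify = FALSE)
  mk2 <- make_markers(rand, rep("lmxll", 12))
  expect_equal(nrow(similarity_dedup(mk2, 0.945)$info), 12L)
  # representative is the least-missing member
  b_miss <- b; b_miss[3:6] <- "--"
  mk3 <- make_markers(list(b_miss, a), rep("lmxll", 2))
  expect_equal(similarity_dedup(mk3, 0.9)$info$marker_id, "mk002")
})

test_that("the cascade is monotone and the report tracks every stage", {
  res <- small_pipeline()
  rep_ <- res$report
  expect_true(all(diff(rep_$n_markers) <= 0))
  expect_true(all(diff(rep_$n_individuals) <= 0))
  expect_equal(rep_$stage[1], "input")
  expect_equal(rep_$n_markers[1], nrow(res$markers_raw$info))
  expect_equal(rep_$n_markers[nrow(rep_)], nrow(res$markers$info))
  # empty input gives an all-zero report
  empty <- cp_markers(data.frame(marker_id = character(0),
                                 seg_type = character(0)),
                      matrix("--", 0, 5))
  rep0 <- run_cascade(empty)$report
  expect_true(all(rep0$n_markers == 0))
})

test_that("F1 and F2 commute as per-site predicates", {
  set.seed(21)
  mk <- make_markers(rep(list(lm_codes(5, 5)), 8), rep("lmxll", 8),
                     allele_ids = c("s1", "s1", "s2", "s3", "s3", "s4",
                                    "s5", "s6"),
                     positions = c(5L, 50L, 7L, 20L, 30L, 9L, 10L, 80L))
  ab <- f2_position(f1_multi_snp(mk))
  ba <- f1_multi_snp(f2_position(mk))
  expect_equal(ab$info$marker_id, ba$info$marker_id)
})
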