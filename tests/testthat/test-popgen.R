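test_that("PI closed form matches pair enumeration exactly", {
  bi <- allele_freqs(list(L = c(`100` = 0.5, `102` = 0.5)))
  expect_equal(prob_identity(bi)$per_locus[["L"]], 0.375)
  expect_equal(prob_identity(bi)$combined, 0.375)  # single locus

  set.seed(91)
  for (r in 1:20) {
    k <- sample(2:5, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    names(p) <- 100 + 2 * seq_len(k)
    af <- allele_freqs(list(L = p))
    expect_equal(prob_identity(af)$per_locus[["L"]], oracle_pi(af$L),
                 tolerance = 1e-12)
  }
})

test_that("PE closed forms match brute-force Mendelian enumeration", {
  bi <- allele_freqs(list(L = c(`100` = 0.5, `102` = 0.5)))
  expect_equal(prob_exclusion(bi, "one-parent-known")$per_locus[["L"]],
               0.1875)
  set.seed(92)
  for (r in 1:12) {
    k <- sample(2:5, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    names(p) <- 100 + 2 * seq_len(k)
    af <- allele_freqs(list(L = p))
    expect_equal(prob_exclusion(af, "one-parent-known")$per_locus[["L"]],
                 oracle_pe2(af$L), tolerance = 1e-12)
    expect_equal(prob_exclusion(af, "no-parent-known")$per_locus[["L"]],
                 oracle_pe3(af$L), tolerance = 1e-12)
  }
  expect_error(prob_exclusion(bi, "nonsense"))
})

test_that("exclusion power grows with allele count at fixed evenness", {
  pe2 <- pe3 <- numeric(0)
  for (k in 2:6) {
    p <- rep(1 / k, k); names(p) <- 100 + 2 * seq_len(k)
    af <- allele_freqs(list(L = p))
    pe2 <- c(pe2, prob_exclusion(af, "one-parent-known")$per_locus)
    pe3 <- c(pe3, prob_exclusion(af, "no-parent-known")$per_locus)
    # the parent-pair test is at least as powerful as the one-parent test
    expect_gte(pe3[length(pe3)], pe2[length(pe2)])
  }
  expect_true(all(diff(pe2) > 0))
  expect_true(all(diff(pe3) > 0))
})

test_that("combined PI and PE respect their per-locus bounds", {
  af <- gen_allele_freqs(7, c(14, 25), seed = 93)
  pi_ <- prob_identity(af)
  pe <- prob_exclusion(af, "one-parent-known")
  expect_lte(pi_$combined, min(pi_$per_locus))
  expect_gte(pe$combined, max(pe$per_locus))
  expect_true(all(pe$per_locus >= 0 & pe$per_locus <= 1))
  # a rich microsatellite panel individualises essentially perfectly
  expect_lt(pi_$combined, 1e-10)
})

test_that("the HWE permutation test behaves at its anchors", {
  # counts exactly at HWE proportions: statistic 0, p ~ 1
  m <- rbind(matrix(rep(c(100L, 100L), 25), ncol = 2, byrow = TRUE),
             matrix(rep(c(100L, 102L), 50), ncol = 2, byrow = TRUE),
             matrix(rep(c(102L, 102L), 25), ncol = 2, byrow = TRUE))
  res <- hwe_test(m, reps = 500, seed = 1)
  expect_equal(res$statistic, 0)
  expect_gt(res$p_value, 0.95)

  # complete heterozygote deficit is detected at n = 100
  m2 <- rbind(matrix(rep(c(100L, 100L), 50), ncol = 2, byrow = TRUE),
              matrix(rep(c(102L, 102L), 50), ncol = 2, byrow = TRUE))
  expect_lt(hwe_test(m2, reps = 500, seed = 1)$p_value, 0.01)

  # insufficient data is flagged, not guessed
  expect_true(is.na(hwe_test(cbind(100L, 100L))$p_value))
})

test_that("the HWE test holds its size on simulated equilibrium data", {
  af <- gen_allele_freqs(1, 6, concentration = 2, seed = 94)
  reps <- 120
  pvals <- vapply(seq_len(reps), function(r) {
    ad <- sim_adults(af, 60, 0, seed = 1000 + r)
    hwe_test(locus_alleles(ad$females, "L01"), reps = 400,
             seed = 2000 + r)$p_value
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  expect_gt(mean(pvals), 0.35)  # roughly uniform, not collapsed
})

test_that("duplicate-genotyping error rate counts mismatched calls", {
  af <- gen_allele_freqs(7, 10, seed = 95)
  ad <- sim_adults(af, 25, 0, seed = 96)
  expect_equal(genotyping_error_rate(ad$females, ad$females)$rate, 0)

  # flip exactly one allele call among the first individual's loci
  dup <- ad$females
  dup$L01_1 <- as.integer(dup$L01_1)
  other <- setdiff(as.integer(names(af$L01)), locus_alleles(dup, "L01")[1, ])
  dup$L01_1[1] <- other[1]
  res <- genotyping_error_rate(ad$females[1, , drop = FALSE],
                               dup[1, , drop = FALSE])
  expect_equal(res$compared, 14)
  expect_equal(res$rate, 1 / 14)

  # one mismatched call in 50 compared is 2% -- the printed-rate anchor
  expect_equal(1 / 50, 0.02)
  ids <- sprintf("i%02d", 1:25)
  a <- genotype_table(ids, list(L1 = matrix(100L, 25, 2)))
  b <- genotype_table(ids, list(L1 = rbind(c(100L, 102L),
                                           matrix(100L, 24, 2))))
  res2 <- genotyping_error_rate(a, b)
  expect_equal(res2$compared, 50)
  expect_equal(res2$rate, 0.02)
})

test_that("the error-rate estimate matches its analytic expectation", {
  k <- 10
  af <- gen_allele_freqs(7, k, concentration = 50, seed = 97)
  ad <- sim_adults(af, 400, 0, seed = 98)
  eps <- 0.03
  # corrupt one replicate with uniform-replacement errors
  dup <- ad$females
  set.seed(99)
  for (loc in names(af)) {
    ladder <- as.integer(names(af[[loc]]))
    for (col in paste0(loc, c("_1", "_2"))) {
      hit <- runif(nrow(dup)) < eps
      dup[[col]][hit] <- sample(ladder, sum(hit), replace = TRUE)
    }
  }
  est <- genotyping_error_rate(ad$females, dup)
  expected <- eps * (1 - 1 / k)   # replacement can collide with the truth
  se <- sqrt(expected * (1 - expected) / est$compared)
  expect_lt(abs(est$rate - expected), 4 * se + 0.002)
})

test_that("the popgen summary table is coherent", {
  af <- gen_allele_freqs(4, 8, seed = 100)
  ad <- sim_adults(af, 80, 0, seed = 101)
  ps <- popgen_summary(ad$females, hwe_reps = 300, seed = 102)
  expect_equal(nrow(ps), 5)
  expect_identical(ps$locus[5], "combined")
  body <- ps[1:4, ]
  expect_true(all(body$Ho >= 0 & body$Ho <= 1))
  expect_true(all(body$He >= 0 & body$He < 1))
  expect_equal(ps$PI[5], prod(body$PI))
  expect_equal(ps$PE2[5], 1 - prod(1 - body$PE2))
})
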