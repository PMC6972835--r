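test_that("Sorensen similarity reproduces its defining cases", {
  expect_equal(sorensen_qs(2, 2, 1), 50)
  expect_equal(sorensen_qs(3, 3, 3), 100)
  expect_equal(sorensen_qs(2, 4, 0), 0)
  expect_equal(sorensen_qs(2, 3, 1), sorensen_qs(3, 2, 1))  # symmetry
  expect_error(sorensen_qs(2, 2, 3), "exceed")
})

test_that("the nonappearance probability follows (1-f)^n", {
  expect_equal(prob_nonappearance(1, 20), 0)
  expect_equal(prob_nonappearance(0, 20), 1)
  expect_equal(prob_nonappearance(0.5, 2), 0.25)
  # strictly decreasing in f and in n
  f <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(vapply(f, prob_nonappearance, numeric(1),
                              n = 10)) < 0))
  expect_true(all(diff(vapply(1:30, function(n)
    prob_nonappearance(0.3, n), numeric(1))) < 0))
})

test_that("father transitions are classified against the chance model", {
  par <- fixed_parents()
  # M2 sires half of clutch 1 then vanishes: disappearance beyond chance
  a <- fit_from_sires(par, rep(c("M1", "M2"), each = 10))
  b <- fit_from_sires(par, rep("M1", 20), order = 2L, prefix = "g")
  ct <- classify_transitions(a, b, f_mode = "first-clutch")
  gone <- ct$transitions[ct$transitions$status == "disappeared", ]
  expect_equal(nrow(gone), 1)
  expect_equal(gone$f, 0.5)
  expect_equal(gone$p_f, (1 - 0.5)^20)
  expect_lt(gone$p_f, 0.05)
  expect_identical(gone$classification, "unlikely due to chance")
  kept <- ct$transitions[ct$transitions$status == "retained", ]
  expect_equal(nrow(kept), 1)

  # a marginal sire absent from a small second clutch is chance-compatible
  a2 <- fit_from_sires(par, c(rep("M1", 19), "M2"))
  b2 <- fit_from_sires(par, rep("M1", 10), order = 2L, prefix = "g")
  ct2 <- classify_transitions(a2, b2, f_mode = "first-clutch")
  gone2 <- ct2$transitions[ct2$transitions$status == "disappeared", ]
  expect_equal(gone2$f, 0.05)
  expect_equal(gone2$p_f, (1 - 0.05)^10, tolerance = 1e-12)
  expect_identical(gone2$classification, "chance or sperm depletion")

  # a strong newcomer in clutch 2 is remating-consistent
  b3 <- fit_from_sires(par, rep(c("M1", "M3"), each = 10), order = 2L,
                       prefix = "g")
  ct3 <- classify_transitions(a2, b3)
  new <- ct3$transitions[ct3$transitions$status == "appeared", ]
  expect_equal(nrow(new), 1)
  expect_equal(new$f, 10 / 40)  # combined-clutch estimate
  expect_equal(new$n, 20)       # tested against the first clutch's sample
  expect_identical(new$classification, "remating-consistent")
})

test_that("detection power matches the inclusion-exclusion closed form", {
  expect_equal(detection_power(c(0.5, 0.5), 20), 1 - 2 * 0.5^20)
  expect_equal(detection_power(c(0.9, 0.1), 20), 1 - 0.9^20 - 0.1^20)
  expect_equal(detection_power(c(0.3, 0.3, 0.4), 1), 0)
  expect_equal(as.numeric(detection_power(1, 20)), 0)
  expect_match(attr(detection_power(1, 20), "note"), "single father")
  expect_error(detection_power(c(0.5, 0.6), 10), "summing to 1")

  # simulation mode agrees within 3 Monte-Carlo SE
  for (f in list(c(0.9, 0.1), c(0.6, 0.3, 0.1))) {
    p <- detection_power(f, 8)
    reps <- 4000
    sim <- detection_power(f, 8, mode = "simulation", reps = reps,
                           seed = 131)
    expect_lt(abs(sim - p), 3 * sqrt(p * (1 - p) / reps) + 1e-9)
  }
})

test_that("breeding sex ratio sums distinct sires over females", {
  counts <- c(1, 1, 3, 1, 1, 1, 1, 1, 1, 1, 1, 5, 1, 3, 2, 1)
  res <- breeding_sex_ratio(counts)
  expect_equal(res$bsr, 25 / 16)
  expect_equal(round(res$bsr, 2), 1.56)
  expect_equal(breeding_sex_ratio(rep(1, 12))$bsr, 1)
  expect_error(breeding_sex_ratio(c(1, 0)), "father")

  # assignment interface: two females, one shared male pool
  par <- fixed_parents()
  f1 <- list(fit_from_sires(par, rep(c("M1", "M2"), each = 8)))
  f2 <- list(fit_from_sires(par, rep("M3", 16), prefix = "g"))
  res2 <- breeding_sex_ratio(list(f1, f2), scope = "all-clutches")
  expect_equal(res2$n_fathers, 3)
  expect_equal(res2$bsr, 1.5)
  # a male siring for both females is merged across them
  f3 <- list(fit_from_sires(par, rep("M1", 16), prefix = "k"))
  res3 <- breeding_sex_ratio(list(f1, f3), scope = "all-clutches")
  expect_equal(res3$n_fathers, 2)
  expect_equal(res3$cross_female_matches, 1)
})

test_that("BSR is invariant to female ordering and respects scope", {
  par <- fixed_parents()
  fem_a <- list(fit_from_sires(par, rep(c("M1", "M2"), each = 8)),
                fit_from_sires(par, rep("M1", 16), order = 2L,
                               prefix = "g"))
  fem_b <- list(fit_from_sires(par, rep("M3", 16), prefix = "k"))
  r1 <- breeding_sex_ratio(list(fem_a, fem_b), "all-clutches")
  r2 <- breeding_sex_ratio(list(fem_b, fem_a), "all-clutches")
  expect_equal(r1$bsr, r2$bsr)
  expect_equal(r1$n_fathers, 3)
  # first-clutch scope sees the same sires here (M2 present in clutch 1)
  rf <- breeding_sex_ratio(list(fem_a, fem_b), "first-clutch-only")
  expect_equal(rf$n_fathers, 3)
})

test_that("population extrapolation reproduces the census arithmetic", {
  ex <- extrapolate_population(634, 3.9, 5.4, 1.46)
  expect_identical(ex$females, c(117, 163))
  expect_identical(ex$males, c(171, 238))
  ex2 <- extrapolate_population(100, 1, 1, 1)
  expect_identical(ex2$females, c(100, 100))
  expect_identical(ex2$males, c(100, 100))
  # male bounds widen monotonically with the sex ratio
  ms <- vapply(seq(1, 3, by = 0.25), function(b)
    extrapolate_population(634, 3.9, 5.4, b)$males[2], numeric(1))
  expect_true(all(diff(ms) > 0))
  expect_error(extrapolate_population(634, 0, 5.4, 1.46), "positive")
})

test_that("mating_system aggregates fits into the season summary", {
  st <- sim_study(n_females = 5, seed = 141, remating_prob = 0.4)
  fits <- lapply(st$clutches, clutch_paternity, mother = st$mothers)
  ms <- mating_system(fits)
  expect_s3_class(ms, "mating_system")
  expect_true(all(ms$pairs$QS >= 0 & ms$pairs$QS <= 100))
  expect_true(all(ms$pairs$C <= pmin(ms$pairs$A, ms$pairs$B)))
  expect_gt(ms$bsr_all$bsr, 0)
  expect_gte(ms$bsr_all$n_fathers, ms$bsr_first$n_fathers)
  sm <- summary(ms)
  expect_named(sm, c("clutches", "pairs", "transitions", "bsr_all",
                     "bsr_first"))
  expect_equal(nrow(sm$clutches), length(fits))
})

test_that("comparing two BSR estimates uses Fisher's exact test", {
  ht <- compare_bsr(23, 16, 25, 16)
  expect_s3_class(ht, "htest")
  expect_gt(ht$p.value, 0.5)   # near-identical ratios are not distinguished
})
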