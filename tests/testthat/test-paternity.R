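test_that("maternal subtraction yields the textbook candidate sets", {
  mom <- genotype_table("M", list(L1 = cbind(100L, 102L),
                                  L2 = cbind(200L, 202L),
                                  L3 = cbind(300L, 302L)))
  kids <- genotype_table(c("h1", "h2", "h3"), list(
    L1 = rbind(c(100L, 106L),   # one maternal match: 106 paternal, certain
               c(100L, 102L),   # both maternal: ambiguous {100, 102}
               c(104L, 106L)),  # no match: mismatch flag
    L2 = rbind(c(200L, 200L),   # homozygote: paternal 200 forced
               c(202L, 204L), c(200L, 204L)),
    L3 = rbind(c(300L, 300L), c(300L, 302L), c(300L, 304L))))
  tab <- paternal_allele_sets(mom, kids)
  expect_identical(tab$candidates$h1$L1, 106L)
  expect_true(tab$certain["h1", "L1"])
  expect_setequal(tab$candidates$h2$L1, c(100L, 102L))
  expect_false(tab$certain["h2", "L1"])
  expect_null(tab$candidates$h3$L1)
  expect_true(tab$mismatch["h3", "L1"])
  expect_identical(tab$candidates$h1$L2, 200L)
  expect_true(tab$certain["h1", "L2"])
})

test_that("hatchlings mismatching the mother at many loci are set aside", {
  mom <- genotype_table("M", list(L1 = cbind(100L, 102L),
                                  L2 = cbind(200L, 202L),
                                  L3 = cbind(300L, 302L),
                                  L4 = cbind(400L, 402L)))
  foreign <- genotype_table("weird", list(L1 = cbind(110L, 112L),
                                          L2 = cbind(210L, 212L),
                                          L3 = cbind(310L, 312L),
                                          L4 = cbind(400L, 404L)))
  own <- genotype_table("own", list(L1 = cbind(100L, 104L),
                                    L2 = cbind(200L, 204L),
                                    L3 = cbind(302L, 304L),
                                    L4 = cbind(402L, 404L)))
  both <- rbind(own, foreign)
  attr(both, "loci") <- attr(mom, "loci")
  class(both) <- class(own)
  expect_warning(tab <- paternal_allele_sets(mom, both), "foreign")
  expect_identical(tab$ids, "own")
  expect_identical(tab$excluded$id, "weird")
})

test_that("single-father clutches collapse to one sibship", {
  par <- fixed_parents()
  fit <- fit_from_sires(par, rep("M1", 12))
  expect_equal(fit$k, 1)
  expect_false(fit$mp$mp)
  expect_equal(unname(fit$f), 1)
  # reconstructed father carries both alleles at every locus
  for (loc in panel7())
    expect_length(fit$fathers$F1[[loc]]$alleles, 2)
})

test_that("a locus with five certain paternal alleles forces three sires", {
  # 3 fathers contribute 5 distinct paternal alleles at L1 in a one-locus
  # panel: the pigeonhole bound says >= ceiling(5/2) = 3
  mom <- genotype_table("M", list(L1 = cbind(100L, 102L)))
  kids <- genotype_table(sprintf("h%d", 1:5), list(
    L1 = rbind(c(100L, 110L), c(100L, 112L), c(100L, 114L),
               c(100L, 116L), c(100L, 118L))))
  tab <- paternal_allele_sets(mom, kids)
  fit <- min_father_partition(tab, method = "exact")
  expect_gte(fit$k, 3)
  expect_equal(fit$lower_bound, 3)
  expect_equal(fit$k, oracle_min_fathers(tab))
})

test_that("exact partition equals the exhaustive set-partition oracle", {
  set.seed(111)
  for (r in 1:60) {
    inst <- random_small_instance(n_hatch = sample(3:7, 1))
    tab <- paternal_allele_sets(inst$mother, inst$hatchlings)
    fit <- min_father_partition(tab, method = "exact")
    expect_equal(fit$k, oracle_min_fathers(tab, ignore_loci =
                                             fit$mutation_locus),
                 info = sprintf("instance %d", r))
    # exact <= greedy, both above the pigeonhole bound
    greedy <- min_father_partition(tab, method = "greedy")
    expect_lte(fit$k, greedy$k)
    expect_gte(fit$k, fit$lower_bound)
  }
})

test_that("the exact partition is invariant to hatchling input order", {
  set.seed(112)
  inst <- random_small_instance(n_hatch = 8, n_fathers = 3)
  tab1 <- paternal_allele_sets(inst$mother, inst$hatchlings)
  shuf <- inst$hatchlings[sample(8), , drop = FALSE]
  tab2 <- paternal_allele_sets(inst$mother, shuf)
  f1 <- min_father_partition(tab1, "exact")
  f2 <- min_father_partition(tab2, "exact")
  expect_identical(f1$groups, f2$groups)
  expect_identical(f1$f, f2$f)
})

test_that("multiple paternity follows the two-loci three-alleles rule", {
  par <- fixed_parents()
  # two sires produce >= 3 paternal alleles at every locus
  fit2 <- fit_from_sires(par, rep(c("M1", "M2"), each = 6))
  expect_true(fit2$mp$mp)
  expect_gte(length(fit2$mp$loci_excess), 2)
  expect_equal(fit2$k, 2)

  # three paternal alleles at exactly one locus: attributed to mutation
  mom <- genotype_table("M", list(L1 = cbind(100L, 102L),
                                  L2 = cbind(200L, 202L)))
  kids <- genotype_table(sprintf("h%d", 1:4), list(
    L1 = rbind(c(100L, 110L), c(100L, 112L), c(100L, 114L),
               c(102L, 110L)),
    L2 = rbind(c(200L, 210L), c(200L, 212L), c(202L, 210L),
               c(202L, 212L))))
  tab <- paternal_allele_sets(mom, kids)
  mp <- call_multiple_paternity(tab)
  expect_false(mp$mp)
  expect_true(mp$mutation_attributed)
  expect_identical(mp$loci_excess, "L1")
  # the flagged locus is excluded from the partition constraints
  fit <- min_father_partition(tab, "exact")
  expect_identical(fit$mutation_locus, "L1")
  expect_equal(fit$k, 1)

  # three alleles at two loci: a genuine multiple-paternity call
  kids2 <- genotype_table(sprintf("h%d", 1:3), list(
    L1 = rbind(c(100L, 110L), c(100L, 112L), c(100L, 114L)),
    L2 = rbind(c(200L, 210L), c(200L, 212L), c(202L, 214L))))
  expect_true(call_multiple_paternity(
    paternal_allele_sets(mom, kids2))$mp)
})

test_that("reconstructed sires match when and only when compatible", {
  par <- fixed_parents()
  a <- fit_from_sires(par, rep(c("M1", "M2"), each = 6))
  b <- fit_from_sires(par, rep(c("M1", "M3"), each = 6), order = 2L,
                      prefix = "g")
  m <- match_fathers(a, b)
  expect_equal(m$A, 2); expect_equal(m$B, 2); expect_equal(m$C, 1)
  # identical partitions match completely
  self <- match_fathers(a, a)
  expect_equal(self$C, 2)
  # fully reconstructed different sires never match at tolerance 0
  m2 <- match_fathers(fit_from_sires(par, rep("M1", 10)),
                      fit_from_sires(par, rep("M2", 10), prefix = "g"))
  expect_equal(m2$C, 0)
  # a mismatch allowance can bridge a single discordant locus
  expect_equal(match_fathers(fit_from_sires(par, rep("M1", 10)),
                             fit_from_sires(par, rep("M2", 10),
                                            prefix = "g"),
                             max_mismatch_loci = 7)$C, 1)
})

test_that("true sires are recovered on clean simulated clutches", {
  af <- gen_allele_freqs(7, c(14, 25), seed = 121)
  ok <- 0; usable <- 0
  for (r in 1:30) {
    ad <- sim_adults(af, 1, 3, seed = 3000 + r)
    kf <- sample(1:3, 1)
    w <- rgamma(kf, 3); w <- w / sum(w)
    plan <- mating_plan("F001", ad$males$id[seq_len(kf)], matrix(w, 1))
    cl <- sim_clutches(plan, ad$females, ad$males, clutch_sizes = 100,
                       sample_n = 20, seed = 4000 + r)[[1]]
    sires <- table(cl$true_fathers)
    if (any(sires < 2)) next   # recovery is only promised at >= 2 sampled
    usable <- usable + 1
    fit <- clutch_paternity(cl, ad$females)
    if (fit$k == length(sires)) ok <- ok + 1
  }
  expect_gte(usable, 15)
  expect_gte(ok / usable, 0.95)
})
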