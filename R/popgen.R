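#' Probability of identity
#'
#' PI is the probability that two individuals drawn at random from a
#' population in Hardy-Weinberg equilibrium share the same multilocus
#' genotype. Per locus, with allele frequencies p_i,
#' `PI_l = 2 (sum p_i^2)^2 - sum p_i^4`; loci combine multiplicatively.
#'
#' @param freqs an [allele_freqs] object.
#' @return List with `per_locus` (named vector) and `combined` (product).
#' @examples
#' prob_identity(allele_freqs(list(L1 = c(`100` = 0.5, `102` = 0.5))))
#' @export
prob_identity <- function(freqs) {
  stopifnot(inherits(freqs, "allele_freqs"))
  per <- vapply(freqs, function(p) 2 * sum(p^2)^2 - sum(p^4), numeric(1L))
  list(per_locus = per, combined = prod(per))
}

#' Probability of exclusion
#'
#' PE is the probability that a random non-parent (or non-parent pair) is
#' genetically excluded from parentage of a random true offspring.
#' `mode = "one-parent-known"` is second-parent exclusion (the mother's
#' genotype is known, a random male is tested); `mode = "no-parent-known"`
#' is parent-pair exclusion (a random male-female pair is tested against the
#' offspring alone). Both use the standard polynomial identities in the
#' allele-frequency power sums (Jamieson & Taylor 1997), and are validated
#' in the test suite against brute-force Mendelian enumeration. Loci combine
#' as `PE = 1 - prod(1 - PE_l)`.
#'
#' @param freqs an [allele_freqs] object.
#' @param mode `"one-parent-known"` or `"no-parent-known"`.
#' @return List with `per_locus` and `combined`.
#' @examples
#' af <- allele_freqs(list(L1 = c(`100` = 0.5, `102` = 0.5)))
#' prob_exclusion(af, "one-parent-known")$combined  # 0.1875
#' @export
prob_exclusion <- function(freqs,
                           mode = c("one-parent-known", "no-parent-known")) {
  stopifnot(inherits(freqs, "allele_freqs"))
  mode <- match.arg(mode)
  per <- vapply(freqs, function(p) {
    a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4); a5 <- sum(p^5)
    a6 <- sum(p^6)
    if (mode == "one-parent-known")
      1 - 2 * a2 + a3 + 2 * a4 - 3 * a5 - 2 * a2^2 + 3 * a2 * a3
    else
      1 + 4 * a4 - 4 * a5 - 3 * a6 - 8 * a2^2 + 8 * a2 * a3 + 2 * a3^2
  }, numeric(1L))
  list(per_locus = per, combined = 1 - prod(1 - per))
}

#' Monte-Carlo exact test for Hardy-Weinberg equilibrium
#'
#' Permutes the observed alleles among individuals (random re-pairing of the
#' 2n allele calls) and compares the chi-square distance between observed and
#' HWE-expected genotype counts with its permutation distribution. Chosen
#' over the asymptotic chi-square test because microsatellite genotype tables
#' with 14-25 alleles are extremely sparse.
#'
#' @param alleles integer `n x 2` matrix of allele calls for one locus
#'   (0 = missing; rows with any missing call are dropped).
#' @param reps number of permutation replicates (default 10000).
#' @param seed optional integer seed.
#' @return List with `p_value`, `statistic`, `reps`, and `n` (individuals
#'   used). With fewer than 2 distinct alleles or fewer than 2 usable
#'   individuals the result is flagged: `p_value = NA`, `note` explains.
#' @export
hwe_test <- function(alleles, reps = 10000L, seed = NULL) {
  alleles <- matrix(as.integer(alleles), ncol = 2L)
  alleles <- alleles[alleles[, 1L] != 0L & alleles[, 2L] != 0L, , drop = FALSE]
  n <- nrow(alleles)
  if (n < 2L || length(unique(as.vector(alleles))) < 2L)
    return(list(p_value = NA_real_, statistic = NA_real_, reps = 0L, n = n,
                note = "insufficient data (need >= 2 individuals and alleles)"))
  reps <- check_count(reps, "reps", min = 1L)
  stat <- function(m) {
    pool <- as.vector(m)
    p <- table(pool) / length(pool)
    lab <- as.integer(names(p))
    gobs <- table(factor(paste(pmin(m[, 1L], m[, 2L]),
                               pmax(m[, 1L], m[, 2L]))))
    exp_ct <- outer(as.numeric(p), as.numeric(p))
    gexp <- 2 * exp_ct; diag(gexp) <- diag(exp_ct)
    keys <- outer(lab, lab, function(a, b) paste(pmin(a, b), pmax(a, b)))
    gexp_v <- gexp[upper.tri(gexp, diag = TRUE)] * n
    keys_v <- keys[upper.tri(keys, diag = TRUE)]
    obs_v <- as.numeric(gobs[match(keys_v, names(gobs))])
    obs_v[is.na(obs_v)] <- 0
    sum((obs_v - gexp_v)^2 / gexp_v)
  }
  with_seed(seed, {
    s_obs <- stat(alleles)
    pool <- as.vector(alleles)
    hits <- 0L
    for (r in seq_len(reps)) {
      perm <- matrix(sample(pool), ncol = 2L)
      if (stat(perm) >= s_obs - 1e-12) hits <- hits + 1L
    }
    list(p_value = (hits + 1L) / (reps + 1L), statistic = s_obs,
         reps = reps, n = n)
  })
}

#' Duplicate-genotyping error rate
#'
#' Rate of disagreeing allele calls between repeat genotypings of the same
#' individuals: mismatched calls divided by total calls compared. At each
#' locus the two unordered allele pairs are aligned to minimise mismatches;
#' calls missing in either replicate are skipped.
#'
#' @param first,second `genotype_table`s of the same individuals (matched by
#'   `id`) genotyped twice.
#' @return List with `rate`, `mismatches`, `compared`; `rate = NA` with a
#'   `note` if no calls are comparable.
#' @export
genotyping_error_rate <- function(first, second) {
  stopifnot(inherits(first, "genotype_table"),
            inherits(second, "genotype_table"))
  ids <- intersect(first$id, second$id)
  if (length(ids) == 0L) stop_invalid("no shared individual ids")
  loci <- intersect(attr(first, "loci"), attr(second, "loci"))
  mism <- 0L; comp <- 0L
  for (loc in loci) {
    a <- locus_alleles(first[match(ids, first$id), , drop = FALSE], loc)
    b <- locus_alleles(second[match(ids, second$id), , drop = FALSE], loc)
    for (i in seq_along(ids)) {
      x <- a[i, ]; y <- b[i, ]
      ok <- x != 0L & y != 0L
      # align unordered pairs: compare as-is vs swapped, keep the better
      d1 <- sum(x != y & ok)
      ok2 <- x != 0L & rev(y) != 0L
      d2 <- sum(x != rev(y) & ok2)
      if (d2 < d1 || (d2 == d1 && sum(ok2) > sum(ok))) {
        mism <- mism + d2; comp <- comp + sum(ok2)
      } else {
        mism <- mism + d1; comp <- comp + sum(ok)
      }
    }
  }
  if (comp == 0L)
    return(list(rate = NA_real_, mismatches = 0L, compared = 0L,
                note = "no comparable calls"))
  list(rate = mism / comp, mismatches = mism, compared = comp)
}

#' Per-locus quality summary of a genotype panel
#'
#' One row per locus: observed heterozygosity Ho, expected heterozygosity
#' He = 1 - sum p_i^2, Monte-Carlo HWE p-value, per-locus PI and exclusion
#' probabilities, plus a combined row (PI multiplicative, PE complementary).
#'
#' @param genotypes a `genotype_table` (typically the maternal panel).
#' @param freqs optional [allele_freqs]; estimated from `genotypes` if NULL.
#' @param hwe_reps permutation replicates for [hwe_test].
#' @param seed optional integer seed for the HWE permutations.
#' @return Data frame of class `popgen_summary` with columns `locus`,
#'   `n_alleles`, `Ho`, `He`, `hwe_p`, `PI`, `PE2`, `PE3`; the last row,
#'   locus `"combined"`, carries the multilocus values.
#' @export
popgen_summary <- function(genotypes, freqs = NULL, hwe_reps = 10000L,
                           seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_table"))
  if (is.null(freqs)) freqs <- estimate_allele_freqs(genotypes)
  pi_ <- prob_identity(freqs)
  pe2 <- prob_exclusion(freqs, "one-parent-known")
  pe3 <- prob_exclusion(freqs, "no-parent-known")
  rows <- lapply(seq_along(freqs), function(j) {
    loc <- names(freqs)[j]
    m <- locus_alleles(genotypes, loc)
    m <- m[m[, 1L] != 0L & m[, 2L] != 0L, , drop = FALSE]
    hw <- hwe_test(m, reps = hwe_reps,
                   seed = if (!is.null(seed)) seed + j)
    data.frame(locus = loc, n_alleles = length(freqs[[loc]]),
               Ho = if (nrow(m)) mean(m[, 1L] != m[, 2L]) else NA_real_,
               He = 1 - sum(freqs[[loc]]^2), hwe_p = hw$p_value,
               PI = pi_$per_locus[[loc]], PE2 = pe2$per_locus[[loc]],
               PE3 = pe3$per_locus[[loc]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(locus = "combined", n_alleles = NA_integer_,
                               Ho = NA_real_, He = NA_real_, hwe_p = NA_real_,
                               PI = pi_$combined, PE2 = pe2$combined,
                               PE3 = pe3$combined, stringsAsFactors = FALSE))
  class(out) <- c("popgen_summary", "data.frame")
  out
}

#' @export
print.popgen_summary <- function(x, digits = 4, ...) {
  cat("Locus quality summary (", nrow(x) - 1L, " loci)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
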