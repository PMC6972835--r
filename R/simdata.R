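#' Mating plan for one female's season
#'
#' Describes which males sired each of a female's clutches and in what
#' proportions. A male whose sperm enters the store only after clutch `k`
#' (a remating event) has siring proportion 0 in every clutch before `k`.
#'
#' @param female_id female id.
#' @param father_ids character vector of male ids.
#' @param proportions numeric matrix, `n_clutches x n_fathers`; each row must
#'   be non-negative and sum to 1.
#' @return Object of class `mating_plan` with fields `female_id`,
#'   `father_ids`, `proportions`, and `entry_clutch` (first clutch in which
#'   each father sires; > 1 marks a remating event).
#' @examples
#' # sperm storage with depletion of the second male
#' mating_plan("F1", c("M1", "M2"), rbind(c(0.6, 0.4), c(1, 0)))
#' @export
mating_plan <- function(female_id, father_ids, proportions) {
  father_ids <- as.character(father_ids)
  if (anyDuplicated(father_ids)) stop_invalid("father ids must be unique")
  p <- as.matrix(proportions)
  if (ncol(p) != length(father_ids))
    stop_invalid("proportions needs one column per father")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9))
    stop_invalid("each clutch's proportions must be non-negative and sum to 1")
  entry <- apply(p, 2L, function(col) which(col > 0)[1L])
  if (anyNA(entry)) stop_invalid("every father must sire at least one clutch")
  structure(list(female_id = as.character(female_id), father_ids = father_ids,
                 proportions = p, entry_clutch = as.integer(entry)),
            class = "mating_plan")
}

#' Simulate adults under Hardy-Weinberg equilibrium
#'
#' Each individual's two alleles at each locus are independent draws from the
#' population frequencies (random union of gametes).
#'
#' @param freqs an [allele_freqs] object.
#' @param n_females,n_males adult counts (>= 0).
#' @param seed optional integer seed.
#' @return List with `females` and `males`, each a `genotype_table`
#'   (ids `F001...`, `M001...`).
#' @export
sim_adults <- function(freqs, n_females, n_males, seed = NULL) {
  stopifnot(inherits(freqs, "allele_freqs"))
  n_females <- check_count(n_females, "n_females")
  n_males <- check_count(n_males, "n_males")
  with_seed(seed, {
    draw <- function(ids) {
      loci <- lapply(freqs, function(p) {
        a <- as.integer(names(p))
        cbind(sample(a, length(ids), TRUE, p), sample(a, length(ids), TRUE, p))
      })
      genotype_table(ids, loci)
    }
    list(females = draw(sprintf("F%03d", seq_len(n_females))),
         males = draw(sprintf("M%03d", seq_len(n_males))))
  })
}

# one transmitted gamete allele, with optional single-step mutation to the
# neighbouring size class (reflecting at the ends of the allele ladder)
transmit <- function(pair, allele_ladder, mutation_rate) {
  a <- pair[[sample.int(2L, 1L)]]
  if (mutation_rate > 0 && stats::runif(1L) < mutation_rate) {
    i <- match(a, allele_ladder)
    step <- if (i == 1L) 1L else if (i == length(allele_ladder)) -1L
            else sample(c(-1L, 1L), 1L)
    a <- allele_ladder[i + step]
  }
  a
}

#' Simulate a female's clutches from a mating plan
#'
#' Every egg receives one maternal allele (uniform over the mother's two) and
#' one paternal allele from a father drawn with the clutch's siring
#' proportions. A transmitted allele mutates to a neighbouring size class
#' with probability `mutation_rate`; each recorded allele call is replaced by
#' a uniform draw from the locus's allele set with probability `error_rate`.
#' A random subset of `sample_n` hatchlings per clutch is returned, with the
#' true father of each sampled hatchling retained for truth-tracking.
#'
#' @param plan a [mating_plan].
#' @param mother the mother's `genotype_table` row (1-row table).
#' @param fathers `genotype_table` containing every father named in the plan.
#' @param clutch_sizes egg counts per clutch (recycled to the number of plan
#'   rows); default 100 eggs.
#' @param sample_n hatchlings sampled per clutch (default 20, capped at the
#'   number that emerge).
#' @param mutation_rate per-allele-transmission mutation probability.
#' @param error_rate per-allele-call genotyping error probability.
#' @param freqs optional [allele_freqs]; required when `error_rate > 0` or
#'   `mutation_rate > 0` so the locus allele ladder is known.
#' @param emergence_prob per-egg probability of hatching and emerging,
#'   used to build a plausible nest inventory.
#' @param season_start lay date of the first clutch.
#' @param internesting_days days between successive clutches.
#' @param seed optional integer seed.
#' @return List of [clutch] objects (with inventories, lay dates, incubation
#'   durations and `true_fathers` labels).
#' @export
sim_clutches <- function(plan, mother, fathers, clutch_sizes = 100L,
                         sample_n = 20L, mutation_rate = 0, error_rate = 0,
                         freqs = NULL, emergence_prob = 0.6,
                         season_start = as.Date("2016-05-01"),
                         internesting_days = 11L, seed = NULL) {
  stopifnot(inherits(plan, "mating_plan"), inherits(mother, "genotype_table"))
  mutation_rate <- check_prob(mutation_rate, "mutation_rate")
  error_rate <- check_prob(error_rate, "error_rate")
  sample_n <- check_count(sample_n, "sample_n", min = 1L)
  missing_f <- setdiff(plan$father_ids, fathers$id)
  if (length(missing_f))
    stop_invalid("father id(s) missing from fathers table: ",
                 paste(missing_f, collapse = ", "))
  if ((mutation_rate > 0 || error_rate > 0) && is.null(freqs))
    stop_invalid("freqs is required when mutation_rate or error_rate > 0")
  loci <- attr(mother, "loci")
  n_clutches <- nrow(plan$proportions)
  clutch_sizes <- rep_len(as.integer(clutch_sizes), n_clutches)
  ladders <- if (!is.null(freqs))
    lapply(freqs, function(p) as.integer(names(p)))
  with_seed(seed, {
    lapply(seq_len(n_clutches), function(k) {
      size <- clutch_sizes[k]
      sire <- sample(plan$father_ids, size, TRUE, plan$proportions[k, ])
      geno <- lapply(stats::setNames(loci, loci), function(loc) {
        mom <- locus_alleles(mother, loc)[1L, ]
        dadm <- locus_alleles(fathers, loc)
        ladder <- if (!is.null(ladders)) ladders[[loc]] else
          sort(unique(c(mom, dadm)))
        m <- t(vapply(seq_len(size), function(e) {
          c(transmit(mom, ladder, mutation_rate),
            transmit(dadm[match(sire[e], fathers$id), ], ladder,
                     mutation_rate))
        }, integer(2L)))
        if (error_rate > 0) {
          hit <- which(stats::runif(length(m)) < error_rate)
          m[hit] <- sample(ladder, length(hit), TRUE)
        }
        m
      })
      emerged <- max(1L, stats::rbinom(1L, size, emergence_prob))
      n_samp <- min(sample_n, emerged, size)
      keep <- sort(sample.int(size, n_samp))
      ids <- sprintf("%s_c%d_h%02d", plan$female_id, k, seq_len(n_samp))
      h <- genotype_table(ids, lapply(geno, function(m)
        m[keep, , drop = FALSE]))
      dead_in_nest <- stats::rbinom(1L, max(emerged, 1L), 0.03)
      live_in_nest <- stats::rbinom(1L, max(emerged, 1L), 0.02)
      inv <- nest_inventory(H = emerged, T_total = size,
                            L = min(live_in_nest, emerged),
                            D = min(dead_in_nest,
                                    emerged - min(live_in_nest, emerged)))
      clutch(plan$female_id, k, h, inventory = inv,
             lay_date = season_start + internesting_days * (k - 1L),
             incubation_days = round(stats::rnorm(1L, 55, 3)),
             true_fathers = sire[keep])
    })
  })
}

#' Simulate a whole nesting study
#'
#' Convenience wrapper assembling a season like the one the analysis targets:
#' females laying 1-3 clutches of ~100 eggs with up to 20 hatchlings sampled
#' per clutch, 1-5 fathers per female with Dirichlet siring proportions, and
#' an optional per-transition remating probability that introduces a new
#' father from clutch 2 onwards.
#'
#' @param n_females number of renesting females (default 16).
#' @param n_males size of the male pool to draw fathers from.
#' @param freqs optional [allele_freqs]; default: 7 loci with 14-25 alleles.
#' @param clutches_per_female sampler or fixed count; default samples 2 with
#'   occasional 3rd clutches (weights 0.1/0.65/0.25 for 1/2/3).
#' @param father_count_probs sampling weights for 1..5 fathers per female;
#'   default heavily favours single paternity (0.72, 0.12, 0.08, 0.04, 0.04).
#' @param remating_prob probability, per clutch transition, that a new male
#'   enters the sperm store with a Beta(2,2)-distributed fresh proportion.
#' @param mutation_rate,error_rate per-transmission / per-call rates.
#' @param sample_n hatchlings sampled per clutch.
#' @param seed optional integer seed.
#' @return List with `freqs`, `mothers`, `males`, `plans` (per female),
#'   `clutches` (flat list, ordered by female then clutch).
#' @export
sim_study <- function(n_females = 16L, n_males = 40L, freqs = NULL,
                      clutches_per_female = NULL,
                      father_count_probs = c(0.72, 0.12, 0.08, 0.04, 0.04),
                      remating_prob = 0, mutation_rate = 0, error_rate = 0,
                      sample_n = 20L, seed = NULL) {
  with_seed(seed, {
    if (is.null(freqs)) freqs <- gen_allele_freqs(7L, c(14L, 25L))
    adults <- sim_adults(freqs, n_females, n_males)
    plans <- list()
    clutches <- list()
    for (i in seq_len(n_females)) {
      fem <- adults$females$id[i]
      n_cl <- if (is.null(clutches_per_female))
        sample(1:3, 1L, prob = c(0.10, 0.65, 0.25))
      else check_count(clutches_per_female, "clutches_per_female", 1L)
      k0 <- sample(seq_along(father_count_probs), 1L,
                   prob = father_count_probs)
      sires <- sample(adults$males$id, k0)
      w <- stats::rgamma(k0, shape = 3)
      base <- w / sum(w)
      p <- matrix(rep(base, each = n_cl), nrow = n_cl)
      extra <- character()
      if (n_cl > 1L && remating_prob > 0) {
        for (k in 2:n_cl) {
          if (stats::runif(1L) < remating_prob) {
            newm <- sample(setdiff(adults$males$id, c(sires, extra)), 1L)
            fresh <- stats::rbeta(1L, 2, 2)
            p <- cbind(p, 0)
            p[k:n_cl, ] <- cbind(p[k:n_cl, -ncol(p), drop = FALSE] *
                                   (1 - fresh), fresh)
            extra <- c(extra, newm)
          }
        }
      }
      plan <- mating_plan(fem, c(sires, extra), p)
      plans[[fem]] <- plan
      clutches <- c(clutches, sim_clutches(
        plan, adults$females[i, , drop = FALSE], adults$males,
        sample_n = sample_n, mutation_rate = mutation_rate,
        error_rate = error_rate, freqs = freqs))
    }
    list(freqs = freqs, mothers = adults$females, males = adults$males,
         plans = plans, clutches = clutches)
  })
}
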