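#' Sorensen similarity of the father sets of two clutches
#'
#' `QS = 2C / (A + B) * 100`, where `A` and `B` are the father counts of the
#' two clutches and `C` the number of fathers shared between them.
#'
#' @param A,B father counts (>= 1).
#' @param C shared father count (`C <= min(A, B)`).
#' @return Similarity in percent.
#' @examples
#' sorensen_qs(2, 2, 1)  # 50
#' @export
sorensen_qs <- function(A, B, C) {
  A <- check_count(A, "A", min = 1L); B <- check_count(B, "B", min = 1L)
  C <- check_count(C, "C")
  if (C > min(A, B)) stop_invalid("C cannot exceed min(A, B)")
  2 * C / (A + B) * 100
}

#' Probability a sire is absent from a sample by chance
#'
#' For a male siring proportion `f` of the sperm store, the probability that
#' none of `n` sampled hatchlings are his is `p_f = (1 - f)^n`. Small values
#' mean his absence from a later clutch is unlikely under random sampling of
#' well-mixed stored sperm, pointing to remating or depletion.
#'
#' @param f siring proportion in `[0, 1]`.
#' @param n number of hatchlings sampled (>= 1).
#' @return The probability `(1 - f)^n`.
#' @examples
#' prob_nonappearance(0.5, 2)  # 0.25
#' @export
prob_nonappearance <- function(f, n) {
  f <- check_prob(f, "f")
  n <- check_count(n, "n", min = 1L)
  (1 - f)^n
}

#' Classify father turnover between two consecutive clutches
#'
#' Fathers present in the first clutch but absent from the second are tested
#' with `p_f = (1 - f)^n`: `p_f >= alpha` is consistent with chance or sperm
#' depletion, `p_f < alpha` means the disappearance is unlikely due to
#' chance. Symmetrically, a father newly appearing in the second clutch is
#' tested with his combined-clutch proportion against the first clutch's
#' sample size; an improbably large new contribution indicates remating
#' between nesting events.
#'
#' @param assign1,assign2 `father_assignment`s of the earlier and later
#'   clutch.
#' @param alpha significance threshold (default 0.05).
#' @param f_mode how to estimate a disappearing father's proportion:
#'   `"first-clutch"` (stored sperm well-mixed, first clutch is the best
#'   estimate) or `"combined"` (pool both clutches).
#' @param max_mismatch_loci passed to [match_fathers].
#' @return List with `matches` (the [match_fathers] result) and
#'   `transitions`, a data frame with one row per father: `father`,
#'   `status` (retained / disappeared / appeared), `f`, `n`, `p_f`,
#'   `classification`. Empty clutches are rejected.
#' @export
classify_transitions <- function(assign1, assign2, alpha = 0.05,
                                 f_mode = c("first-clutch", "combined"),
                                 max_mismatch_loci = 0L) {
  f_mode <- match.arg(f_mode)
  alpha <- check_prob(alpha, "alpha")
  if (assign1$n == 0L || assign2$n == 0L)
    stop_invalid("both clutches need sampled hatchlings")
  m <- match_fathers(assign1, assign2, max_mismatch_loci)
  n1 <- assign1$n; n2 <- assign2$n
  rows <- list()
  for (g in names(assign1$groups)) {
    j <- match(g, m$pairs$group_a)
    size1 <- length(assign1$groups[[g]])
    if (!is.na(j)) {
      rows[[length(rows) + 1L]] <- data.frame(
        father = paste0("1:", g), status = "retained", f = NA_real_,
        n = NA_integer_, p_f = NA_real_, classification = "retained",
        stringsAsFactors = FALSE)
    } else {
      f <- if (f_mode == "first-clutch") size1 / n1
           else size1 / (n1 + n2)
      p <- prob_nonappearance(f, n2)
      rows[[length(rows) + 1L]] <- data.frame(
        father = paste0("1:", g), status = "disappeared", f = f, n = n2,
        p_f = p,
        classification = if (p >= alpha) "chance or sperm depletion"
                         else "unlikely due to chance",
        stringsAsFactors = FALSE)
    }
  }
  for (g in setdiff(names(assign2$groups), m$pairs$group_b)) {
    size2 <- length(assign2$groups[[g]])
    f <- size2 / (n1 + n2)     # combined estimate for a newcomer
    p <- prob_nonappearance(f, n1)
    rows[[length(rows) + 1L]] <- data.frame(
      father = paste0("2:", g), status = "appeared", f = f, n = n1,
      p_f = p,
      classification = if (p >= alpha) "chance (sperm mixing or remating)"
                       else "remating-consistent",
      stringsAsFactors = FALSE)
  }
  list(matches = m, transitions = do.call(rbind, rows))
}

#' Probability that multiple paternity is detected in a finite sample
#'
#' With siring proportions `f_1..f_k`, a sample of `n` hatchlings reveals
#' multiple paternity unless every hatchling happens to come from the same
#' father; the analytic detection probability is `1 - sum(f_i^n)` (the
#' single-father events are disjoint). Simulation mode estimates the same
#' quantity by seeded Monte-Carlo.
#'
#' @param f vector of siring proportions summing to 1.
#' @param n sample size (>= 1).
#' @param mode `"analytic"` or `"simulation"`.
#' @param reps Monte-Carlo replicates (simulation mode).
#' @param seed optional integer seed (simulation mode).
#' @return Detection probability; for a single father, 0 with a `note`
#'   attribute.
#' @examples
#' detection_power(c(0.5, 0.5), 20)        # 1 - 2 * 0.5^20
#' detection_power(c(0.9, 0.1), 20)        # ~0.878
#' @export
detection_power <- function(f, n, mode = c("analytic", "simulation"),
                            reps = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(f) || any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop_invalid("f must be non-negative proportions summing to 1")
  n <- check_count(n, "n", min = 1L)
  if (length(f) == 1L)
    return(structure(0, note = "single father: nothing to detect"))
  if (mode == "analytic") return(1 - sum(f^n))
  reps <- check_count(reps, "reps", min = 1L)
  with_seed(seed, {
    hits <- 0L
    for (r in seq_len(reps)) {
      s <- sample.int(length(f), n, replace = TRUE, prob = f)
      if (length(unique(s)) > 1L) hits <- hits + 1L
    }
    hits / reps
  })
}

# chain-match one female's clutch assignments (ordered by clutch order) into
# season-level father identities; returns list of fathers, each a list of
# per-locus attributed alleles merged across the clutches he appears in
female_father_register <- function(assigns) {
  reg <- list()   # each: list(genotype, clutches, cur_group)
  for (a in seq_along(assigns)) {
    cur <- assigns[[a]]
    if (a > 1L) {
      m <- match_fathers(assigns[[a - 1L]], cur, 0L)
      taken <- character()
      for (r in seq_along(reg)) {
        pg <- reg[[r]]$cur_group
        j <- if (is.na(pg)) NA_integer_ else match(pg, m$pairs$group_a)
        if (!is.na(j)) {
          g <- m$pairs$group_b[j]
          reg[[r]]$genotype <- merge_father(reg[[r]]$genotype,
                                            cur$fathers[[g]])
          reg[[r]]$clutches <- c(reg[[r]]$clutches, a)
          reg[[r]]$cur_group <- g
          taken <- c(taken, g)
        } else reg[[r]]$cur_group <- NA_character_
      }
      new_groups <- setdiff(names(cur$groups), taken)
    } else new_groups <- names(cur$groups)
    for (g in new_groups)
      reg[[length(reg) + 1L]] <- list(genotype = cur$fathers[[g]],
                                      clutches = a, cur_group = g)
  }
  reg
}

merge_father <- function(x, y) {
  for (loc in names(x)) {
    al <- sort(unique(c(x[[loc]]$alleles, y[[loc]]$alleles)))
    x[[loc]]$alleles <- al[seq_len(min(2L, length(al)))]
    x[[loc]]$inferred <- sort(unique(c(x[[loc]]$inferred, y[[loc]]$inferred)))
  }
  x
}

fathers_compatible <- function(ga, gb) {
  all(vapply(names(ga), function(loc)
    father_locus_compatible(ga[[loc]], gb[[loc]]), logical(1L)))
}

#' Breeding sex ratio of a nesting assemblage
#'
#' The number of distinct sires contributing to the sampled clutches divided
#' by the number of females. Given per-female father counts (a numeric
#' vector), the ratio is `sum(counts) / length(counts)` — appropriate when
#' no male is shared between females. Given per-female lists of
#' `father_assignment`s, distinct sires are counted after matching
#' reconstructed fathers across each female's clutches and then across
#' females (a cross-female match merges the two sires into one).
#'
#' @param x numeric vector of per-female father counts, or a list (one
#'   element per female) of lists of `father_assignment`s ordered by clutch.
#' @param scope `"all-clutches"` or `"first-clutch-only"`.
#' @return List with `bsr` (males per female), `n_fathers`, `n_females`,
#'   and `cross_female_matches`.
#' @examples
#' counts <- c(1, 1, 3, 1, 1, 1, 1, 1, 1, 1, 1, 5, 1, 3, 2, 1)
#' breeding_sex_ratio(counts)$bsr  # 1.5625
#' @export
breeding_sex_ratio <- function(x, scope = c("all-clutches",
                                            "first-clutch-only")) {
  scope <- match.arg(scope)
  if (is.numeric(x)) {
    if (length(x) < 1L || any(x < 1)) stop_invalid("need >= 1 father per female")
    return(list(bsr = sum(x) / length(x), n_fathers = sum(x),
                n_females = length(x), cross_female_matches = 0L))
  }
  stopifnot(is.list(x), length(x) >= 1L)
  regs <- lapply(x, function(assigns) {
    if (inherits(assigns, "father_assignment")) assigns <- list(assigns)
    ord <- order(vapply(assigns, function(a) a$order %||% 1L, numeric(1L)))
    assigns <- assigns[ord]
    if (scope == "first-clutch-only") assigns <- assigns[1L]
    female_father_register(assigns)
  })
  # cross-female matching: any compatible pair of registered sires from two
  # different females collapses to a single male
  flat <- do.call(rbind, lapply(seq_along(regs), function(i)
    data.frame(female = i, idx = seq_along(regs[[i]]))))
  nf <- nrow(flat)
  parent <- seq_len(nf)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  matches <- 0L
  if (nf > 1L) for (i in seq_len(nf - 1L)) for (j in seq(i + 1L, nf)) {
    if (flat$female[i] == flat$female[j]) next
    ga <- regs[[flat$female[i]]][[flat$idx[i]]]$genotype
    gb <- regs[[flat$female[j]]][[flat$idx[j]]]$genotype
    if (fathers_compatible(ga, gb)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) { parent[rj] <- ri; matches <- matches + 1L }
    }
  }
  distinct <- length(unique(vapply(seq_len(nf), find, integer(1L))))
  list(bsr = distinct / length(x), n_fathers = distinct,
       n_females = length(x), cross_female_matches = matches)
}

#' Extrapolate female and male population sizes from a nest census
#'
#' Divides the season's total nest count by the regional clutch-frequency
#' range to bound the number of nesting females, then multiplies by the
#' breeding sex ratio to bound the number of contributing males. Rounding is
#' to the nearest integer at each step.
#'
#' @param total_nests nests laid in the season.
#' @param clutch_freq_low,clutch_freq_high nests per female per season
#'   (low <= high); the high frequency gives the lower female bound.
#' @param bsr breeding sex ratio (males per female).
#' @return List with `females` and `males`, each `c(lower, upper)`.
#' @examples
#' extrapolate_population(634, 3.9, 5.4, 1.46)
#' # females 117-163, males 171-238
#' @export
extrapolate_population <- function(total_nests, clutch_freq_low,
                                   clutch_freq_high, bsr) {
  total_nests <- check_count(total_nests, "total_nests", min = 1L)
  if (!is.numeric(clutch_freq_low) || !is.numeric(clutch_freq_high) ||
      clutch_freq_low <= 0 || clutch_freq_high <= 0)
    stop_invalid("clutch frequencies must be positive")
  if (clutch_freq_low > clutch_freq_high)
    stop_invalid("clutch_freq_low must be <= clutch_freq_high")
  if (!is.numeric(bsr) || bsr <= 0) stop_invalid("bsr must be positive")
  females <- c(round(total_nests / clutch_freq_high),
               round(total_nests / clutch_freq_low))
  males <- round(females * bsr)
  list(females = females, males = males)
}

#' Compare two breeding-sex-ratio estimates
#'
#' Fisher's exact test on the 2x2 table of (fathers, females) counts behind
#' each estimate.
#'
#' @param fathers1,females1 counts behind the first estimate.
#' @param fathers2,females2 counts behind the second estimate.
#' @return The `htest` object from [stats::fisher.test].
#' @export
compare_bsr <- function(fathers1, females1, fathers2, females2) {
  stats::fisher.test(matrix(c(fathers1, females1, fathers2, females2), 2L))
}

#' Season-level mating-system summary
#'
#' Aggregates per-clutch paternity fits into the season's mating-system
#' inference: Sorensen similarity and father matching for each female's
#' consecutive clutch pairs, chance-vs-remating classification of every
#' father transition, and the assemblage breeding sex ratio under both
#' scopes.
#'
#' @param fits list of [clutch_paternity] fits (any order; grouped by
#'   mother id and ordered by clutch order internally).
#' @param alpha significance threshold for the transition test.
#' @param f_mode proportion estimate for disappearing fathers; see
#'   [classify_transitions].
#' @param max_mismatch_loci father-matching tolerance.
#' @return Object of class `mating_system`: `pairs` (data frame of QS rows),
#'   `transitions` (data frame), `bsr_all`, `bsr_first`, `females`, `fits`.
#' @export
mating_system <- function(fits, alpha = 0.05,
                          f_mode = c("first-clutch", "combined"),
                          max_mismatch_loci = 0L) {
  f_mode <- match.arg(f_mode)
  stopifnot(length(fits) >= 1L)
  mothers <- vapply(fits, function(f) f$mother_id, character(1L))
  by_female <- split(fits, mothers)
  by_female <- lapply(by_female, function(fl)
    fl[order(vapply(fl, function(f) f$order, numeric(1L)))])
  pair_rows <- list(); trans_rows <- list()
  for (fem in names(by_female)) {
    fl <- by_female[[fem]]
    if (length(fl) < 2L) next
    for (t in seq_len(length(fl) - 1L)) {
      a <- fl[[t]]; b <- fl[[t + 1L]]
      ct <- classify_transitions(a, b, alpha = alpha, f_mode = f_mode,
                                 max_mismatch_loci = max_mismatch_loci)
      qs <- sorensen_qs(ct$matches$A, ct$matches$B, ct$matches$C)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        mother_id = fem, pair = paste0(a$order, "-", b$order),
        A = ct$matches$A, B = ct$matches$B, C = ct$matches$C, QS = qs,
        stringsAsFactors = FALSE)
      tr <- ct$transitions
      if (!is.null(tr) && nrow(tr)) {
        tr$mother_id <- fem
        tr$pair <- paste0(a$order, "-", b$order)
        trans_rows[[length(trans_rows) + 1L]] <- tr
      }
    }
  }
  bsr_all <- breeding_sex_ratio(unname(by_female), "all-clutches")
  bsr_first <- breeding_sex_ratio(unname(by_female), "first-clutch-only")
  structure(list(
    pairs = if (length(pair_rows)) do.call(rbind, pair_rows)
            else data.frame(),
    transitions = if (length(trans_rows)) do.call(rbind, trans_rows)
                  else data.frame(),
    bsr_all = bsr_all, bsr_first = bsr_first,
    females = names(by_female), fits = by_female,
    alpha = alpha, f_mode = f_mode), class = "mating_system")
}

#' @export
print.mating_system <- function(x, ...) {
  nmp <- sum(vapply(unlist(x$fits, recursive = FALSE),
                    function(f) f$mp$mp, logical(1L)))
  ncl <- length(unlist(x$fits, recursive = FALSE))
  cat(sprintf("Mating-system summary: %d females, %d clutches (%d MP)\n",
              length(x$females), ncl, nmp))
  cat(sprintf("  BSR all clutches: %.3f (%d fathers / %d females)\n",
              x$bsr_all$bsr, x$bsr_all$n_fathers, x$bsr_all$n_females))
  cat(sprintf("  BSR first clutches: %.3f (%d fathers / %d females)\n",
              x$bsr_first$bsr, x$bsr_first$n_fathers, x$bsr_first$n_females))
  if (nrow(x$pairs)) {
    cat("  Clutch-pair similarity:\n")
    print.data.frame(x$pairs, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.mating_system <- function(object, ...) {
  clutch_tab <- do.call(rbind, lapply(unlist(object$fits, recursive = FALSE),
                                      summary))
  list(clutches = clutch_tab, pairs = object$pairs,
       transitions = object$transitions,
       bsr_all = object$bsr_all$bsr, bsr_first = object$bsr_first$bsr)
}

#' Plot paternal contributions across a female's clutches
#'
#' Stacked bars of the siring proportions per clutch for each female with a
#' multiply-sired clutch (the classic subsequent-clutch paternity figure).
#'
#' @param x a `mating_system` object.
#' @param ... passed to [graphics::barplot].
#' @return Invisibly, the matrix list plotted.
#' @export
plot.mating_system <- function(x, ...) {
  mp_fem <- Filter(function(fl) any(vapply(fl, function(f) f$k > 1L,
                                           logical(1L))), x$fits)
  if (length(mp_fem) == 0L) {
    message("no multiply-sired clutches to plot")
    return(invisible(NULL))
  }
  old <- graphics::par(mfrow = c(1, length(mp_fem)))
  on.exit(graphics::par(old))
  out <- list()
  for (fem in names(mp_fem)) {
    fl <- mp_fem[[fem]]
    kmax <- max(vapply(fl, function(f) f$k, integer(1L)))
    m <- vapply(fl, function(f) c(unname(f$f), rep(0, kmax - f$k)),
                numeric(kmax))
    m <- matrix(m, nrow = kmax)
    colnames(m) <- vapply(fl, function(f)
      sprintf("clutch %d (n=%d)", f$order, f$n), character(1L))
    graphics::barplot(m, main = fem, ylab = "proportion sired", ...)
    out[[fem]] <- m
  }
  invisible(out)
}
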