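#' Candidate paternal alleles after subtracting the maternal contribution
#'
#' For each hatchling and locus, the maternal allele is subtracted from the
#' hatchling genotype: if exactly one hatchling allele matches the mother,
#' the other allele is paternal (certain); if both match, either could be
#' maternal and the candidate set is both alleles (ambiguous); if neither
#' matches, the locus is flagged as a mismatch (never silently dropped).
#' A hatchling mismatching at more than `max_mismatch` loci is reported as a
#' candidate foreign hatchling (not this mother's offspring) and excluded
#' with a warning.
#'
#' @param mother the mother's genotype (1-row `genotype_table`).
#' @param hatchlings `genotype_table` of the clutch's sampled hatchlings.
#' @param max_mismatch mismatch-locus tolerance before a hatchling is
#'   declared foreign (default 2).
#' @return Object of class `paternal_alleles`: candidate allele sets per
#'   hatchling per locus, certainty and mismatch flags, and the excluded
#'   foreign hatchlings.
#' @examples
#' mom <- genotype_table("M", list(L1 = cbind(100, 102)))
#' kid <- genotype_table("h1", list(L1 = cbind(100, 106)))
#' paternal_allele_sets(mom, kid)$candidates$h1$L1  # 106, certain
#' @export
paternal_allele_sets <- function(mother, hatchlings, max_mismatch = 2L) {
  stopifnot(inherits(mother, "genotype_table"),
            inherits(hatchlings, "genotype_table"))
  if (nrow(mother) != 1L) stop_invalid("mother must be a single genotype")
  loci <- attr(mother, "loci")
  if (!identical(loci, attr(hatchlings, "loci")))
    stop_invalid("mother and hatchlings must share the locus panel")
  ids <- hatchlings$id
  nh <- length(ids); nl <- length(loci)
  cand <- stats::setNames(rep(list(stats::setNames(vector("list", nl), loci)),
                              nh), ids)
  certain <- matrix(FALSE, nh, nl, dimnames = list(ids, loci))
  mismatch <- matrix(FALSE, nh, nl, dimnames = list(ids, loci))
  for (loc in loci) {
    M <- locus_alleles(mother, loc)[1L, ]
    M <- M[M != 0L]
    H <- locus_alleles(hatchlings, loc)
    for (i in seq_len(nh)) {
      h <- H[i, ]; h <- h[h != 0L]
      if (length(h) == 0L || length(M) == 0L) next  # missing: uninformative
      if (length(h) == 1L) {
        # single-allele call: paternal only if it cannot be maternal
        if (!h %in% M) {
          cand[[i]][[loc]] <- h; certain[i, loc] <- TRUE
        }
        next
      }
      inM <- h %in% M
      if (all(inM)) {
        u <- unique(h)
        cand[[i]][[loc]] <- u
        certain[i, loc] <- length(u) == 1L  # homozygote: paternal is forced
      } else if (any(inM)) {
        cand[[i]][[loc]] <- h[!inM][1L]
        certain[i, loc] <- TRUE
      } else {
        mismatch[i, loc] <- TRUE
      }
    }
  }
  n_mm <- rowSums(mismatch)
  foreign <- ids[n_mm > max_mismatch]
  if (length(foreign)) {
    warning("excluding ", length(foreign), " candidate foreign hatchling(s): ",
            paste(foreign, collapse = ", "))
    keep <- !(ids %in% foreign)
    excluded <- data.frame(id = foreign, n_mismatch = n_mm[foreign])
    cand <- cand[keep]
    certain <- certain[keep, , drop = FALSE]
    mismatch <- mismatch[keep, , drop = FALSE]
    ids <- ids[keep]
  } else excluded <- data.frame(id = character(), n_mismatch = integer())
  structure(list(mother_id = mother$id, ids = ids, loci = loci,
                 candidates = cand, certain = certain, mismatch = mismatch,
                 excluded = excluded, n = length(ids)),
            class = "paternal_alleles")
}

# distinct certain paternal alleles per locus (pigeonhole & MP-rule input)
certain_allele_counts <- function(table) {
  vapply(table$loci, function(loc) {
    al <- unlist(lapply(seq_along(table$ids), function(i)
      if (table$certain[i, loc]) table$candidates[[i]][[loc]]))
    length(unique(al))
  }, integer(1L))
}

#' Call multiple paternity under the conservative allele-count rule
#'
#' A clutch is multiply sired when more than two certain paternal alleles
#' are present at two or more loci; a single locus with three or more
#' paternal alleles is conservatively attributed to mutation and does not
#' trigger the call.
#'
#' @param x a `paternal_alleles` table or a `father_assignment`.
#' @return List with `mp` (logical), `loci_excess` (loci showing >= 3
#'   certain paternal alleles), and `mutation_attributed` (TRUE when exactly
#'   one such locus was set aside as a presumed mutation).
#' @export
call_multiple_paternity <- function(x) {
  table <- if (inherits(x, "father_assignment")) x$table else x
  stopifnot(inherits(table, "paternal_alleles"))
  counts <- certain_allele_counts(table)
  excess <- names(counts)[counts >= 3L]
  list(mp = length(excess) >= 2L, loci_excess = excess,
       mutation_attributed = length(excess) == 1L)
}

# ---- partition feasibility ------------------------------------------------
# A sibship group is feasible at a locus iff one father genotype {x, y} can
# cover every hatchling's candidate set (each set must contain x or y).
# Candidate sets have size 1 (certain) or 2 (maternal/paternal ambiguous).
locus_feasible <- function(sets) {
  if (length(sets) == 0L) return(TRUE)
  certain <- unique(unlist(sets[lengths(sets) == 1L]))
  if (length(certain) > 2L) return(FALSE)
  amb <- sets[lengths(sets) == 2L]
  if (length(certain) == 2L)
    return(all(vapply(amb, function(s) any(s %in% certain), logical(1L))))
  uncovered <- amb[!vapply(amb, function(s) any(s %in% certain), logical(1L))]
  if (length(uncovered) == 0L) return(TRUE)
  slots <- 2L - length(certain)
  if (slots == 0L) return(FALSE)
  common <- Reduce(intersect, uncovered)
  if (length(common) >= 1L) return(TRUE)
  if (slots < 2L) return(FALSE)
  # need two free alleles covering all sets: try every pair in the union
  u <- unique(unlist(uncovered))
  for (i in seq_along(u)) for (j in seq_len(i))
    if (all(vapply(uncovered, function(s) u[i] %in% s || u[j] %in% s,
                   logical(1L)))) return(TRUE)
  FALSE
}

# ---- tie-break key --------------------------------------------------------
# canonical comparison among equally minimal partitions: fewer groups first,
# then lexicographically smaller sorted group-size profile, then
# lexicographically smallest id sequence of groups ordered by smallest member
partition_key <- function(groups, ids) {
  sizes <- sort(lengths(groups))
  named <- lapply(groups, function(g) sort(ids[g]))
  ord <- order(vapply(named, `[`, character(1L), 1L))
  list(k = length(groups), sizes = sizes,
       flat = unlist(named[ord], use.names = FALSE))
}

key_less <- function(a, b) {
  if (a$k != b$k) return(a$k < b$k)
  for (i in seq_along(a$sizes))
    if (a$sizes[i] != b$sizes[i]) return(a$sizes[i] < b$sizes[i])
  for (i in seq_along(a$flat))
    if (a$flat[i] != b$flat[i]) return(a$flat[i] < b$flat[i])
  FALSE
}

#' Partition a clutch into the minimum number of paternal sibships
#'
#' The exact method runs a branch-and-bound search over hatchling-to-group
#' assignments: a group is admissible when, at every informative locus, one
#' father genotype (at most two alleles) can cover every member's candidate
#' paternal allele set, with maternal/paternal ambiguity resolved inside the
#' search rather than greedily beforehand. The greedy method places each
#' hatchling in the first compatible group. Hatchlings are processed in
#' sorted id order, and ties among equally minimal partitions are broken by
#' the canonical key (sorted group sizes, then member ids), so the exact
#' result is invariant to input order.
#'
#' If exactly one locus shows three or more certain paternal alleles while
#' all others show at most two, that locus is designated a presumed mutation
#' (the conservative multiple-paternity rule) and dropped from the partition
#' constraints.
#'
#' @param table a `paternal_alleles` table for one clutch.
#' @param method `"exact"` (default) or `"greedy"`.
#' @return Object of class `father_assignment`: sibship `groups` (named
#'   `F1`, `F2`, ... in decreasing size), reconstructed father genotypes,
#'   siring proportions `f`, minimum father count `k`, the pigeonhole
#'   `lower_bound`, the `mutation_locus` if one was set aside, and the
#'   multiple-paternity call.
#' @export
min_father_partition <- function(table, method = c("exact", "greedy")) {
  stopifnot(inherits(table, "paternal_alleles"))
  method <- match.arg(method)
  mp <- call_multiple_paternity(table)
  counts <- certain_allele_counts(table)
  # a presumed-mutation locus can only be set aside when other loci remain
  # to carry the constraints; a one-locus panel keeps its pigeonhole signal
  mutation_locus <- if (mp$mutation_attributed && length(table$loci) >= 2L)
    mp$loci_excess else NA_character_
  loci <- setdiff(table$loci, mutation_locus)
  n <- table$n
  if (n == 0L) stop_invalid("empty clutch")
  ord <- order(table$ids)          # input-order invariance
  lower <- max(1L, ceiling(max(c(0L, counts[loci])) / 2))

  # per-locus candidate sets in flat form for cheap incremental checks
  cand <- lapply(stats::setNames(loci, loci), function(loc)
    lapply(seq_len(n), function(i) table$candidates[[i]][[loc]]))
  new_group <- function(i) {
    list(members = i, sets = lapply(cand, function(cl)
      if (is.null(cl[[i]])) list() else list(cl[[i]])))
  }
  # returns the grown group state, or NULL when member i cannot join
  add_member <- function(gs, i) {
    for (loc in loci) {
      s <- cand[[loc]][[i]]
      if (!is.null(s) &&
          !locus_feasible(c(gs$sets[[loc]], list(s)))) return(NULL)
    }
    gs$members <- c(gs$members, i)
    for (loc in loci) {
      s <- cand[[loc]][[i]]
      if (!is.null(s)) gs$sets[[loc]] <- c(gs$sets[[loc]], list(s))
    }
    gs
  }

  greedy_states <- list()
  for (i in ord) {
    placed <- FALSE
    for (g in seq_along(greedy_states)) {
      ng <- add_member(greedy_states[[g]], i)
      if (!is.null(ng)) { greedy_states[[g]] <- ng; placed <- TRUE; break }
    }
    if (!placed) greedy_states[[length(greedy_states) + 1L]] <- new_group(i)
  }
  greedy_groups <- lapply(greedy_states, `[[`, "members")

  groups <- greedy_groups
  if (method == "exact" && length(greedy_groups) > lower) {
    # iterative deepening: the smallest k admitting a feasible partition is
    # the minimum; at that k every partition is enumerated so the canonical
    # tie-break key picks a deterministic representative
    best <- NULL
    for (k_target in seq(lower, length(greedy_groups))) {
      search <- function(pos, gs) {
        if (pos > n) {
          grp <- lapply(gs, `[[`, "members")
          key <- partition_key(grp, table$ids)
          if (is.null(best) || key_less(key, best$key))
            best <<- list(groups = grp, key = key)
          return(invisible())
        }
        i <- ord[pos]
        for (g in seq_along(gs)) {
          ng <- add_member(gs[[g]], i)
          if (!is.null(ng)) { gs2 <- gs; gs2[[g]] <- ng; search(pos + 1L, gs2) }
        }
        if (length(gs) < k_target)
          search(pos + 1L, c(gs, list(new_group(i))))
        invisible()
      }
      search(2L, list(new_group(ord[1L])))
      if (!is.null(best)) break
    }
    groups <- best$groups
  }

  # order groups by decreasing size then smallest member id
  first_id <- vapply(groups, function(g) min(table$ids[g]), character(1L))
  groups <- groups[order(-lengths(groups), first_id)]
  names(groups) <- paste0("F", seq_along(groups))
  fathers <- lapply(groups, function(g)
    reconstruct_father(table, g, loci, mutation_locus))
  f <- lengths(groups) / n
  structure(list(mother_id = table$mother_id,
                 groups = lapply(groups, function(g) sort(table$ids[g])),
                 fathers = fathers, f = f, k = length(groups), n = n,
                 lower_bound = lower, method = method,
                 mutation_locus = mutation_locus, mp = mp, table = table),
            class = "father_assignment")
}

# attribute alleles to a group's father: `alleles` are forced (certain or
# the only way to cover the members), `inferred` complete the coverage when
# a deterministic smallest choice had to be made
reconstruct_father <- function(table, members, loci, mutation_locus) {
  out <- list()
  for (loc in table$loci) {
    if (!is.na(mutation_locus) && loc %in% mutation_locus) {
      out[[loc]] <- list(alleles = integer(), inferred = integer())
      next
    }
    sets <- lapply(members, function(i) table$candidates[[i]][[loc]])
    sets <- sets[!vapply(sets, is.null, logical(1L))]
    certain <- sort(unique(unlist(sets[lengths(sets) == 1L])))
    amb <- sets[lengths(sets) == 2L]
    uncovered <- amb[!vapply(amb, function(s) any(s %in% certain),
                             logical(1L))]
    inferred <- integer()
    if (length(uncovered)) {
      common <- sort(Reduce(intersect, uncovered))
      if (length(certain) == 1L || length(certain) == 0L) {
        if (length(common) >= 1L) inferred <- common[1L]
        else if (length(certain) == 0L) {
          u <- sort(unique(unlist(uncovered)))
          found <- FALSE
          for (x in u) {
            if (found) break
            for (y in u[u >= x]) {
              if (all(vapply(uncovered, function(s) x %in% s || y %in% s,
                             logical(1L)))) {
                inferred <- unique(c(x, y)); found <- TRUE; break
              }
            }
          }
        }
      }
    }
    out[[loc]] <- list(alleles = certain, inferred = inferred)
  }
  out
}

#' @export
print.father_assignment <- function(x, ...) {
  cat(sprintf("Paternal sibship partition: mother %s, %d hatchlings, %d father(s) [%s]\n",
              x$mother_id, x$n, x$k, x$method))
  for (g in names(x$groups))
    cat(sprintf("  %s: %d hatchlings (f = %.2f)\n", g,
                length(x$groups[[g]]), x$f[[g]]))
  if (!is.na(x$mutation_locus[1L]))
    cat("  locus", x$mutation_locus, "set aside as a presumed mutation\n")
  cat(sprintf("  multiple paternity: %s\n",
              if (x$mp$mp) paste("yes (", paste(x$mp$loci_excess,
                                                collapse = ", "), ")")
              else "no"))
  invisible(x)
}

#' @export
coef.father_assignment <- function(object, ...) object$f

# per-locus compatibility of two attributed allele sets: an empty set is
# uninformative; two full genotypes must be equal; a full genotype must
# contain a half-reconstructed father's allele; two single alleles can
# always coexist in one genotype
father_locus_compatible <- function(a, b) {
  if (length(a$alleles) == 0L || length(b$alleles) == 0L) return(TRUE)
  if (length(a$alleles) == 2L && length(b$alleles) == 2L)
    return(identical(a$alleles, b$alleles))
  if (length(a$alleles) == 2L) return(b$alleles %in% a$alleles)
  if (length(b$alleles) == 2L) return(a$alleles %in% b$alleles)
  TRUE
}

#' Match reconstructed fathers between two sibship partitions
#'
#' Two reconstructed fathers match when their attributed allele sets are
#' non-contradictory at all but at most `max_mismatch_loci` loci. Among all
#' one-to-one pairings the one matching the most fathers is returned (ties
#' broken by lexicographic group order), together with the father counts
#' `A`, `B` and shared count `C` used by the Sorensen similarity index.
#'
#' @param assign_a,assign_b `father_assignment` objects on the same panel.
#' @param max_mismatch_loci mismatching loci tolerated per pair (default 0).
#' @return List with `pairs` (data frame: `group_a`, `group_b`,
#'   `mismatch_loci`), `A`, `B`, `C`.
#' @export
match_fathers <- function(assign_a, assign_b, max_mismatch_loci = 0L) {
  stopifnot(inherits(assign_a, "father_assignment"),
            inherits(assign_b, "father_assignment"))
  ka <- assign_a$k; kb <- assign_b$k
  loci <- intersect(names(assign_a$fathers[[1L]]), names(assign_b$fathers[[1L]]))
  mm <- matrix(0L, ka, kb)
  for (i in seq_len(ka)) for (j in seq_len(kb))
    mm[i, j] <- sum(!vapply(loci, function(loc)
      father_locus_compatible(assign_a$fathers[[i]][[loc]],
                              assign_b$fathers[[j]][[loc]]), logical(1L)))
  ok <- mm <= max_mismatch_loci
  # maximum bipartite matching; k <= ~5 so enumerate assignments of A-groups
  best_pairs <- integer(0)
  best_size <- -1L
  search <- function(i, used_b, pairs) {
    if (i > ka) {
      if (length(pairs) / 2L > best_size) {
        best_size <<- length(pairs) / 2L; best_pairs <<- pairs
      }
      return(invisible())
    }
    upper <- length(pairs) / 2L + (ka - i + 1L)
    if (upper <= best_size) return(invisible())
    for (j in seq_len(kb))
      if (ok[i, j] && !(j %in% used_b))
        search(i + 1L, c(used_b, j), c(pairs, i, j))
    search(i + 1L, used_b, pairs)
    invisible()
  }
  search(1L, integer(), integer())
  pairs <- if (best_size > 0L)
    data.frame(group_a = names(assign_a$groups)[best_pairs[c(TRUE, FALSE)]],
               group_b = names(assign_b$groups)[best_pairs[c(FALSE, TRUE)]],
               mismatch_loci = mm[cbind(best_pairs[c(TRUE, FALSE)],
                                        best_pairs[c(FALSE, TRUE)])],
               stringsAsFactors = FALSE)
    else data.frame(group_a = character(), group_b = character(),
                    mismatch_loci = integer())
  list(pairs = pairs, A = ka, B = kb, C = nrow(pairs))
}

#' Fit the exclusion-paternity model to one clutch
#'
#' The main per-clutch fitting function: subtracts the maternal contribution
#' ([paternal_allele_sets]), finds the minimum-father sibship partition
#' ([min_father_partition]) and calls multiple paternity. Returns a classed
#' object carrying the clutch metadata alongside the assignment.
#'
#' @param clutch a [clutch] object.
#' @param mother the mother's genotype (1-row `genotype_table`).
#' @param method partition search method, `"exact"` or `"greedy"`.
#' @param max_mismatch foreign-hatchling mismatch tolerance.
#' @return Object of class `c("clutch_paternity", "father_assignment")` with
#'   the fields of [min_father_partition] plus `order` and `clutch`.
#' @examples
#' st <- sim_study(n_females = 2, seed = 42)
#' fit <- clutch_paternity(st$clutches[[1]],
#'                         st$mothers[1, ], method = "exact")
#' coef(fit)  # siring proportions
#' @export
clutch_paternity <- function(clutch, mother, method = c("exact", "greedy"),
                             max_mismatch = 2L) {
  stopifnot(inherits(clutch, "clutch"))
  if (!clutch$mother_id %in% mother$id)
    stop_invalid("mother table does not contain ", clutch$mother_id)
  mom <- mother[match(clutch$mother_id, mother$id), , drop = FALSE]
  table <- paternal_allele_sets(mom, clutch$hatchlings,
                                max_mismatch = max_mismatch)
  fit <- min_father_partition(table, method = method)
  fit$order <- clutch$order
  fit$clutch <- clutch
  class(fit) <- c("clutch_paternity", class(fit))
  fit
}

#' @export
summary.clutch_paternity <- function(object, ...) {
  data.frame(mother_id = object$mother_id, clutch_order = object$order,
             n = object$n, k_fathers = object$k, mp = object$mp$mp,
             f = paste(sprintf("%.2f", object$f), collapse = "/"),
             stringsAsFactors = FALSE)
}
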