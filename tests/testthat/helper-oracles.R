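# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (enumeration over genotype space, set
# partitions, numeric integration) and share no code with the package
# internals they check.

# all unordered genotypes of a locus with allele labels `al` and HWE probs
hwe_genotypes <- function(p) {
  al <- as.integer(names(p))
  g <- list()
  for (i in seq_along(al)) for (j in i:length(al)) {
    pr <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    g[[length(g) + 1L]] <- list(a = c(al[i], al[j]), pr = unname(pr))
  }
  g
}

# PI: probability two random individuals share a genotype
oracle_pi <- function(p) sum(vapply(hwe_genotypes(p), function(g) g$pr^2,
                                    numeric(1)))

# child genotypes (with probs) of a known parent pair
mendel_children <- function(m, f) {
  out <- list()
  for (i in 1:2) for (j in 1:2) {
    key <- paste(sort(c(m[i], f[j])), collapse = "/")
    out[[key]] <- (out[[key]] %||% 0) + 0.25
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# PE2: mother known; probability a random male is excluded as the father
oracle_pe2 <- function(p) {
  gts <- hwe_genotypes(p)
  total <- 0
  for (M in gts) for (F_ in gts) {
    kids <- mendel_children(M$a, F_$a)
    for (key in names(kids)) {
      C <- as.integer(strsplit(key, "/")[[1]])
      # candidate paternal alleles: allele whose partner appears in mother
      S <- unique(c(if (C[2] %in% M$a) C[1], if (C[1] %in% M$a) C[2]))
      p_excl <- sum(vapply(gts, function(R)
        if (!any(R$a %in% S)) R$pr else 0, numeric(1)))
      total <- total + M$pr * F_$pr * kids[[key]] * p_excl
    }
  }
  total
}

# PE3: no parent known; probability a random pair is excluded as the parents
oracle_pe3 <- function(p) {
  gts <- hwe_genotypes(p)
  total <- 0
  for (M in gts) for (F_ in gts) {
    kids <- mendel_children(M$a, F_$a)
    for (key in names(kids)) {
      C <- sort(as.integer(strsplit(key, "/")[[1]]))
      p_excl <- 0
      for (R1 in gts) for (R2 in gts) {
        can <- FALSE
        for (a in R1$a) for (b in R2$a)
          if (identical(sort(c(a, b)), C)) can <- TRUE
        if (!can) p_excl <- p_excl + R1$pr * R2$pr
      }
      total <- total + M$pr * F_$pr * kids[[key]] * p_excl
    }
  }
  total
}

# ---- minimum-father set-partition oracle ---------------------------------
# independent feasibility check: a sibship is one father's offspring iff at
# every locus some unordered allele pair covers every member's candidate set
oracle_group_ok <- function(table, members) {
  for (loc in table$loci) {
    sets <- Filter(Negate(is.null),
                   lapply(members, function(i) table$candidates[[i]][[loc]]))
    if (length(sets) == 0L) next
    u <- unique(unlist(sets))
    ok <- FALSE
    for (x in u) {
      for (y in u) {
        if (all(vapply(sets, function(s) x %in% s || y %in% s, logical(1))))
          ok <- TRUE
      }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

# enumerate all set partitions of 1..n (restricted growth strings), return
# the minimum number of single-father-feasible blocks
oracle_min_fathers <- function(table, ignore_loci = character()) {
  tab <- table
  if (length(ignore_loci)) tab$loci <- setdiff(tab$loci, ignore_loci)
  n <- tab$n
  best <- n
  recurse <- function(i, blocks) {
    if (length(blocks) >= best) return(invisible())
    if (i > n) { best <<- min(best, length(blocks)); return(invisible()) }
    for (b in seq_along(blocks)) {
      cand <- c(blocks[[b]], i)
      if (oracle_group_ok(tab, cand)) {
        nb <- blocks; nb[[b]] <- cand
        recurse(i + 1L, nb)
      }
    }
    recurse(i + 1L, c(blocks, list(i)))
  }
  recurse(2L, list(1L))
  best
}

# ---- numeric ellipsoid surface area --------------------------------------
# midpoint double integration of the first-fundamental-form area element
oracle_ellipsoid_sa <- function(a, b, c, n = 400L) {
  th <- (seq_len(n) - 0.5) * pi / n
  ph <- (seq_len(n) - 0.5) * 2 * pi / n
  s <- 0
  for (t in th) {
    integ <- sin(t) * sqrt(b^2 * c^2 * sin(t)^2 * cos(ph)^2 +
                           a^2 * c^2 * sin(t)^2 * sin(ph)^2 +
                           a^2 * b^2 * cos(t)^2)
    s <- s + sum(integ)
  }
  s * (pi / n) * (2 * pi / n)
}

# ---- random small paternity instances ------------------------------------
# Mendelian clutch from explicit parents over a tiny panel; returns the
# mother row, hatchling table and the true number of sampled sires
random_small_instance <- function(n_hatch, n_loci = 3L, n_alleles = 4L,
                                  n_fathers = NULL) {
  loci <- sprintf("L%d", seq_len(n_loci))
  alleles <- 100L + 2L * (seq_len(n_alleles) - 1L)
  rand_geno <- function() sort(sample(alleles, 2L, replace = TRUE))
  if (is.null(n_fathers)) n_fathers <- sample(1:3, 1L)
  mom <- lapply(loci, function(l) rand_geno())
  dads <- lapply(seq_len(n_fathers), function(i)
    lapply(loci, function(l) rand_geno()))
  sire <- sample(n_fathers, n_hatch, replace = TRUE)
  kid_m <- lapply(seq_along(loci), function(j)
    t(vapply(seq_len(n_hatch), function(h)
      sort(c(sample(mom[[j]], 1L), sample(dads[[sire[h]]][[j]], 1L))),
      integer(2))))
  names(kid_m) <- loci
  mom_m <- lapply(seq_along(loci), function(j) matrix(mom[[j]], ncol = 2))
  names(mom_m) <- loci
  list(mother = genotype_table("MOM", mom_m),
       hatchlings = genotype_table(sprintf("h%02d", seq_len(n_hatch)), kid_m),
       true_k = length(unique(sire)))
}

# deterministic two-clutch fixture: explicit parent genotypes over 7
# well-separated loci so partitions and matches are unambiguous
panel7 <- function() sprintf("L%d", 1:7)
fixed_parents <- function() {
  loci <- panel7()
  mk <- function(base) {
    m <- lapply(seq_along(loci), function(j) matrix(base[[j]], ncol = 2))
    names(m) <- loci
    m
  }
  list(
    mother = genotype_table("MOM", mk(lapply(1:7, function(j)
      c(100L + 20L * j, 102L + 20L * j)))),
    M1 = mk(lapply(1:7, function(j) c(110L + 20L * j, 112L + 20L * j))),
    M2 = mk(lapply(1:7, function(j) c(114L + 20L * j, 116L + 20L * j))),
    M3 = mk(lapply(1:7, function(j) c(118L + 20L * j, 119L + 20L * j))))
}

# build a clutch's hatchling table from a sire vector, alternating which
# maternal/paternal allele is transmitted so reconstructions are complete
build_clutch_table <- function(parents, sires, prefix = "h") {
  loci <- panel7()
  n <- length(sires)
  kid <- lapply(seq_along(loci), function(j) {
    t(vapply(seq_len(n), function(h) {
      mom_al <- parents$mother[[paste0(loci[j], "_", 1 + h %% 2)]][1]
      dad <- parents[[sires[h]]][[j]]
      sort(c(mom_al, dad[1 + (h %/% 2) %% 2]))
    }, integer(2)))
  })
  names(kid) <- loci
  genotype_table(sprintf("%s%02d", prefix, seq_len(n)), kid)
}

fit_from_sires <- function(parents, sires, order = 1L, prefix = "h") {
  ht <- build_clutch_table(parents, sires, prefix)
  cl <- clutch("MOM", order, ht)
  clutch_paternity(cl, parents$mother)
}
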