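#' Population allele frequencies for a microsatellite panel
#'
#' Container for per-locus allele relative frequencies. Alleles are labelled
#' by integer fragment size; frequencies at each locus sum to one and every
#' locus carries at least two alleles (a monomorphic locus carries no
#' parentage information and is rejected).
#'
#' @param freqs named list, one element per locus: a named numeric vector of
#'   relative frequencies; names are integer allele sizes.
#' @return An object of class `allele_freqs`: a named list of per-locus
#'   frequency vectors, normalised to sum to one.
#' @examples
#' af <- allele_freqs(list(L1 = c(`100` = 0.5, `102` = 0.5)))
#' af$L1
#' @export
allele_freqs <- function(freqs) {
  if (!is.list(freqs) || length(freqs) == 0L || is.null(names(freqs)) ||
      anyDuplicated(names(freqs)))
    stop_invalid("freqs must be a named list with unique locus names")
  out <- lapply(names(freqs), function(loc) {
    p <- freqs[[loc]]
    if (!is.numeric(p) || length(p) < 2L)
      stop_invalid("locus ", loc, " must have >= 2 alleles")
    if (is.null(names(p)) || anyDuplicated(names(p)) ||
        anyNA(suppressWarnings(as.integer(names(p)))))
      stop_invalid("locus ", loc, " alleles must have unique integer labels")
    if (any(p < 0) || sum(p) <= 0)
      stop_invalid("locus ", loc, " frequencies must be non-negative, sum > 0")
    p / sum(p)
  })
  names(out) <- names(freqs)
  structure(out, class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("Allele frequencies:", length(x), "loci\n")
  for (loc in names(x))
    cat(sprintf("  %-10s %2d alleles, He = %.3f\n", loc, length(x[[loc]]),
                1 - sum(x[[loc]]^2)))
  invisible(x)
}

loci_of <- function(freqs) names(freqs)

#' Draw synthetic population allele frequencies
#'
#' Generates per-locus allele frequencies from a symmetric Dirichlet
#' distribution (via independent gamma draws), emulating a microsatellite
#' panel. Allele labels are consecutive even fragment sizes starting at 100,
#' so "neighbouring size class" is well defined for the single-step mutation
#' model.
#'
#' @param n_loci number of loci (>= 1).
#' @param alleles_per_locus allele count per locus: a single count, a
#'   length-2 range `c(lo, hi)` sampled uniformly per locus, or a vector of
#'   length `n_loci`.
#' @param concentration Dirichlet concentration parameter (> 0); 1 gives a
#'   uniform simplex, large values give even frequencies.
#' @param seed optional integer seed; same seed gives an identical object.
#' @param locus_names optional character vector of locus names.
#' @return An [allele_freqs] object.
#' @examples
#' gen_allele_freqs(7, c(14, 25), seed = 1)
#' @export
gen_allele_freqs <- function(n_loci, alleles_per_locus, concentration = 1,
                             seed = NULL, locus_names = NULL) {
  n_loci <- check_count(n_loci, "n_loci", min = 1L)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration <= 0)
    stop_invalid("concentration must be a single positive number")
  if (!is.numeric(alleles_per_locus) || anyNA(alleles_per_locus) ||
      any(alleles_per_locus < 2))
    stop_invalid("alleles_per_locus must be counts >= 2")
  if (is.null(locus_names)) locus_names <- sprintf("L%02d", seq_len(n_loci))
  if (length(locus_names) != n_loci) stop_invalid("locus_names length mismatch")
  with_seed(seed, {
    k <- if (length(alleles_per_locus) == 2L && n_loci != 2L)
      sample(seq(alleles_per_locus[1], alleles_per_locus[2]), n_loci,
             replace = TRUE)
    else rep_len(as.integer(alleles_per_locus), n_loci)
    fl <- lapply(k, function(ki) {
      g <- stats::rgamma(ki, shape = concentration)
      p <- g / sum(g)
      names(p) <- as.character(seq(100L, by = 2L, length.out = ki))
      p
    })
    names(fl) <- locus_names
    allele_freqs(fl)
  })
}

#' Estimate population allele frequencies from genotypes
#'
#' Frequency of each allele is its count divided by the total number of
#' non-missing allele calls at that locus (0 encodes a missing call and is
#' excluded from the denominator). Several genotype tables (for example
#' maternal panels from different years) may be pooled by passing a list.
#'
#' @param genotypes a genotype data frame (see [read_genotypes]) or a list of
#'   them, pooled before counting.
#' @return An [allele_freqs] object; loci with zero non-missing calls are
#'   dropped with a warning.
#' @examples
#' gt <- genotype_table(c("a", "b"), list(L1 = rbind(c(100, 100), c(100, 102))))
#' estimate_allele_freqs(gt)  # p_100 = 0.75
#' @export
estimate_allele_freqs <- function(genotypes) {
  if (is.data.frame(genotypes)) genotypes <- list(genotypes)
  loci <- attr(genotypes[[1L]], "loci")
  for (g in genotypes)
    if (!identical(attr(g, "loci"), loci))
      stop_invalid("all genotype tables must share the same locus panel")
  fl <- list()
  for (loc in loci) {
    calls <- unlist(lapply(genotypes, function(g)
      c(g[[paste0(loc, "_1")]], g[[paste0(loc, "_2")]])))
    calls <- calls[!is.na(calls) & calls != 0L]
    if (length(calls) == 0L) {
      warning("locus ", loc, " has no non-missing calls; excluded")
      next
    }
    tab <- table(calls)
    if (length(tab) < 2L) {
      warning("locus ", loc, " is monomorphic in the sample; excluded")
      next
    }
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(tab)
    fl[[loc]] <- p[order(as.integer(names(p)))]
  }
  if (length(fl) == 0L) stop_invalid("no locus with usable calls")
  allele_freqs(fl)
}
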