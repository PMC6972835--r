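#' Build a genotype table
#'
#' The package-wide genotype container is a plain data frame: one row per
#' individual, an `id` column, then two integer columns per locus named
#' `<locus>_1` and `<locus>_2` (the two-columns-per-locus CSV dialect used by
#' GenAlEx-style spreadsheets). 0 encodes a missing allele call; a single
#' missing allele at a locus is allowed and kept. Allele pairs are unordered:
#' each pair is stored sorted (missing calls last) so equality is
#' order-insensitive.
#'
#' @param ids character vector of individual ids.
#' @param loci named list, one element per locus: an `n x 2` matrix of
#'   integer allele sizes (0 = missing).
#' @return A data frame of class `genotype_table` with attribute `loci`.
#' @examples
#' genotype_table("turtle1", list(L1 = cbind(100, 104)))
#' @export
genotype_table <- function(ids, loci) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_invalid("individual ids must be unique")
  if (!is.list(loci) || is.null(names(loci))) stop_invalid("loci must be a named list")
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (loc in names(loci)) {
    m <- loci[[loc]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 2L)
    if (ncol(m) != 2L || nrow(m) != length(ids))
      stop_invalid("locus ", loc, ": need an n x 2 allele matrix")
    if (anyNA(m) || any(m != trunc(m)) || any(m < 0))
      stop_invalid("locus ", loc, ": alleles must be non-negative integers")
    m <- matrix(as.integer(m), ncol = 2L)
    m <- if (nrow(m)) t(apply(m, 1L, sort_pair)) else m
    out[[paste0(loc, "_1")]] <- m[, 1L]
    out[[paste0(loc, "_2")]] <- m[, 2L]
  }
  structure(out, loci = names(loci), class = c("genotype_table", "data.frame"))
}

# unordered storage convention: non-missing first, ascending
sort_pair <- function(ab) {
  if (any(ab == 0L)) c(max(ab), min(ab)) else sort(ab)
}

#' @export
`[.genotype_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "loci") <- attr(x, "loci")
    class(out) <- class(x)
  }
  out
}

#' Extract the allele pair matrix for one locus
#'
#' @param gt a `genotype_table`.
#' @param locus locus name.
#' @return Integer `n x 2` matrix (0 = missing), rownames = ids.
#' @export
locus_alleles <- function(gt, locus) {
  c1 <- paste0(locus, "_1"); c2 <- paste0(locus, "_2")
  if (!all(c(c1, c2) %in% names(gt))) stop_invalid("unknown locus ", locus)
  m <- cbind(gt[[c1]], gt[[c2]])
  rownames(m) <- gt$id
  m
}

#' Read genotypes from a two-columns-per-locus CSV
#'
#' The header must name two columns per locus, `<locus>_1` and `<locus>_2`,
#' plus an `id` column (extra metadata columns are carried through as
#' attributes only if requested by `keep`). Malformed rows are reported with
#' their line numbers.
#'
#' @param path CSV file path.
#' @param locus_names optional character vector; defaults to every locus
#'   inferred from paired column names.
#' @param keep optional extra column names to retain.
#' @return A `genotype_table`; any `keep` columns are attached as columns
#'   after the locus columns.
#' @export
read_genotypes <- function(path, locus_names = NULL, keep = character()) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(raw)) stop_invalid("missing 'id' column in ", path)
  inferred <- infer_loci(names(raw))
  if (is.null(locus_names)) locus_names <- inferred
  missing_cols <- setdiff(c(paste0(locus_names, "_1"), paste0(locus_names, "_2")),
                          names(raw))
  if (length(missing_cols))
    stop_invalid("locus columns absent (odd or missing pair): ",
                 paste(missing_cols, collapse = ", "))
  bad_lines <- integer()
  loci <- list()
  for (loc in locus_names) {
    m <- cbind(suppressWarnings(as.numeric(raw[[paste0(loc, "_1")]])),
               suppressWarnings(as.numeric(raw[[paste0(loc, "_2")]])))
    bad <- which(is.na(m[, 1L]) | is.na(m[, 2L]) | m != trunc(m))
    bad <- unique((bad - 1L) %% nrow(m) + 1L)
    if (length(bad)) bad_lines <- union(bad_lines, bad)
    m[is.na(m)] <- 0
    loci[[loc]] <- m
  }
  if (length(bad_lines))
    stop_invalid("non-integer allele calls at data line(s) ",
                 paste(sort(bad_lines) + 1L, collapse = ", "), " of ", path)
  gt <- genotype_table(as.character(raw$id), loci)
  for (k in intersect(keep, names(raw))) gt[[k]] <- raw[[k]]
  gt
}

infer_loci <- function(cols) {
  c1 <- grep("_1$", cols, value = TRUE)
  loci <- sub("_1$", "", c1)
  loci[paste0(loci, "_2") %in% cols]
}

#' Write genotypes to CSV
#'
#' Inverse of [read_genotypes]; columns are written in stable order
#' (id, then locus pairs in panel order) so repeated writes diff bit-exactly.
#'
#' @param gt a `genotype_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  utils::write.csv(as.data.frame(gt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a clutch record
#'
#' A clutch is one nesting event of one female: the sampled hatchling
#' genotypes plus the nest metadata the downstream quality metrics use.
#'
#' @param mother_id female id.
#' @param order clutch order within the season (1 = primary, 2 = secondary,
#'   3 = tertiary).
#' @param hatchlings `genotype_table` of sampled hatchlings.
#' @param inventory optional [nest_inventory].
#' @param lay_date optional `Date` (ISO-8601 when read from file).
#' @param incubation_days optional positive number.
#' @param true_fathers optional character vector (simulation truth labels,
#'   one per hatchling).
#' @return An object of class `clutch`.
#' @export
clutch <- function(mother_id, order, hatchlings, inventory = NULL,
                   lay_date = NULL, incubation_days = NULL,
                   true_fathers = NULL) {
  order <- check_count(order, "order", min = 1L)
  if (!inherits(hatchlings, "genotype_table"))
    stop_invalid("hatchlings must be a genotype_table")
  n <- nrow(hatchlings)
  if (!is.null(inventory)) {
    stopifnot(inherits(inventory, "nest_inventory"))
    if (n > inventory$T)
      stop_invalid("sampled hatchlings exceed total egg count")
  }
  if (!is.null(true_fathers) && length(true_fathers) != n)
    stop_invalid("true_fathers must have one label per hatchling")
  structure(list(mother_id = as.character(mother_id), order = order,
                 hatchlings = hatchlings, n = n, inventory = inventory,
                 lay_date = lay_date, incubation_days = incubation_days,
                 true_fathers = true_fathers),
            class = "clutch")
}

#' @export
print.clutch <- function(x, ...) {
  cat(sprintf("Clutch: mother %s, order %d, %d hatchlings sampled\n",
              x$mother_id, x$order, x$n))
  if (!is.null(x$inventory))
    cat(sprintf("  inventory H=%d T=%d L=%d D=%d\n", x$inventory$H,
                x$inventory$T, x$inventory$L, x$inventory$D))
  invisible(x)
}

#' Nest inventory counts
#'
#' @param H hatched eggs.
#' @param T_total total eggs.
#' @param L live hatchlings found in the nest at inventory.
#' @param D dead hatchlings found in the nest at inventory.
#' @return An object of class `nest_inventory`.
#' @export
nest_inventory <- function(H, T_total, L = 0, D = 0) {
  H <- check_count(H, "H"); T_total <- check_count(T_total, "T_total")
  L <- check_count(L, "L"); D <- check_count(D, "D")
  if (H > T_total) stop_invalid("H must be <= total eggs T")
  if (L + D > H) stop_invalid("L + D must be <= H")
  structure(list(H = H, T = T_total, L = L, D = D), class = "nest_inventory")
}

#' Write a set of clutches as plain-text tables
#'
#' Three CSV files: hatchling genotypes (with `mother_id` and `clutch_order`
#' columns), clutch metadata (inventory counts, ISO-8601 lay dates,
#' incubation days), and optionally a truth sidecar mapping hatchling id to
#' its simulated father. Stable column order for bit-exact diffing.
#'
#' @param clutches list of [clutch] objects.
#' @param genotypes_path,clutches_path,truth_path output CSV paths;
#'   `truth_path = NULL` suppresses the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_clutch_tables <- function(clutches, genotypes_path, clutches_path,
                                truth_path = NULL) {
  gts <- lapply(clutches, function(cl) {
    g <- as.data.frame(cl$hatchlings)
    g$mother_id <- cl$mother_id
    g$clutch_order <- cl$order
    g
  })
  utils::write.csv(do.call(rbind, gts), genotypes_path, row.names = FALSE,
                   quote = FALSE)
  meta <- do.call(rbind, lapply(clutches, function(cl) {
    inv <- cl$inventory %||% list(H = NA, T = NA, L = NA, D = NA)
    data.frame(mother_id = cl$mother_id, clutch_order = cl$order,
               lay_date = if (is.null(cl$lay_date)) NA_character_
                          else format(cl$lay_date, "%Y-%m-%d"),
               n_sampled = cl$n, H = inv$H, T_total = inv$T, L = inv$L,
               D = inv$D,
               incubation_days = cl$incubation_days %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(meta, clutches_path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    truth <- do.call(rbind, lapply(clutches, function(cl) {
      if (is.null(cl$true_fathers)) return(NULL)
      data.frame(id = cl$hatchlings$id, true_father = cl$true_fathers,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(truth))
      utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(c(genotypes_path, clutches_path, truth_path))
}

#' Read clutches back from the tables written by [write_clutch_tables]
#'
#' @param genotypes_path,clutches_path,truth_path input CSV paths
#'   (`truth_path` optional).
#' @return List of [clutch] objects ordered by mother then clutch order.
#' @export
read_clutch_tables <- function(genotypes_path, clutches_path,
                               truth_path = NULL) {
  gt <- read_genotypes(genotypes_path, keep = c("mother_id", "clutch_order"))
  meta <- utils::read.csv(clutches_path, stringsAsFactors = FALSE)
  truth <- if (!is.null(truth_path) && file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  loci <- attr(gt, "loci")
  out <- vector("list", nrow(meta))
  ord <- order(meta$mother_id, meta$clutch_order)
  meta <- meta[ord, , drop = FALSE]
  for (i in seq_len(nrow(meta))) {
    sel <- gt$mother_id == meta$mother_id[i] &
      gt$clutch_order == meta$clutch_order[i]
    sub <- gt[sel, , drop = FALSE]
    h <- genotype_table(sub$id, stats::setNames(
      lapply(loci, function(l) locus_alleles(sub, l)), loci))
    inv <- if (!is.na(meta$H[i]))
      nest_inventory(meta$H[i], meta$T_total[i], meta$L[i], meta$D[i])
    tf <- if (!is.null(truth)) truth$true_father[match(h$id, truth$id)]
    out[[i]] <- clutch(
      meta$mother_id[i], meta$clutch_order[i], h, inventory = inv,
      lay_date = if (!is.na(meta$lay_date[i])) as.Date(meta$lay_date[i]),
      incubation_days = if (!is.na(meta$incubation_days[i]))
        meta$incubation_days[i],
      true_fathers = if (!is.null(tf) && !anyNA(tf)) tf)
  }
  out
}
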