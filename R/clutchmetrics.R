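#' Emergence success of a nest
#'
#' `E = (H - (L + D)) / T`: the fraction of eggs that produced hatchlings
#' which left the nest unaided — a hatchling-quality proxy stricter than
#' hatch success.
#'
#' @param inv a [nest_inventory], or the count `H` if the remaining counts
#'   are given separately.
#' @param T_total,L,D counts, used when `inv` is numeric.
#' @return Emergence success in `[0, 1]`; `NA` with a warning when `T = 0`.
#' @examples
#' emergence_success(nest_inventory(H = 80, T_total = 100, L = 5, D = 5))
#' @export
emergence_success <- function(inv, T_total = NULL, L = 0, D = 0) {
  if (!inherits(inv, "nest_inventory"))
    inv <- nest_inventory(inv, T_total, L, D)
  if (inv$T == 0L) {
    warning("total egg count is zero; emergence success undefined")
    return(NA_real_)
  }
  (inv$H - (inv$L + inv$D)) / inv$T
}

# Ramanujan's approximation to the perimeter of an ellipse with semi-axes
# a and c; exact in the circular limit, relative error < 1e-3 over the
# eccentricities seen in carapace data
ellipse_perimeter <- function(a, c) {
  pi * (3 * (a + c) - sqrt((3 * a + c) * (a + 3 * c)))
}

# invert CCL = half-perimeter of the (a, c) ellipse for the depth axis c
solve_depth_axis <- function(a, CCL) {
  if (2 * CCL <= ellipse_perimeter(a, 1e-12))
    stop_invalid("no positive half-axis c solves CCL = ", CCL,
                 " with SCL = ", 2 * a)
  upper <- CCL
  while (ellipse_perimeter(a, upper) < 2 * CCL) upper <- upper * 2
  stats::uniroot(function(cc) ellipse_perimeter(a, cc) / 2 - CCL,
                 c(1e-12, upper), tol = 1e-9)$root
}

#' Half-ellipsoid carapace surface area
#'
#' Models the carapace as the upper half of an ellipsoid with semi-axes
#' `a = SCL/2`, `b = SCW/2`, and `c` recovered numerically from the curved
#' length: CCL is treated as half the perimeter of the ellipse with
#' semi-axes `a` and `c` (the curve a tape measure follows along the shell's
#' length), inverted with Ramanujan's perimeter approximation to 1e-9.
#' The area uses the Thomsen approximation with exponent p = 1.6,
#' `SA = 4 * pi * ((a^p b^p + a^p c^p + b^p c^p) / 3)^(1/p) / 2`,
#' halved because only the dorsal surface is measured.
#'
#' @param SCL,SCW straight carapace length and width (cm).
#' @param CCL curved carapace length (cm); must exceed `SCL * pi/...`
#'   enough to admit a positive `c` (i.e. `CCL > SCL/2 * pi/2` in the
#'   degenerate flat limit).
#' @return Surface area in cm^2 (vectorised over the inputs).
#' @examples
#' half_ellipsoid_sa(20, 20, 10 * pi)  # sphere limit: 2*pi*10^2
#' @export
half_ellipsoid_sa <- function(SCL, SCW, CCL) {
  n <- max(length(SCL), length(SCW), length(CCL))
  SCL <- rep_len(SCL, n); SCW <- rep_len(SCW, n); CCL <- rep_len(CCL, n)
  if (any(SCL <= 0 | SCW <= 0 | CCL <= 0))
    stop_invalid("all measurements must be positive")
  vapply(seq_len(n), function(i) {
    a <- SCL[i] / 2; b <- SCW[i] / 2
    c_ax <- solve_depth_axis(a, CCL[i])
    p <- 1.6
    4 * pi * ((a^p * b^p + a^p * c_ax^p + b^p * c_ax^p) / 3)^(1 / p) / 2
  }, numeric(1L))
}

#' Read and write morphometric tables
#'
#' The morphometrics CSV schema: `id`, then the four standard carapace
#' measurements `CCL`, `CCW`, `SCL`, `SCW` in cm (curved/straight length
#' and width). Columns are written in that fixed order so repeated writes
#' diff bit-exactly.
#'
#' @param path CSV path.
#' @return `read_morphometrics`: a validated data frame.
#' @export
read_morphometrics <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "CCL", "CCW", "SCL", "SCW")
  if (!all(need %in% names(df)))
    stop_invalid("morphometrics file needs columns: ",
                 paste(need, collapse = ", "))
  for (col in need[-1])
    if (!is.numeric(df[[col]]) || any(df[[col]] <= 0, na.rm = TRUE))
      stop_invalid("column ", col, " must be positive lengths (cm)")
  df[need]
}

#' @param df data frame with the columns above.
#' @rdname read_morphometrics
#' @return `write_morphometrics`: `path`, invisibly.
#' @export
write_morphometrics <- function(df, path) {
  utils::write.csv(df[c("id", "CCL", "CCW", "SCL", "SCW")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derived shell geometry for a morphometrics table
#'
#' Appends the half-ellipsoid model's quantities to a morphometrics table:
#' semi-axes `a = SCL/2`, `b = SCW/2`, the depth axis `c` solved from CCL,
#' and the dorsal surface area `SA` (cm^2) from [half_ellipsoid_sa].
#'
#' @param df morphometrics data frame (see [read_morphometrics]).
#' @return The data frame with columns `a`, `b`, `c`, `SA` appended.
#' @export
shell_metrics <- function(df) {
  df$a <- df$SCL / 2
  df$b <- df$SCW / 2
  df$c <- vapply(seq_len(nrow(df)), function(i)
    solve_depth_axis(df$SCL[i] / 2, df$CCL[i]), numeric(1L))
  df$SA <- half_ellipsoid_sa(df$SCL, df$SCW, df$CCL)
  df
}

#' Group-comparison tests for clutch and morphometric data
#'
#' The standard comparison battery for two groups of nests (single versus
#' multiple paternity, or primary versus secondary clutches): pooled-variance
#' two-sample t test, F variance-ratio test, and (for suitably discretised
#' responses) a chi-square test. One- and two-tailed p-values are both
#' reported for the t test.
#'
#' @param values numeric response (e.g. hatchling SCL, emergence success).
#' @param group two-level factor or character vector of group labels.
#' @param tests subset of `c("t", "F", "chisq")`.
#' @param chisq_breaks number of quantile bins for the chi-square test.
#' @return Data frame with columns `test`, `statistic`, `df`, `p_two_tailed`,
#'   `p_one_tailed`, `note`.
#' @export
group_comparisons <- function(values, group, tests = c("t", "F", "chisq"),
                              chisq_breaks = 4L) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop_invalid("need exactly two groups")
  g1 <- values[group == levels(group)[1L]]
  g2 <- values[group == levels(group)[2L]]
  rows <- list()
  degenerate <- stats::var(g1) == 0 && stats::var(g2) == 0
  if ("t" %in% tests) {
    if (length(g1) < 2L || length(g2) < 2L)
      stop_invalid("t test needs >= 2 observations per group")
    if (degenerate && mean(g1) == mean(g2)) {
      rows$t <- data.frame(test = "t", statistic = 0,
                           df = length(g1) + length(g2) - 2L,
                           p_two_tailed = 1, p_one_tailed = 0.5,
                           note = "degenerate variance")
    } else {
      tt <- stats::t.test(g1, g2, var.equal = TRUE)
      rows$t <- data.frame(test = "t", statistic = unname(tt$statistic),
                           df = unname(tt$parameter),
                           p_two_tailed = tt$p.value,
                           p_one_tailed = tt$p.value / 2, note = "")
    }
  }
  if ("F" %in% tests) {
    if (degenerate) {
      rows$F <- data.frame(test = "F", statistic = NA_real_, df = NA_real_,
                           p_two_tailed = NA_real_, p_one_tailed = NA_real_,
                           note = "degenerate variance")
    } else {
      ft <- stats::var.test(g1, g2)
      rows$F <- data.frame(test = "F", statistic = unname(ft$statistic),
                           df = paste(ft$parameter, collapse = ","),
                           p_two_tailed = ft$p.value,
                           p_one_tailed = ft$p.value / 2, note = "")
    }
  }
  if ("chisq" %in% tests) {
    br <- unique(stats::quantile(values, seq(0, 1, length.out =
                                               chisq_breaks + 1L)))
    if (length(br) > 2L) {
      bins <- cut(values, br, include.lowest = TRUE)
      ct <- suppressWarnings(stats::chisq.test(table(group, bins)))
      rows$chisq <- data.frame(test = "chisq",
                               statistic = unname(ct$statistic),
                               df = unname(ct$parameter),
                               p_two_tailed = ct$p.value,
                               p_one_tailed = NA_real_, note = "")
    } else {
      rows$chisq <- data.frame(test = "chisq", statistic = NA_real_,
                               df = NA_real_, p_two_tailed = NA_real_,
                               p_one_tailed = NA_real_,
                               note = "response too coarse to bin")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares fit with the standard F test
#'
#' Thin wrapper over [stats::lm] returning the quantities the study's
#' regressions report: slope, intercept, R-squared, overall F and its
#' p-value.
#'
#' @param x predictor values.
#' @param y response values (n >= 3).
#' @return List with `slope`, `intercept`, `r_squared`, `F`, `df`, `p`,
#'   and the underlying `fit`. A constant predictor is flagged
#'   (`slope = NA`, `note`).
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_invalid("need matched x and y with n >= 3")
  if (stats::var(x) == 0)
    return(list(slope = NA_real_, intercept = mean(y), r_squared = NA_real_,
                F = NA_real_, df = c(NA, NA), p = NA_real_, fit = NULL,
                note = "constant predictor"))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       F = if (is.null(fstat)) NA_real_ else unname(fstat[1L]),
       df = if (is.null(fstat)) c(NA, NA) else unname(fstat[2:3]),
       p = if (is.null(fstat)) NA_real_ else
         unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                          lower.tail = FALSE)),
       fit = fit)
}
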