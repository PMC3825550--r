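#' Bin morphant records by fluorescence intensity
#'
#' Groups embryos into half-open FI bins `[lo, hi)` with the last bin
#' unbounded above, following the convention "FI >= 2 and < 4": lower
#' edges are inclusive. The default edges `c(2, 4, 8)` yield the four
#' classes FI < 2, 2 <= FI < 4, 4 <= FI < 8 and FI >= 8.
#'
#' @param records data frame with a numeric `fi` column.
#' @param edges strictly increasing bin edges.
#' @return `records` with an added `fi_bin` factor column.
#' @export
bin_by_fi <- function(records, edges = c(2, 4, 8)) {
  if (!"fi" %in% names(records)) stop_input("`records` needs an `fi` column")
  if (is.unsorted(edges, strictly = TRUE))
    stop_input("`edges` must be strictly increasing")
  brk <- c(-Inf, edges, Inf)
  labs <- character(length(edges) + 1L)
  labs[1L] <- sprintf("FI<%g", edges[1L])
  if (length(edges) > 1L)
    labs[2:length(edges)] <- sprintf("%g<=FI<%g", head(edges, -1L),
                                     tail(edges, -1L))
  labs[length(labs)] <- sprintf("FI>=%g", edges[length(edges)])
  records$fi_bin <- cut(records$fi, breaks = brk, labels = labs,
                        right = FALSE)
  records
}

#' Normalize expression ratios to low-dose controls
#'
#' Divides every expression ratio (e.g. target/reference transcript
#' ratio) by the mean ratio of the control subset, defined as records with
#' FI below `control_fi_max` (embryos that effectively received no
#' morpholino). The control subset mean maps to exactly 1.
#'
#' @param records data frame with `fi` and `expression_ratio` columns.
#' @param control_fi_max FI cutoff defining the control subset.
#' @return `records` with an added `relative_expression` column.
#' @export
normalize_expression <- function(records, control_fi_max = 1) {
  need <- c("fi", "expression_ratio")
  if (!all(need %in% names(records)))
    stop_input("`records` needs `fi` and `expression_ratio` columns")
  ctrl <- records$expression_ratio[records$fi < control_fi_max]
  ctrl <- ctrl[!is.na(ctrl)]
  if (!length(ctrl))
    stop_input("empty control subset (no records with FI < ",
               control_fi_max, ")")
  records$relative_expression <- records$expression_ratio / mean(ctrl)
  records
}

# all permutations of 1..n as an n! x n matrix (n <= 9)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Spearman rank correlation with exact small-sample p value
#'
#' Rank correlation using average ranks for ties. The two-sided p value
#' is computed by exhaustive permutation of one variable for `n <= 9`
#' (the proportion of permutations with `|rho|` at least as extreme) and
#' by the t approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom otherwise.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return A list: `rho`, `p`, `n`, `method`.
#' @export
spearman_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_input("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop_input("Spearman correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(r2) {
    sx <- rx - mean(rx); s2 <- r2 - mean(r2)
    sum(sx * s2) / sqrt(sum(sx^2) * sum(s2^2))
  }
  rho <- rho_of(ry)
  if (n <= 9L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(p) rho_of(ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Two-sided Student's t test (pooled variance)
#'
#' Classic two-sample pooled-variance t test (Welch's correction
#' available via `welch = TRUE`). Degenerate case: when both groups have
#' zero variance, equal means give `p = 1` and unequal means `p = 0`
#' (infinite t), by convention.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) form.
#' @return A list: `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
t_test_two_sided <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop_input("both groups need at least 2 observations")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  mean_a = mean(a), mean_b = mean(b)))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' All pairwise two-sided Student's t tests between groups, with
#' Bonferroni adjustment: adjusted p = min(1, raw p x number of
#' comparisons performed). Pairs involving a group with fewer than two
#' observations are skipped with a warning (and do not count toward the
#' multiplier).
#'
#' @param values numeric vector of the measured metric.
#' @param groups group labels, same length as `values`.
#' @param alpha significance level used for the `significant` flag.
#' @param welch use Welch's t test for each pair.
#' @return A data frame with one row per comparison: `group1`, `group2`,
#'   `statistic`, `p_raw`, `p_adjusted`, `significant`, `method`.
#' @export
bonferroni_pairwise <- function(values, groups, alpha = 0.05,
                                welch = FALSE) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop_input("`values` and `groups` must have equal length")
  gl <- unique(groups)
  if (length(gl) < 2L) stop_input("need at least 2 groups")
  pairs <- utils::combn(gl, 2L)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    v1 <- values[groups == g1]; v2 <- values[groups == g2]
    if (sum(is.finite(v1)) < 2L || sum(is.finite(v2)) < 2L) {
      warning(sprintf("skipping %s vs %s: fewer than 2 observations",
                      g1, g2), call. = FALSE)
      next
    }
    ht <- t_test_two_sided(v1, v2, welch = welch)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = g1, group2 = g2, statistic = ht$t, p_raw = ht$p)
  }
  if (!length(rows)) stop_input("no testable group pairs")
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out$significant <- out$p_adjusted < alpha
  out$method <- sprintf("Bonferroni-adjusted %s t test (m = %d)",
                        if (welch) "Welch" else "Student", m)
  out
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Pearson chi-square statistic `N (ad - bc)^2 / (r1 r2 c1 c2)` with one
#' degree of freedom and upper-tail p value; no continuity correction by
#' default (Yates' correction via `yates = TRUE`). Used for example to
#' test whether co-injecting rescue mRNA changes the proportion of
#' embryos with a cardiac phenotype.
#'
#' @param table 2x2 matrix of non-negative integer counts, all margins
#'   positive.
#' @param yates apply Yates' continuity correction.
#' @return A list: `chi2`, `p`, `df`.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) stop_input("`table` must be 2x2")
  if (any(tb < 0) || any(tb != round(tb)))
    stop_input("counts must be non-negative integers")
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0))
    stop_input("all table margins must be positive")
  n <- sum(tb)
  num <- abs(tb[1, 1] * tb[2, 2] - tb[1, 2] * tb[2, 1])
  if (yates) num <- max(0, num - n / 2)
  chi2 <- n * num^2 /
    (prod(rowSums(tb)) * prod(colSums(tb)))
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE), df = 1L)
}
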