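#' Two-sample Kolmogorov-Smirnov comparison of a feature
#'
#' Two-sided two-sample KS test between feature values of two groups,
#' exact when both groups have at most 25 observations (and no ties),
#' asymptotic otherwise. Missing values are dropped.
#'
#' @param values_a,values_b numeric vectors (non-empty after NA removal).
#' @param feature optional feature name carried into the result.
#' @return One-row `data.frame`: `feature`, `n_a`, `n_b`, `D`, `p`,
#'   `median_a`, `median_b`.
#' @examples
#' ks_compare(c(1, 2, 3), c(4, 5, 6))
#' @export
ks_compare <- function(values_a, values_b, feature = "") {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) == 0 || length(b) == 0)
    stop_bad_arg("both groups must be non-empty after dropping NAs")
  exact <- length(a) <= 25 && length(b) <= 25
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  data.frame(feature = feature, n_a = length(a), n_b = length(b),
             D = unname(kt$statistic), p = kt$p.value,
             median_a = median(a), median_b = median(b),
             stringsAsFactors = FALSE)
}

#' Build a 2x2 contingency table of motif presence by group
#'
#' @param a,b,c,d non-negative integer counts: group 1 with / without the
#'   motif, group 2 with / without.
#' @return 2x2 integer matrix of class `contingency_table` (rows = groups,
#'   columns = with/without).
#' @export
contingency_table <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x)))
    stop_bad_arg("contingency counts must be non-negative integers")
  structure(matrix(as.integer(x), 2, 2, byrow = TRUE,
                   dimnames = list(c("group1", "group2"),
                                   c("with", "without"))),
            class = c("contingency_table", "matrix"))
}

#' Reconstruct a contingency table from reported percentages
#'
#' With-motif counts are `round(pct * n / 100)` with halves rounded away
#' from zero; complements fill the table. Used to recover testable counts
#' from published group percentages.
#'
#' @param pct_a,pct_b percentages (0-100) with the motif in each group.
#' @param n_a,n_b group sizes.
#' @return A [contingency_table()].
#' @examples
#' reconstruct_table(62, 156, 35, 49)
#' @export
reconstruct_table <- function(pct_a, n_a, pct_b, n_b) {
  if (pct_a < 0 || pct_a > 100 || pct_b < 0 || pct_b > 100)
    stop_bad_arg("percentages must lie in [0, 100]")
  half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  a <- half_away(pct_a * n_a / 100)
  c0 <- half_away(pct_b * n_b / 100)
  contingency_table(a, n_a - a, c0, n_b - c0)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the conventional rule: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one. Degenerate margins give p = 1.
#'
#' @param table a [contingency_table()] or any 2x2 count matrix.
#' @return Two-sided p-value in (0, 1\].
#' @examples
#' fisher_exact(contingency_table(5, 0, 0, 5))
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(unclass(table))
  if (!all(dim(table) == c(2, 2)))
    stop_bad_arg("fisher_exact needs a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Percentage of flagged members per group
#'
#' @param flags logical vector of motif presence.
#' @param groups group labels aligned with `flags`.
#' @param digits rounding for the reported percentage (default 0, as
#'   typically published); full precision is returned alongside.
#' @return `data.frame`: `group`, `n`, `n_with`, `pct` (full precision),
#'   `pct_rounded`.
#' @export
group_percentages <- function(flags, groups, digits = 0) {
  if (length(flags) != length(groups))
    stop_bad_arg("flags and groups must have equal length")
  lev <- unique(as.character(groups))
  if (!length(lev))
    return(data.frame(group = character(), n = integer(),
                      n_with = integer(), pct = numeric(),
                      pct_rounded = numeric(), stringsAsFactors = FALSE))
  out <- lapply(lev, function(g) {
    f <- flags[groups == g & !is.na(flags)]
    n <- length(f)
    data.frame(group = g, n = n, n_with = sum(f),
               pct = if (n == 0) NA_real_ else 100 * sum(f) / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$pct_rounded <- round(out$pct, digits)
  out
}

#' Between-class enrichment report for UTR features
#'
#' Compares the two transcript classes on continuous features (two-sample
#' KS: G/C content, folding energy, length, uAUG count) and on motif
#' presence flags (Fisher's exact on the 2x2 presence table, with group
#' percentages).
#'
#' @param features a [utr_features()] table.
#' @param classes character vector aligned with `features` rows, typically
#'   `"dependent"` / `"independent"` (other labels are ignored).
#' @param class_a,class_b the two class labels to compare.
#' @param adjust apply Benjamini-Hochberg adjustment across the motif tests
#'   (default `FALSE`: nominal p-values).
#' @return A list with `continuous` (KS rows) and `motifs` (one row per
#'   flag: percentages in each class, Fisher p, optionally `p_adj`).
#' @export
enrichment_report <- function(features, classes, class_a = "dependent",
                              class_b = "independent", adjust = FALSE) {
  if (nrow(features) != length(classes))
    stop_bad_arg("features and classes must align row-wise")
  ia <- classes == class_a
  ib <- classes == class_b
  if (!any(ia) || !any(ib))
    stop_bad_arg("both classes must be non-empty")
  cont <- do.call(rbind, lapply(c("gc", "dG", "length", "n_uaug"),
                                function(f) {
    ks_compare(features[[f]][ia], features[[f]][ib], feature = f)
  }))
  flags <- grep("^has_", names(features), value = TRUE)
  motifs <- do.call(rbind, lapply(flags, function(f) {
    fa <- features[[f]][ia]
    fb <- features[[f]][ib]
    fa <- fa[!is.na(fa)]
    fb <- fb[!is.na(fb)]
    tab <- contingency_table(sum(fa), sum(!fa), sum(fb), sum(!fb))
    data.frame(motif = f, n_a = length(fa), n_b = length(fb),
               pct_a = 100 * mean(fa), pct_b = 100 * mean(fb),
               p = fisher_exact(tab), stringsAsFactors = FALSE)
  }))
  if (adjust) motifs$p_adj <- stats::p.adjust(motifs$p, method = "BH")
  list(continuous = cont, motifs = motifs,
       class_a = class_a, class_b = class_b)
}
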