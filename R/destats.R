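#' Normalize a miRNA count matrix to reads per million
#'
#' NE = count / total * 1e6, per library. When `totals` are the per-library
#' summed miRNA counts, each NE column sums to 1e6 exactly (up to IEEE
#' rounding).
#'
#' @param counts integer matrix, miRNA ids in rows, libraries in columns.
#' @param totals per-library totals used for normalization; default: the
#'   column sums of `counts` (miRNA-total normalization). Pass clean-read
#'   totals for clean-total normalization.
#' @return class `expression_matrix`: list with `counts`, `ne`, `totals`.
#' @examples
#' m <- matrix(c(12, 0, 8, 4), 2, dimnames = list(c("a", "b"), c("XX", "XY")))
#' normalize_expression(m, totals = c(XX = 6e6, XY = 6e6))$ne
#' @export
normalize_expression <- function(counts, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(totals <= 0)) stopf("normalization totals must be positive")
  stopifnot(length(totals) == ncol(counts))
  ne <- sweep(counts, 2, totals, "/") * 1e6
  structure(list(counts = counts, ne = ne, totals = totals),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d miRNAs x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  totals:", paste(sprintf("%s=%g", colnames(x$counts), x$totals),
                         collapse = " "), "\n")
  invisible(x)
}

#' Audic-Claverie two-sided p-value for a pair of tag counts
#'
#' Exact test for equality of two counts x and y observed in libraries of
#' sizes N1 and N2, based on the conditional distribution
#' p(y | x) = (N2/N1)^y * (x+y)! / (x! y! (1 + N2/N1)^(x+y+1)).
#' The two-sided p-value is min(1, 2 * min(P(k <= y | x), P(k >= y | x))),
#' evaluated in log space.
#'
#' @param x,y observed counts (vectorized).
#' @param N1,N2 library sizes.
#' @return two-sided p-value(s) in (0, 1].
#' @examples
#' audic_claverie_p(0, 0, 1e6, 1e6)   # 1
#' audic_claverie_p(10, 0, 1e6, 1e6)  # 2 * 2^-11
#' @export
audic_claverie_p <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stopf("counts must be non-negative")
  if (any(N1 <= 0) || any(N2 <= 0)) stopf("library sizes must be positive")
  mapply(ac_p_one, x, y, N1, N2)
}

# log p(k | x) for k = 0..kmax under the Audic-Claverie conditional
ac_log_pmf <- function(x, kmax, r) {
  k <- 0:kmax
  k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(r)
}

ac_p_one <- function(x, y, N1, N2) {
  r <- N2 / N1
  lp <- ac_log_pmf(x, y, r)
  lower <- exp(logsumexp(lp))  # P(k <= y)
  # upper tail P(k >= y) summed directly (never via 1 - lower, which
  # cancels catastrophically when the tail is small); terms eventually
  # decay geometrically with ratio r / (1 + r)
  kmax <- y + 200L
  repeat {
    lp_ext <- ac_log_pmf(x, kmax, r)
    tail_lp <- lp_ext[(y + 1):(kmax + 1)]
    upper <- exp(logsumexp(tail_lp))
    if (exp(lp_ext[kmax + 1]) < 1e-17 * max(upper, 1e-300)) break
    kmax <- kmax * 2L + 200L
  }
  min(1, 2 * min(lower, min(upper, 1)))
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

#' Fisher exact and chi-squared tests on the 2x2 count table
#'
#' Table is `[[x, N1 - x], [y, N2 - y]]`. Fisher is two-sided by the
#' point-probability rule; the chi-squared test has 1 df, continuity
#' correction off by default.
#'
#' @param x,y observed counts.
#' @param N1,N2 library sizes (x <= N1, y <= N2).
#' @param correct apply Yates continuity correction to the chi-squared test.
#' @return list with `p_fisher` and `p_chi2`.
#' @export
contingency_tests <- function(x, y, N1, N2, correct = FALSE) {
  if (x > N1 || y > N2) stopf("count exceeds its library size")
  tab <- matrix(c(x, N1 - x, y, N2 - y), 2, byrow = TRUE)
  p_f <- fisher.test(tab)$p.value
  p_c <- suppressWarnings(chisq.test(tab, correct = correct)$p.value)
  if (is.nan(p_c)) p_c <- 1  # degenerate table (all-zero margin)
  list(p_fisher = p_f, p_chi2 = p_c)
}

#' Pairwise differential expression calls
#'
#' Applies the full call rule set for one library pair (A vs B):
#' * rows with NE < 1 in **all** libraries of the matrix are `filtered` and
#'   excluded from testing and from the Bonferroni family;
#' * rows with NE zero in exactly one of A, B are sex-specific
#'   (`specific_A` when NE_B = 0 and NE_A > 0, and symmetrically) and are
#'   not tested;
#' * remaining rows get Audic-Claverie, Fisher and chi-squared p-values; the
#'   policy p-value is Bonferroni-multiplied by the number of tested rows,
#'   capped at 1;
#' * `up` iff adjusted p < `alpha` and log2 fold change
#'   (log2(NE_A / NE_B)) exceeds `lfc`; `down` iff adjusted p < `alpha` and
#'   log2fc < -`lfc`; else `not_significant`.
#'
#' @param em an `expression_matrix` (must contain both pair members; the
#'   NE < 1 filter uses all of its columns).
#' @param pair character vector `c(A, B)` of library ids.
#' @param alpha significance level on the adjusted p-value.
#' @param lfc absolute log2 fold-change threshold.
#' @param policy which p-value drives the call: `"ac"` (Audic-Claverie,
#'   default), `"fisher"`, `"chi2"`, or `"consensus"` (max of the three).
#' @return data.frame, one row per miRNA: counts and NE for both libraries,
#'   `log2fc`, `p_ac`, `p_fisher`, `p_chi2`, `p_adjusted`, `status`, `tier`.
#' @export
call_de <- function(em, pair, alpha = 0.05, lfc = 1.0,
                    policy = c("ac", "fisher", "chi2", "consensus")) {
  policy <- match.arg(policy)
  stopifnot(inherits(em, "expression_matrix"), length(pair) == 2,
            all(pair %in% colnames(em$counts)))
  a <- pair[1]; b <- pair[2]
  ids <- rownames(em$counts)
  ne_a <- em$ne[, a]; ne_b <- em$ne[, b]
  x <- em$counts[, a]; y <- em$counts[, b]
  N1 <- em$totals[[a]]; N2 <- em$totals[[b]]

  status <- rep(NA_character_, length(ids))
  filtered <- apply(em$ne < 1, 1, all)
  status[filtered] <- "filtered"
  spec_a <- !filtered & ne_b == 0 & ne_a > 0
  spec_b <- !filtered & ne_a == 0 & ne_b > 0
  status[spec_a] <- "specific_A"
  status[spec_b] <- "specific_B"
  undetected <- !filtered & ne_a == 0 & ne_b == 0
  status[undetected] <- "not_significant"

  test_idx <- which(is.na(status))
  p_ac <- p_f <- p_c <- p_adj <- rep(NA_real_, length(ids))
  log2fc <- rep(NA_real_, length(ids))
  log2fc[test_idx] <- log2(ne_a[test_idx] / ne_b[test_idx])
  n_tested <- length(test_idx)
  for (i in test_idx) {
    p_ac[i] <- ac_p_one(x[i], y[i], N1, N2)
    ct <- contingency_tests(x[i], y[i], N1, N2)
    p_f[i] <- ct$p_fisher
    p_c[i] <- ct$p_chi2
  }
  p_policy <- switch(policy,
    ac = p_ac, fisher = p_f, chi2 = p_c,
    consensus = pmax(p_ac, p_f, p_c))
  p_adj[test_idx] <- pmin(1, p_policy[test_idx] * n_tested)
  sig <- !is.na(p_adj) & p_adj < alpha
  status[test_idx] <- "not_significant"
  status[sig & log2fc > lfc] <- "up"
  status[sig & log2fc < -lfc] <- "down"

  copies <- (x + y) / 2  # per-miRNA copy number within the pair
  tier <- if (mean(copies) > 0) {
    vapply(copies, abundance_tier, character(1), mean_copy = mean(copies))
  } else rep("Low", length(copies))

  data.frame(mirna = ids,
             count_a = x, count_b = y, ne_a = ne_a, ne_b = ne_b,
             log2fc = log2fc, p_ac = p_ac, p_fisher = p_f, p_chi2 = p_c,
             p_adjusted = p_adj, status = status, tier = tier,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Abundance tier of a miRNA
#'
#' High: read count above the dataset mean copy number; Middle: above 10 but
#' at most the mean; Low: at most 10 reads. Boundary cases (exactly 10,
#' exactly the mean) are assigned downward.
#'
#' @param count read count.
#' @param mean_copy dataset mean copy number (> 0).
#' @return "High", "Middle" or "Low".
#' @export
abundance_tier <- function(count, mean_copy) {
  stopifnot(mean_copy > 0)
  if (count > mean_copy) "High"
  else if (count > 10) "Middle"
  else "Low"
}

#' Scatter-plot values with zeros revised to 0.01
#'
#' For log-scale scatter plots of one pair: every zero NE is replaced by
#' 0.01; the expression matrix itself is not modified.
#'
#' @param em an `expression_matrix`.
#' @param pair character vector `c(A, B)`.
#' @return data.frame with `mirna`, `ne_a`, `ne_b` (zeros replaced).
#' @export
plot_values <- function(em, pair) {
  stopifnot(inherits(em, "expression_matrix"), all(pair %in%
                                                     colnames(em$ne)))
  ne_a <- em$ne[, pair[1]]
  ne_b <- em$ne[, pair[2]]
  ne_a[ne_a == 0] <- 0.01
  ne_b[ne_b == 0] <- 0.01
  data.frame(mirna = rownames(em$ne), ne_a = ne_a, ne_b = ne_b,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative quantification by the 2^(-ddCt) method
#'
#' ddCt = (Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control); the relative quantity is
#' 2^(-ddCt), so the control condition maps to 1 by construction.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Ct values (finite, positive); vectorized.
#' @return relative quantity (numeric).
#' @examples
#' ddct(20, 15, 22, 15)  # 4
#' @export
ddct <- function(ct_target_treated, ct_ref_treated, ct_target_control,
                 ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stopf("Ct values must be finite and positive")
  dd <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-dd)
}

#' Two-sided Welch t-test
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with `t` (statistic) and `p` (two-sided p-value).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stopf("each group needs at least two values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: identical constants give t = 0 / p = 1, otherwise t.test
    # errors; separation is decided by the means
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- t.test(a, b)
  list(t = unname(tt$statistic), p = tt$p.value)
}
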