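REGIONS <- c("XX", "XY", "YY", "XX.XY", "XX.YY", "XY.YY", "XX.XY.YY")

new_venn_partition <- function(regions) {
  stopifnot(identical(names(regions), REGIONS))
  regions <- stats::setNames(as.numeric(regions), REGIONS)
  if (any(regions < 0)) stopf("negative region count")
  totals <- c(
    XX = sum(regions[c("XX", "XX.XY", "XX.YY", "XX.XY.YY")]),
    XY = sum(regions[c("XY", "XX.XY", "XY.YY", "XX.XY.YY")]),
    YY = sum(regions[c("YY", "XX.YY", "XY.YY", "XX.XY.YY")]))
  pairwise <- c(
    XX.XY = unname(regions["XX.XY"] + regions["XX.XY.YY"]),
    XX.YY = unname(regions["XX.YY"] + regions["XX.XY.YY"]),
    XY.YY = unname(regions["XY.YY"] + regions["XX.XY.YY"]))
  union <- sum(regions)
  pct <- if (union > 0) round(100 * regions / union, 1) else regions * 0
  structure(list(regions = regions, totals = totals, pairwise = pairwise,
                 union = unname(union), percentages = pct,
                 total_percentages = if (union > 0)
                   round(100 * totals / union, 1) else totals * 0),
            class = "venn_partition")
}

#' Three-set Venn partition of detection sets
#'
#' Splits the union of the XX, XY and YY detection sets into the seven
#' disjoint Venn regions and derives per-set totals, pairwise co-detection
#' counts, the union size, and region percentages of the union (one
#' decimal).
#'
#' @param xx,xy,yy character vectors of detected ids (detection = NE > 0 by
#'   the pipeline's convention).
#' @return class `venn_partition`: list with `regions` (named 7-vector in
#'   the order XX, XY, YY, XX.XY, XX.YY, XY.YY, XX.XY.YY — exclusive
#'   regions first, then pair-only, then the triple), `totals`, `pairwise`
#'   (co-detection counts), `union`, `percentages`, `total_percentages`.
#' @examples
#' venn_partition(c("a", "b"), c("b", "c"), c("b"))$regions
#' @export
venn_partition <- function(xx, xy, yy) {
  xx <- unique(as.character(xx))
  xy <- unique(as.character(xy))
  yy <- unique(as.character(yy))
  u <- unique(c(xx, xy, yy))
  inxx <- u %in% xx; inxy <- u %in% xy; inyy <- u %in% yy
  regions <- c(
    XX = sum(inxx & !inxy & !inyy),
    XY = sum(!inxx & inxy & !inyy),
    YY = sum(!inxx & !inxy & inyy),
    XX.XY = sum(inxx & inxy & !inyy),
    XX.YY = sum(inxx & !inxy & inyy),
    XY.YY = sum(!inxx & inxy & inyy),
    XX.XY.YY = sum(inxx & inxy & inyy))
  new_venn_partition(regions)
}

#' Reconstruct a Venn partition from printed marginal counts
#'
#' Given the three per-set totals, the three exclusive (single-set) region
#' counts and **one** pair-only region count, the remaining two pair-only
#' regions and the triple overlap are determined by the per-set total
#' identities; this solves that 3-unknown linear system and validates the
#' result (all regions non-negative integers).
#'
#' @param totals named numeric vector `c(XX=, XY=, YY=)` of per-set totals.
#' @param exclusives named numeric vector `c(XX=, XY=, YY=)` of
#'   exclusive-region counts.
#' @param pair_only named length-1 numeric vector giving one pair-only
#'   region, named `"XX.XY"`, `"XX.YY"` or `"XY.YY"`.
#' @return a `venn_partition` (see [venn_partition()]).
#' @examples
#' p <- solve_partition(c(XX = 390, XY = 454, YY = 430),
#'                      c(XX = 23, XY = 30, YY = 14), c(XY.YY = 63))
#' p$regions[["XX.XY.YY"]]  # 347
#' p$union                  # 497
#' @export
solve_partition <- function(totals, exclusives, pair_only) {
  stopifnot(setequal(names(totals), GROUPS),
            setequal(names(exclusives), GROUPS),
            length(pair_only) == 1L,
            names(pair_only) %in% c("XX.XY", "XX.YY", "XY.YY"))
  if (any(c(totals, exclusives, pair_only) < 0))
    stopf("all inputs must be non-negative")
  totals <- totals[GROUPS]
  exclusives <- exclusives[GROUPS]
  known <- names(pair_only)
  gk <- strsplit(known, ".", fixed = TRUE)[[1]]   # groups in the known pair
  g0 <- setdiff(GROUPS, gk)                        # group not in it
  # for each group in the known pair: (its other pair-only) + triple
  u <- stats::setNames(vapply(gk, function(g)
    totals[[g]] - exclusives[[g]] - pair_only[[1]], numeric(1)), gk)
  w <- totals[[g0]] - exclusives[[g0]]             # = both its pair-onlys + triple
  triple <- sum(u) - w
  regions <- stats::setNames(numeric(7), REGIONS)
  regions[GROUPS] <- exclusives
  regions[known] <- pair_only
  for (g in gk) {
    other <- paste(sort(c(g, g0)), collapse = ".")
    regions[other] <- w - u[[setdiff(gk, g)]]
  }
  regions["XX.XY.YY"] <- triple
  bad <- names(regions)[regions < 0 | abs(regions - round(regions)) > 1e-9]
  if (length(bad))
    stopf("infeasible marginals: region %s solves to a negative or non-integer count",
          paste(bad, collapse = ", "))
  new_venn_partition(round(regions))
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Three-set Venn partition\n")
  lab <- c("XX only", "XY only", "YY only", "XX&XY only", "XX&YY only",
           "XY&YY only", "all three")
  for (i in seq_along(REGIONS)) {
    cat(sprintf("  %-11s %6d  (%.1f%%)\n", lab[i],
                x$regions[[REGIONS[i]]], x$percentages[[REGIONS[i]]]))
  }
  cat(sprintf("  union %d; totals XX=%d (%.1f%%) XY=%d (%.1f%%) YY=%d (%.1f%%)\n",
              x$union, x$totals[["XX"]], x$total_percentages[["XX"]],
              x$totals[["XY"]], x$total_percentages[["XY"]],
              x$totals[["YY"]], x$total_percentages[["YY"]]))
  cat(sprintf("  pairwise co-detection: XX&XY=%d XX&YY=%d XY&YY=%d\n",
              x$pairwise[["XX.XY"]], x$pairwise[["XX.YY"]],
              x$pairwise[["XY.YY"]]))
  invisible(x)
}

#' Deterministic hierarchical clustering of expression rows
#'
#' Agglomerative clustering of miRNAs on log10-transformed NE values (zeros
#' revised to 0.01 before the log, the same convention as the scatter
#' plots), Euclidean distance and complete linkage by default. Rows are
#' sorted by id before clustering so the leaf order is independent of input
#' order.
#'
#' @param em an `expression_matrix`, or a numeric matrix of NE values with
#'   row names.
#' @param ids optional subset of row ids to cluster (default: all).
#' @param metric distance metric for [stats::dist()].
#' @param linkage linkage method for [stats::hclust()].
#' @param transform transformation applied to NE values before clustering.
#' @return list with `order` (row ids in leaf order), `hclust` (the merge
#'   tree), `values` (the transformed matrix used).
#' @export
cluster_order <- function(em, ids = NULL, metric = "euclidean",
                          linkage = "complete",
                          transform = function(v) log10(pmax(v, 0.01))) {
  ne <- if (inherits(em, "expression_matrix")) em$ne else as.matrix(em)
  if (!is.null(ids)) ne <- ne[ids, , drop = FALSE]
  if (nrow(ne) < 2) stopf("clustering needs at least two rows")
  ne <- ne[order(rownames(ne)), , drop = FALSE]
  v <- transform(ne)
  hc <- hclust(dist(v, method = metric), method = linkage)
  list(order = rownames(v)[hc$order], hclust = hc, values = v)
}
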