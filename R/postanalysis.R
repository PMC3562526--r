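# Downstream analysis of the DE probe-sets: chord-distance complete-linkage
# clustering of expression profiles, Wilcoxon functional-bin enrichment, and
# the cross-platform comparison of up-regulated gene sets.

#' Chord distance
#'
#' Euclidean distance between the two vectors rescaled to unit length:
#' `d = || x/||x|| - y/||y|| ||_2 = sqrt(2 - 2 cos(theta))`. Scale-invariant,
#' range [0, 2].
#'
#' @param x,y nonzero numeric vectors of equal length.
#' @return The chord distance.
#' @export
chord_distance <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("chord distance undefined for the zero vector", call. = FALSE)
  sqrt(sum((x / nx - y / ny)^2))
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative complete-linkage clustering under the chord distance, cut
#' into `k` clusters. Deterministic given the input row order (ties follow
#' the stable pair ordering of [stats::hclust()]).
#'
#' @param rows numeric matrix: one row per probe-set (e.g. log2 intensity
#'   vectors of the DE probe-sets), rownames = probe-set IDs.
#' @param k number of clusters (1 <= k <= nrow(rows)).
#' @return A `cluster_result` list: `probe_set_ids`, `labels` (integers in
#'   1..k), `k`, `merge` and `heights` (the agglomeration history), and the
#'   underlying `hclust` object.
#' @export
hcluster <- function(rows, k) {
  if (k < 1 || k > nrow(rows)) stop("k must lie in 1..nrow(rows)", call. = FALSE)
  norms <- sqrt(rowSums(rows^2))
  if (any(norms == 0)) stop("zero row: chord distance undefined", call. = FALSE)
  unit <- rows / norms
  hc <- stats::hclust(stats::dist(unit, method = "euclidean"), method = "complete")
  labels <- stats::cutree(hc, k = k)
  structure(list(probe_set_ids = rownames(rows),
                 labels = as.integer(labels), k = as.integer(k),
                 merge = hc$merge, heights = hc$height, hclust = hc),
            class = "cluster_result")
}

#' Partition a DE table by direction
#'
#' @param de a `de_table` from [de_test()].
#' @return List with `up` and `down`: the selected probe-set IDs with
#'   positive and negative log2 fold change. Disjoint; their union is the
#'   selected set.
#' @export
partition_direction <- function(de) {
  list(up = de$probe_set_id[de$selected & de$log2fc > 0],
       down = de$probe_set_id[de$selected & de$log2fc < 0])
}

#' Wilcoxon functional-bin enrichment
#'
#' For each annotation bin with at least `min_bin_size` scored members, a
#' two-sided Mann-Whitney rank-sum test of the members' log2 fold changes
#' against all non-members: exact enumeration when the smaller group has
#' <= 8 values and there are no ties, otherwise the normal approximation with
#' midranks, tie correction and continuity correction. BH adjustment across
#' bins. A bin is directed `"up"` when its member median log2fc exceeds the
#' non-member median.
#'
#' @param log2fc named numeric: probe-set ID -> log2 fold change (ripe vs
#'   unripe).
#' @param annotation an annotation map ([read_annotation()]).
#' @param min_bin_size smallest bin tested (default 3).
#' @return A `bin_enrichment` data frame: `bin`, `n_members`, `statistic`
#'   (rank-sum W), `p_raw`, `p_adj`, `direction`.
#' @export
wilcoxon_bin_enrichment <- function(log2fc, annotation, min_bin_size = 3) {
  bins <- annotation_bins(annotation)
  bins <- lapply(bins, intersect, names(log2fc))
  bins <- bins[lengths(bins) >= min_bin_size]
  if (!length(bins)) stop("no annotated bin of size >= ", min_bin_size, call. = FALSE)
  rows <- lapply(names(bins), function(b) {
    members <- log2fc[bins[[b]]]
    others <- log2fc[setdiff(names(log2fc), bins[[b]])]
    if (!length(others)) {
      stop("bin ", b, " contains every scored gene; enrichment undefined", call. = FALSE)
    }
    exact <- min(length(members), length(others)) <= 8 &&
      !anyDuplicated(c(members, others))
    wt <- suppressWarnings(
      stats::wilcox.test(members, others, alternative = "two.sided",
                         exact = exact, correct = TRUE)
    )
    data.frame(bin = b, n_members = length(members),
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               direction = if (stats::median(members) > stats::median(others))
                 "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out <- out[, c("bin", "n_members", "statistic", "p_raw", "p_adj", "direction")]
  class(out) <- c("bin_enrichment", "data.frame")
  out
}

#' Cross-platform comparison of up-regulated gene sets
#'
#' Each species' up-set is the genes with `log2fc >= log2_threshold`; the
#' result gives every Venn cell (exclusive counts and all intersections),
#' matching genes across platforms by shared gene identifier.
#'
#' @param tables named list (one element per species) of named numeric
#'   vectors: gene ID -> log2 fold change.
#' @param log2_threshold up-regulation threshold on the log2 scale
#'   (default 0.3).
#' @return A data frame with one row per Venn region: the species membership
#'   pattern (one logical column per species), `region` (e.g. `"papaya&tomato"`)
#'   and `count`.
#' @export
compare_up_sets <- function(tables, log2_threshold = 0.3) {
  if (length(tables) < 2L) stop("need >= 2 species tables", call. = FALSE)
  species <- names(tables)
  up <- lapply(tables, function(tab) names(tab)[tab >= log2_threshold])
  if (!length(Reduce(intersect, lapply(tables, names)))) {
    warning("no gene identifier shared across all platforms")
  }
  universe <- unique(unlist(up))
  membership <- vapply(up, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(species)))
  names(patterns) <- species
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  counts <- apply(patterns, 1, function(p) {
    sum(apply(membership, 1, function(m) all(m == p)))
  })
  out <- cbind(patterns,
               region = apply(patterns, 1, function(p)
                 paste(species[as.logical(p)], collapse = "&")),
               count = as.integer(counts))
  rownames(out) <- NULL
  out
}
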