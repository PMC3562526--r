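# Two-group differential expression with BH FDR, and mask-threshold
# optimization by DE count — the criterion that selected the published mask.

#' Differential-expression options
#'
#' @param fc_min linear-scale fold-change threshold (> 1, default 1.25, i.e.
#'   |log2fc| > log2(1.25) ~ 0.3219).
#' @param p_max p-value cutoff (default 0.05).
#' @param use_adjusted apply `p_max` to the BH-adjusted p (default) or to the
#'   raw p.
#' @param group_labels the two condition labels, reference first; the fold
#'   change is `mean(group 2) - mean(group 1)` on the log2 scale.
#' @return A `de_options` list.
#' @export
de_options <- function(fc_min = 1.25, p_max = 0.05, use_adjusted = TRUE,
                       group_labels = c("unripe", "ripe")) {
  if (!(fc_min > 1)) stop("fc_min must be > 1", call. = FALSE)
  if (!(p_max > 0 && p_max < 1)) stop("p_max must be in (0, 1)", call. = FALSE)
  if (length(group_labels) != 2L) stop("exactly two group labels", call. = FALSE)
  structure(list(fc_min = fc_min, p_max = p_max, use_adjusted = use_adjusted,
                 group_labels = group_labels), class = "de_options")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' mapped back to input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Selection rule for differential expression
#'
#' A probe-set is selected iff `|log2fc| > log2(fc_min)` and the p-value
#' (adjusted or raw per `options`) is `<= p_max`; its direction is the sign
#' of the fold change when selected, `"flat"` otherwise.
#'
#' @param log2fc numeric log2 fold changes.
#' @param p p-values on the scale chosen by `options$use_adjusted`.
#' @param options a [de_options()].
#' @return Data frame with columns `selected` and `direction`.
#' @export
classify_de <- function(log2fc, p, options = de_options()) {
  selected <- abs(log2fc) > log2(options$fc_min) & p <= options$p_max
  direction <- ifelse(!selected, "flat", ifelse(log2fc > 0, "up", "down"))
  data.frame(selected = selected, direction = direction,
             stringsAsFactors = FALSE)
}

#' Two-group differential-expression test
#'
#' Per probe-set: `log2fc = mean(log2 group2) - mean(log2 group1)`; the raw p
#' comes from a one-way ANOVA F-test with pooled variance (for two groups,
#' identical to the two-sided equal-variance t-test); BH adjustment across
#' probe-sets. Probe-sets with zero within-group variance get a variance
#' floor of 1e-12 and are flagged in `var_floored`.
#'
#' @param expr an [expr_matrix()] whose condition labels contain exactly the
#'   two groups in `options$group_labels`, each with >= 2 arrays.
#' @param options a [de_options()].
#' @return A `de_table` data frame: `probe_set_id`, `log2fc`, `p_raw`,
#'   `p_adj`, `direction`, `selected`, `var_floored`.
#' @export
de_test <- function(expr, options = de_options()) {
  cond <- conditions(expr)
  g1 <- cond == options$group_labels[1]
  g2 <- cond == options$group_labels[2]
  if (!setequal(unique(cond), options$group_labels)) {
    stop("expression matrix must contain exactly the two groups ",
         paste(options$group_labels, collapse = ", "), call. = FALSE)
  }
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 replicate arrays", call. = FALSE)
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, g2, drop = FALSE])
  ss1 <- rowSums((expr[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((expr[, g2, drop = FALSE] - m2)^2)
  df_w <- n1 + n2 - 2L
  pooled <- (ss1 + ss2) / df_w
  floored <- pooled < 1e-12
  pooled[floored] <- 1e-12
  f_stat <- (m2 - m1)^2 / (pooled * (1 / n1 + 1 / n2))
  p_raw <- stats::pf(f_stat, 1, df_w, lower.tail = FALSE)
  p_adj <- bh_adjust(p_raw)
  log2fc <- m2 - m1
  cls <- classify_de(log2fc, if (options$use_adjusted) p_adj else p_raw, options)
  out <- data.frame(probe_set_id = rownames(expr), log2fc = log2fc,
                    p_raw = p_raw, p_adj = p_adj,
                    direction = cls$direction, selected = cls$selected,
                    var_floored = floored,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Optimize the mask threshold by differential-expression count
#'
#' For each threshold: build the gDNA mask, apply it, run mask-aware RMA and
#' the DE test, and count selected probe-sets. The best threshold is the
#' smallest one attaining the maximal count (ties go to the smaller
#' threshold, i.e. the larger retained chip). A threshold that eliminates
#' every probe-set contributes a count of 0.
#'
#' @param gdna list of gDNA [probe_intensities()] tables.
#' @param rna list of RNA [probe_intensities()] tables.
#' @param layout the full [chip_layout()].
#' @param thresholds strictly increasing sweep (default 0, 25, ..., 500).
#' @param options a [de_options()].
#' @param background,quantile passed to [rma()].
#' @return A `mask_optimization` list: `thresholds`, `de_counts`,
#'   `best_threshold`, `best_count`.
#' @export
optimize_mask_threshold <- function(gdna, rna, layout,
                                    thresholds = seq(0, 500, by = 25),
                                    options = de_options(),
                                    background = TRUE, quantile = TRUE) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  de_counts <- vapply(thresholds, function(t) {
    mask <- build_mask(gdna, layout, t)
    if (!length(mask$retained_sets)) return(0L)
    masked <- apply_mask(layout, mask)
    expr <- rma(rna, masked, background = background, quantile = quantile)
    sum(de_test(expr, options)$selected)
  }, integer(1))
  best <- which.max(de_counts)  # which.max returns the first (smallest) argmax
  structure(list(thresholds = thresholds, de_counts = de_counts,
                 best_threshold = thresholds[best],
                 best_count = de_counts[best]),
            class = "mask_optimization")
}
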