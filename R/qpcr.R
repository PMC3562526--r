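# Relative-standard-curve qPCR quantification with dual reference-gene
# normalization, calibrator scaling, and ANOVA + Tukey significance across
# ripening time points.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 template quantity over a dilution
#' series. The amplification efficiency is `E = 10^(-1/slope) - 1`; a slope
#' of `-1/log10(2)` (about -3.3219) corresponds to perfect doubling (E = 1).
#'
#' @param dilutions data frame with columns `log10_quantity` and `ct`
#'   (>= 3 distinct quantities).
#' @return A `standard_curve` list: `slope`, `intercept`, `r2`, `efficiency`.
#' @export
fit_standard_curve <- function(dilutions) {
  if (!all(c("log10_quantity", "ct") %in% names(dilutions))) {
    stop("dilutions must have columns log10_quantity and ct", call. = FALSE)
  }
  if (length(unique(dilutions$log10_quantity)) < 3) {
    stop("need >= 3 distinct dilution points", call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10_quantity, data = dilutions)
  slope <- unname(stats::coef(fit)[2])
  tss <- sum((dilutions$ct - mean(dilutions$ct))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / tss
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' Quantify template from a Ct value
#'
#' Inverts the standard curve: `quantity = 10^((ct - intercept) / slope)`
#' (arbitrary units, relative to the dilution series).
#'
#' @param ct threshold-cycle value(s).
#' @param curve a [fit_standard_curve()] result; slope must be negative.
#' @return Quantity, strictly decreasing in `ct`.
#' @export
quantify <- function(ct, curve) {
  if (curve$slope >= 0) stop("standard-curve slope must be negative", call. = FALSE)
  10^((ct - curve$intercept) / curve$slope)
}

#' Average technical replicates at the Ct level
#'
#' @param measurements data frame with columns `gene`, `sample`, `replicate`,
#'   `ct` (>= 2 technical replicates per gene x sample).
#' @return Data frame `gene`, `sample`, `ct` (the mean Ct).
#' @export
average_ct <- function(measurements) {
  if (any(measurements$ct <= 0)) stop("ct must be > 0", call. = FALSE)
  n <- stats::aggregate(ct ~ gene + sample, measurements, length)
  if (any(n$ct < 2)) {
    stop("need >= 2 technical replicates per gene and sample", call. = FALSE)
  }
  stats::aggregate(ct ~ gene + sample, measurements, mean)
}

#' Relative expression by the standard-curve method
#'
#' Target quantities are normalized by the geometric mean of the reference
#' genes' quantities, then scaled so the calibrator sample equals exactly 1.
#'
#' @param target named numeric: sample -> target-gene quantity.
#' @param references list of named numeric vectors, one per reference gene
#'   (e.g. actin and 18S), each covering every sample.
#' @param calibrator name of the calibrator sample (e.g. first day after
#'   harvest).
#' @return Named numeric of relative expression values;
#'   `result[calibrator] == 1`.
#' @export
relative_expression <- function(target, references, calibrator) {
  samples <- names(target)
  if (!calibrator %in% samples) stop("calibrator sample not present", call. = FALSE)
  ref_mat <- vapply(references, function(r) {
    if (!all(samples %in% names(r))) {
      stop("reference gene missing a sample quantity", call. = FALSE)
    }
    r[samples]
  }, numeric(length(samples)))
  if (length(samples) == 1L) ref_mat <- matrix(ref_mat, nrow = 1L)
  if (any(ref_mat <= 0)) stop("reference quantities must be > 0", call. = FALSE)
  geo <- exp(rowMeans(log(ref_mat)))
  normalized <- target / geo
  normalized / normalized[[calibrator]]
}

#' One-way ANOVA with Tukey HSD across time points
#'
#' Tests whether any sample differs, then compares all sample pairs with
#' Tukey's honestly-significant-difference test (Tukey-Kramer for unbalanced
#' groups) and reports which samples differ from the calibrator at `alpha`.
#'
#' @param groups named list: sample -> numeric replicate values (>= 2 each).
#' @param calibrator name of the calibrator sample.
#' @param alpha familywise significance level (default 0.05).
#' @return List: `f` and `p` (overall ANOVA), `tukey` (data frame of pairs,
#'   differences, adjusted p), `differs_from_calibrator` (named logical).
#' @export
anova_tukey <- function(groups, calibrator, alpha = 0.05) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) stop("every group needs >= 2 replicates", call. = FALSE)
  if (!calibrator %in% names(groups)) stop("calibrator group not present", call. = FALSE)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    sample = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- stats::aov(value ~ sample, data = df)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$sample
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  tukey <- data.frame(group1 = pairs[, 2], group2 = pairs[, 1],
                      diff = tk[, "diff"], p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL, stringsAsFactors = FALSE)
  others <- setdiff(names(groups), calibrator)
  differs <- vapply(others, function(s) {
    row <- tukey$significant[(tukey$group1 == calibrator & tukey$group2 == s) |
                               (tukey$group1 == s & tukey$group2 == calibrator)]
    any(row)
  }, logical(1))
  list(f = tab[1, "F value"], p = tab[1, "Pr(>F)"], tukey = tukey,
       differs_from_calibrator = differs)
}
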