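#' @keywords internal
#' @aliases xspecies-package
"_PACKAGE"

#' Run the masked expression pipeline on a dataset
#'
#' Convenience wrapper over the stage functions: build the gDNA mask at one
#' threshold, apply it, summarize with mask-aware RMA, and test for
#' differential expression.
#'
#' @param dataset a `sim_dataset` (or any list with `gdna`, `rna`, `layout`).
#' @param threshold gDNA mask threshold; `0` keeps every probe-pair.
#' @param options a [de_options()].
#' @param background,quantile passed to [rma()].
#' @return List: `mask`, `masked_layout`, `expr` (an [expr_matrix()]), `de`
#'   (a `de_table`).
#' @export
masked_de_pipeline <- function(dataset, threshold, options = de_options(),
                               background = TRUE, quantile = TRUE) {
  mask <- build_mask(dataset$gdna, dataset$layout, threshold)
  masked <- apply_mask(dataset$layout, mask)
  expr <- rma(dataset$rna, masked, background = background, quantile = quantile)
  de <- de_test(expr, options)
  list(mask = mask, masked_layout = masked, expr = expr, de = de)
}
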