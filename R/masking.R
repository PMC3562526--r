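# gDNA-based probe masking.
#
# The cross-species premise: probes whose sequence diverges from the target
# species hybridize weakly to its genomic DNA, so the gDNA hybridization
# signal ranks probes by how well they can interrogate the target
# transcriptome. A probe-pair is retained if its mean gDNA PM signal exceeds
# a threshold (strict >); a probe-set is retained if it keeps at least two
# pairs.

#' Build a probe mask from gDNA hybridizations
#'
#' @param gdna list of gDNA [probe_intensities()] tables (>= 1); multiple
#'   arrays are combined by the arithmetic mean per probe before
#'   thresholding.
#' @param layout the [chip_layout()] being masked.
#' @param threshold nonnegative intensity threshold; a pair is retained iff
#'   its mean gDNA PM intensity is strictly greater.
#' @return A `probe_mask`: list with `threshold`, `retained_pairs` (named
#'   list probe-set ID -> integer pair ranks) and `retained_sets` (character;
#'   exactly the sets keeping >= 2 pairs).
#' @export
build_mask <- function(gdna, layout, threshold) {
  if (!length(gdna)) stop("need at least one gDNA intensity table", call. = FALSE)
  if (threshold < 0) stop("threshold must be nonnegative", call. = FALSE)
  pm <- as.character(layout$pm_index)
  sig <- rowMeans(vapply(gdna, function(g) g$intensities[pm],
                         numeric(length(pm))))
  keep <- sig > threshold
  retained_pairs <- lapply(split(data.frame(rank = layout$pair_rank, keep = keep),
                                 layout$probe_set_id),
                           function(d) d$rank[d$keep])
  retained_pairs <- retained_pairs[probe_set_ids(layout)]  # layout order
  retained_sets <- names(retained_pairs)[lengths(retained_pairs) >= 2L]
  structure(list(threshold = threshold,
                 retained_pairs = retained_pairs,
                 retained_sets = retained_sets),
            class = "probe_mask")
}

#' Probe-pair and probe-set retention across a threshold sweep
#'
#' @param gdna,layout as in [build_mask()].
#' @param thresholds strictly increasing nonnegative thresholds (the sweep
#'   used for mask optimization; default lattice 0, 25, ..., 500).
#' @return A `retention_curve` data frame with columns `threshold`,
#'   `n_pairs_retained`, `n_sets_retained`.
#' @export
retention_curve <- function(gdna, layout, thresholds = seq(0, 500, by = 25)) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  counts <- vapply(thresholds, function(t) {
    m <- build_mask(gdna, layout, t)
    c(sum(lengths(m$retained_pairs[m$retained_sets])), length(m$retained_sets))
  }, numeric(2))
  out <- data.frame(threshold = thresholds,
                    n_pairs_retained = as.integer(counts[1, ]),
                    n_sets_retained = as.integer(counts[2, ]))
  class(out) <- c("retention_curve", "data.frame")
  out
}

#' Apply a probe mask to a chip layout
#'
#' Returns the masked layout: exactly the retained probe-sets, each with
#' exactly its retained pairs, original pair ranks and order preserved.
#'
#' @param layout the [chip_layout()] the mask was built on.
#' @param mask a `probe_mask` from [build_mask()].
#' @return A `chip_layout` (ranks may be non-contiguous after masking).
#' @export
apply_mask <- function(layout, mask) {
  unknown <- setdiff(names(mask$retained_pairs), probe_set_ids(layout))
  if (length(unknown)) {
    stop("mask refers to probe-set(s) absent from layout: ", unknown[1], call. = FALSE)
  }
  if (!length(mask$retained_sets)) {
    stop("mask retains no probe-set at threshold ", mask$threshold,
         "; refusing to build an empty layout", call. = FALSE)
  }
  keep <- logical(nrow(layout))
  for (s in mask$retained_sets) {
    keep <- keep | (layout$probe_set_id == s &
                      layout$pair_rank %in% mask$retained_pairs[[s]])
  }
  sub <- layout[keep, , drop = FALSE]
  chip_layout(sub$probe_set_id, sub$pair_rank, sub$pm_index, sub$mm_index,
              chip_name = attr(layout, "chip_name"), contiguous_ranks = FALSE)
}

#' Write / read a probe mask (TSV: `probe_set_id  retained_ranks`)
#' @param mask a `probe_mask`.
#' @param path file path.
#' @return `path` invisibly (write); a `probe_mask` (read).
#' @export
write_mask <- function(mask, path) {
  df <- data.frame(
    probe_set_id = names(mask$retained_pairs),
    retained_ranks = vapply(mask$retained_pairs, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#threshold=", format(mask$threshold, digits = 15)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  thr <- as.numeric(sub("^#threshold=", "", lines[1]))
  df <- utils::read.delim(text = lines[-1], stringsAsFactors = FALSE,
                          na.strings = NULL)
  pairs <- lapply(strsplit(df$retained_ranks, ";", fixed = TRUE), as.integer)
  pairs <- lapply(pairs, function(x) x[!is.na(x)])
  names(pairs) <- df$probe_set_id
  structure(list(threshold = thr, retained_pairs = pairs,
                 retained_sets = names(pairs)[lengths(pairs) >= 2L]),
            class = "probe_mask")
}
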