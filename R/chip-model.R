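# Domain containers for the cross-species chip analysis.
#
# A chip layout maps probe-set IDs to ordered probe-pairs (the CDF role on
# Affymetrix chips); probe intensities are per-array probe-level signals (the
# CEL role); an expression matrix holds probe-set x array log2 expression.
# All on-disk formats are plain UTF-8 TSV so fixtures stay human-readable.

#' Construct a chip layout
#'
#' A chip layout maps each probe-set ID to its ordered probe-pairs, playing
#' the role of an Affymetrix chip definition file (CDF). Each probe-pair has
#' a perfect-match (PM) probe index, an optional mismatch (MM) index, and a
#' 1-based rank within its probe-set.
#'
#' @param probe_set_id character vector of probe-set IDs (one row per pair).
#' @param pair_rank integer rank of the pair within its probe-set (1-based).
#' @param pm_index integer PM probe address, unique chip-wide (0-based).
#' @param mm_index integer MM probe address or `NA`.
#' @param chip_name single string naming the chip.
#' @param contiguous_ranks if `TRUE` (fresh layouts) ranks must be 1..n per
#'   probe-set; masked layouts keep their original, possibly gappy, ranks.
#' @return A `chip_layout`: a data frame with the four columns above and a
#'   `chip_name` attribute.
#' @export
chip_layout <- function(probe_set_id, pair_rank, pm_index, mm_index = NA_integer_,
                        chip_name = "synthetic", contiguous_ranks = TRUE) {
  layout <- data.frame(
    probe_set_id = as.character(probe_set_id),
    pair_rank = as.integer(pair_rank),
    pm_index = as.integer(pm_index),
    mm_index = as.integer(mm_index),
    stringsAsFactors = FALSE
  )
  attr(layout, "chip_name") <- chip_name
  class(layout) <- c("chip_layout", "data.frame")
  validate_layout(layout, contiguous_ranks = contiguous_ranks)
  layout
}

validate_layout <- function(layout, contiguous_ranks = TRUE) {
  if (nrow(layout) == 0L) stop("layout has no probe-pairs", call. = FALSE)
  if (anyNA(layout$pm_index)) stop("pm_index must be integer, got NA", call. = FALSE)
  dup <- duplicated(layout$pm_index)
  if (any(dup)) {
    stop("pm_index not unique chip-wide: ", layout$pm_index[dup][1], call. = FALSE)
  }
  key <- paste(layout$probe_set_id, layout$pair_rank)
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1]
    stop("duplicated (probe_set_id, pair_rank): ", bad, call. = FALSE)
  }
  for (ranks in split(layout$pair_rank, layout$probe_set_id)) {
    if (any(ranks < 1L)) stop("pair_rank must be >= 1", call. = FALSE)
    if (is.unsorted(ranks, strictly = TRUE)) {
      stop("pair_rank must be strictly increasing within a probe-set", call. = FALSE)
    }
    if (contiguous_ranks && !identical(as.integer(ranks), seq_along(ranks))) {
      stop("pair_rank must be contiguous 1..n within a probe-set", call. = FALSE)
    }
  }
  invisible(layout)
}

#' Probe-set IDs of a layout
#' @param layout a `chip_layout`.
#' @return Character vector of unique probe-set IDs in layout order.
#' @export
probe_set_ids <- function(layout) unique(layout$probe_set_id)

#' Read a chip layout from TSV
#'
#' Expects a tab-delimited file with header
#' `probe_set_id  pair_rank  pm_index  mm_index` (`mm_index` may be `NA`).
#' Row order within a probe-set defines the pair_rank order.
#'
#' @param path file path.
#' @param contiguous_ranks passed to the validator; masked layouts written by
#'   [write_layout()] may have non-contiguous ranks.
#' @return A `chip_layout`.
#' @export
read_layout <- function(path, contiguous_ranks = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_set_id", "pair_rank", "pm_index", "mm_index")
  if (!all(need %in% names(df))) {
    stop("layout file must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  for (col in c("pair_rank", "pm_index")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v)) stop("non-integer ", col, " in layout file", call. = FALSE)
    df[[col]] <- v
  }
  df$mm_index <- suppressWarnings(as.integer(df$mm_index))
  chip_layout(df$probe_set_id, df$pair_rank, df$pm_index, df$mm_index,
              chip_name = basename(path), contiguous_ranks = contiguous_ranks)
}

#' Write a chip layout to TSV
#' @param layout a `chip_layout`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(as.data.frame(layout)[, c("probe_set_id", "pair_rank",
                                               "pm_index", "mm_index")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a probe-intensity table
#'
#' Per-array probe-level fluorescence intensities (the CEL-file role).
#' Genomic-DNA (`gdna`) and RNA (`rna`) hybridizations share this container.
#'
#' @param array_id single string.
#' @param kind `"gdna"` or `"rna"`.
#' @param condition condition label (e.g. `"unripe"`); empty for gDNA arrays.
#' @param intensities numeric vector of nonnegative intensities named by
#'   probe index.
#' @return A `probe_intensities` object.
#' @export
probe_intensities <- function(array_id, kind, condition, intensities) {
  kind <- match.arg(kind, c("gdna", "rna"))
  if (is.null(names(intensities))) stop("intensities must be named by probe index", call. = FALSE)
  if (any(!is.finite(intensities))) stop("non-finite intensity", call. = FALSE)
  if (any(intensities < 0)) {
    stop("negative intensity for probe ", names(intensities)[intensities < 0][1], call. = FALSE)
  }
  structure(list(array_id = array_id, kind = kind, condition = condition,
                 intensities = intensities),
            class = "probe_intensities")
}

#' Read a probe-intensity table from TSV
#'
#' Metadata lines `#array_id=`, `#kind=`, `#condition=` precede a header
#' `probe_index  intensity`. The table must cover every PM probe of `layout`.
#'
#' @param path file path.
#' @param layout the `chip_layout` the array was hybridized against.
#' @return A `probe_intensities` object.
#' @export
read_intensities <- function(path, layout) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(array_id = basename(path), kind = "rna", condition = "")
  for (m in meta_lines) {
    kv <- sub("^#", "", m)
    key <- sub("=.*$", "", kv)
    if (key %in% names(meta)) meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  if (!all(c("probe_index", "intensity") %in% names(df))) {
    stop("intensity file must have columns probe_index, intensity", call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(df$intensity))
  if (anyNA(vals)) stop("non-numeric intensity in ", path, call. = FALSE)
  if (any(vals < 0)) {
    stop("negative intensity for probe ", df$probe_index[vals < 0][1], call. = FALSE)
  }
  intens <- stats::setNames(vals, as.character(df$probe_index))
  missing <- setdiff(as.character(layout$pm_index), names(intens))
  if (length(missing)) {
    stop("intensity table does not cover PM probe ", missing[1],
         " (and ", length(missing) - 1L, " more)", call. = FALSE)
  }
  probe_intensities(meta$array_id, meta$kind, meta$condition, intens)
}

#' Write a probe-intensity table to TSV
#' @param tab a `probe_intensities` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_intensities <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#array_id=", tab$array_id),
               paste0("#kind=", tab$kind),
               paste0("#condition=", tab$condition),
               "probe_index\tintensity"), con)
  writeLines(paste(names(tab$intensities),
                   format(tab$intensities, digits = 15, trim = TRUE, scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}

#' Construct an expression matrix
#'
#' Probe-set x array matrix of log2 expression values with per-array
#' condition labels.
#'
#' @param values numeric matrix, rownames = probe-set IDs, colnames = array IDs.
#' @param conditions character vector of condition labels, one per column.
#' @return An `expr_matrix`.
#' @export
expr_matrix <- function(values, conditions) {
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  if (nrow(values) == 0L) stop("refusing an expression matrix with no probe-sets", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have row and column names", call. = FALSE)
  }
  if (length(conditions) != ncol(values)) {
    stop("one condition label per array required", call. = FALSE)
  }
  if (anyNA(values)) stop("expression matrix has missing cells", call. = FALSE)
  structure(values, conditions = as.character(conditions),
            class = c("expr_matrix", "matrix", "array"))
}

#' Condition labels of an expression matrix
#' @param x an `expr_matrix`.
#' @return Character vector, one label per array column.
#' @export
conditions <- function(x) attr(x, "conditions")

#' Write / read an expression matrix (TSV)
#'
#' The file carries one `#condition` metadata line aligned with the array
#' columns, then a header row `probe_set_id <array ids...>`. Values round-trip
#' to at least 12 significant digits.
#'
#' @param mat an `expr_matrix`.
#' @param path file path.
#' @return `path` invisibly (write); an `expr_matrix` (read).
#' @export
write_expression_matrix <- function(mat, path) {
  if (nrow(mat) == 0L) stop("refusing to write an empty expression matrix", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#condition", conditions(mat)), collapse = "\t"), con)
  writeLines(paste(c("probe_set_id", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1, function(r) paste(format(r, digits = 15, trim = TRUE), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#condition")) {
    stop("expression matrix file must start with a #condition line", call. = FALSE)
  }
  cond <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  header <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  array_ids <- header[-1]
  if (length(cond) != length(array_ids)) {
    stop("condition line and header disagree on array count", call. = FALSE)
  }
  rows <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  if (any(lengths(rows) != length(header))) {
    stop("row with wrong number of fields in expression matrix file", call. = FALSE)
  }
  ids <- vapply(rows, `[[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(array_ids))))
  if (length(array_ids) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(ids, array_ids)
  expr_matrix(vals, cond)
}

#' Read / write a probe-set annotation map (TSV)
#'
#' Columns: `probe_set_id  gene_id  bins  go`, with `bins` (functional
#' category codes) and `go` semicolon-joined; either may be empty.
#' Annotation is partial: probe-sets absent from the map are permitted.
#'
#' @param path file path.
#' @return A data frame with class `annotation_map`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  if (!all(c("probe_set_id", "gene_id", "bins") %in% names(df))) {
    stop("annotation file must have columns probe_set_id, gene_id, bins", call. = FALSE)
  }
  if (is.null(df$go)) df$go <- ""
  if (anyDuplicated(df$probe_set_id)) {
    stop("duplicated probe_set_id in annotation: ",
         df$probe_set_id[duplicated(df$probe_set_id)][1], call. = FALSE)
  }
  class(df) <- c("annotation_map", "data.frame")
  df
}

#' @rdname read_annotation
#' @param annot an `annotation_map` data frame.
#' @export
write_annotation <- function(annot, path) {
  utils::write.table(as.data.frame(annot), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bin membership from an annotation map
#' @param annot an `annotation_map`.
#' @return Named list: bin code -> character vector of probe-set IDs.
#' @export
annotation_bins <- function(annot) {
  pieces <- strsplit(annot$bins, ";", fixed = TRUE)
  long <- data.frame(
    probe_set_id = rep(annot$probe_set_id, lengths(pieces)),
    bin = unlist(pieces),
    stringsAsFactors = FALSE
  )
  long <- long[nzchar(long$bin), , drop = FALSE]
  split(long$probe_set_id, long$bin)
}

#' Write / read a differential-expression table (TSV)
#' @param de a `de_table` data frame from [de_test()].
#' @param path file path.
#' @return `path` invisibly (write); a `de_table` (read).
#' @export
write_de_table <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$selected <- as.logical(df$selected)
  class(df) <- c("de_table", "data.frame")
  df
}
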