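# Comparative stage: p-distances from aligned amino-acid sequences and
# neighbor-joining trees with Newick output.

#' Read an aligned amino-acid FASTA
#'
#' @param path aligned FASTA; all sequences must have equal length and the
#'   alignment must contain >= 3 uniquely labelled taxa.
#' @return An `aa_alignment`: character matrix, one row per taxon (rownames =
#'   labels), one column per alignment position, gaps as `"-"`.
#' @export
read_alignment <- function(path) {
  seqs <- ape::read.FASTA(path, type = "AA")
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned: unequal lengths", call. = FALSE)
  }
  aln <- toupper(as.character(as.matrix(seqs)))
  as_alignment(aln)
}

#' @rdname read_alignment
#' @param x character matrix (or named character vector of equal-length
#'   strings) of aligned sequences.
#' @export
as_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (length(unique(nchar(x))) != 1L) {
      stop("sequences are not aligned: unequal lengths", call. = FALSE)
    }
    x <- do.call(rbind, strsplit(toupper(x), ""))
  }
  if (nrow(x) < 3L) stop("alignment needs >= 3 taxa", call. = FALSE)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop("taxon labels must be present and unique", call. = FALSE)
  }
  structure(x, class = c("aa_alignment", "matrix", "array"))
}

#' Pairwise p-distance matrix
#'
#' Uncorrected proportion of differing residues under pairwise gap deletion:
#' for each pair of taxa, sites where either sequence has a gap (`-`) are
#' excluded, and the distance is differences / comparable sites. p-distances
#' lie in [0, 1] but need not satisfy the triangle inequality.
#'
#' @param aln an alignment from [read_alignment()] or [as_alignment()].
#' @return A `dist_matrix`: symmetric numeric matrix with zero diagonal and
#'   taxon dimnames.
#' @export
p_distance_matrix <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- aln[i, ] != "-" & aln[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable position between ", rownames(aln)[i], " and ",
             rownames(aln)[j], call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(aln[i, ok] != aln[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix: iteratively
#' joins the pair minimizing the Q-criterion, with branch lengths from the
#' standard formulas. Additive input distances are reproduced exactly by the
#' tree's path lengths. Negative branch lengths, when the input is
#' non-additive, are retained as computed. The tree is unrooted.
#'
#' @param dm symmetric numeric distance matrix with taxon dimnames (>= 3
#'   taxa) or a `dist` object.
#' @return An unrooted `phylo` tree (ape) with branch lengths in the input
#'   distance units (residue substitutions per site for p-distances).
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm))) stop("distance matrix must be symmetric", call. = FALSE)
  if (nrow(dm) < 3L) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  ape::nj(stats::as.dist(dm))
}

#' Write / read a Newick tree
#'
#' Writes standard Newick with branch lengths formatted to 6 decimal places;
#' a round trip preserves topology and lengths to 1e-6. Sibling subtrees are
#' serialized in alphabetical order of their smallest tip label, so equal
#' trees produce identical files.
#'
#' @param tree a `phylo` tree.
#' @param path file path.
#' @return `path` invisibly (write); a `phylo` tree (read).
#' @export
write_newick <- function(tree, path) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf("%.6f", x)
  min_tip <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[children[[as.character(node)]], 2]
    min(vapply(kids, min_tip, ""))
  }
  ser <- function(node, edge_idx) {
    len <- if (is.na(edge_idx)) "" else paste0(":", fmt(tree$edge.length[edge_idx]))
    if (node <= ntip) return(paste0(tree$tip.label[node], len))
    kid_edges <- children[[as.character(node)]]
    kid_edges <- kid_edges[order(vapply(kid_edges,
                                        function(e) min_tip(tree$edge[e, 2]), ""))]
    inner <- paste(vapply(kid_edges, function(e) ser(tree$edge[e, 2], e), ""),
                   collapse = ",")
    paste0("(", inner, ")", len)
  }
  writeLines(paste0(ser(root, NA_integer_), ";"), path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed Newick in ", path, call. = FALSE)
  tree
}

#' Path-length (patristic) distance matrix of a tree
#'
#' Used to verify that neighbor joining reproduces additive distances.
#'
#' @param tree a `phylo` tree.
#' @return Symmetric matrix of tip-to-tip path lengths, taxon dimnames,
#'   in taxon-label order.
#' @export
tree_path_distances <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[order(rownames(m)), order(colnames(m))]
}
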