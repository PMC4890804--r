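#' A signed gene list for one comparison
#'
#' Holds the up- and down-regulated gene identifiers called significant in
#' one group-vs-group comparison. The two directions must be disjoint.
#'
#' @param label comparison label (e.g. \code{"mTBI_vs_sham"}).
#' @param up,down character vectors of gene/probe identifiers.
#' @return an object of class \code{"signed_gene_list"}.
#' @export
signed_gene_list <- function(label, up = character(), down = character()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  both <- intersect(up, down)
  if (length(both)) {
    stop("gene(s) listed both up and down in ", label, ": ",
         paste(both, collapse = ", "))
  }
  structure(list(label = label, up = up, down = down),
            class = "signed_gene_list")
}

#' Extract the signed significant-gene list from a comparison result
#'
#' @param result a data frame from \code{\link{compare_groups}} (or any
#'   frame with \code{probe_id}, \code{significant}, \code{direction}).
#' @param label comparison label; defaults to the result's
#'   \code{"comparison"} attribute joined as \code{"A_vs_B"}.
#' @return a \code{\link{signed_gene_list}}.
#' @export
significant_genes <- function(result, label = NULL) {
  stopifnot(is.data.frame(result))
  if (is.null(label)) {
    cmp <- attr(result, "comparison")
    label <- if (is.null(cmp)) "comparison" else paste(cmp, collapse = "_vs_")
  }
  signed_gene_list(label,
                   up = result$probe_id[result$significant &
                                          result$direction == "up"],
                   down = result$probe_id[result$significant &
                                            result$direction == "down"])
}

# The 7 regions of a 3-set Venn for one direction, as disjoint sets.
venn3_regions <- function(a, b, c_, labels) {
  only <- function(x, y, z) setdiff(x, union(y, z))
  pair <- function(x, y, z) setdiff(intersect(x, y), z)
  regions <- list(only(a, b, c_), only(b, a, c_), only(c_, a, b),
                  pair(a, b, c_), pair(a, c_, b), pair(b, c_, a),
                  Reduce(intersect, list(a, b, c_)))
  names(regions) <- c(labels,
                      paste(labels[1], labels[2], sep = "&"),
                      paste(labels[1], labels[3], sep = "&"),
                      paste(labels[2], labels[3], sep = "&"),
                      paste(labels, collapse = "&"))
  lapply(regions, sort)
}

#' Signed three-way Venn partition of significant-gene lists
#'
#' Partitions the up-regulated and the down-regulated gene lists of exactly
#' three comparisons into the seven disjoint regions of a 3-set Venn
#' diagram, separately per direction (a gene up in one comparison and down
#' in another contributes to both direction-specific diagrams). Region names
#' join the contributing comparison labels with \code{"&"}; a bare label is
#' that comparison's exclusive region.
#'
#' @param lists a list of exactly three \code{\link{signed_gene_list}}
#'   objects with distinct labels.
#' @return an object of class \code{"venn_partition"}: list with
#'   \code{labels}, \code{up} and \code{down} (each a named list of 7
#'   sorted region member vectors), and \code{counts} (7 x 2 matrix).
#' @export
partition_signed <- function(lists) {
  if (length(lists) != 3L ||
      !all(vapply(lists, inherits, logical(1), "signed_gene_list"))) {
    stop("partition_signed needs exactly 3 signed_gene_list objects")
  }
  labels <- vapply(lists, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate comparison labels")
  up <- venn3_regions(lists[[1]]$up, lists[[2]]$up, lists[[3]]$up, labels)
  down <- venn3_regions(lists[[1]]$down, lists[[2]]$down, lists[[3]]$down,
                        labels)
  counts <- cbind(up = lengths(up), down = lengths(down))
  structure(list(labels = labels, up = up, down = down, counts = counts),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition of", paste(x$labels, collapse = ", "), "\n")
  print(x$counts)
  invisible(x)
}

#' Genes whose regulation is reversed between two comparisons
#'
#' The "treatment reverses injury" signature: genes up in comparison
#' \code{a} and down in \code{b}, or down in \code{a} and up in \code{b}.
#'
#' @param a,b \code{\link{signed_gene_list}} objects.
#' @return sorted character vector of reversed gene identifiers.
#' @export
reversal_genes <- function(a, b) {
  stopifnot(inherits(a, "signed_gene_list"), inherits(b, "signed_gene_list"))
  sort(union(intersect(a$up, b$down), intersect(a$down, b$up)))
}
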