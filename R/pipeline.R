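#' Run the full expression-analysis pipeline
#'
#' Orchestrates, for each requested group-vs-control comparison:
#' log transform, per-array Z-score normalization, Z-ratio statistics with
#' the five-criterion significance filter, optional PAGE enrichment over a
#' GMT collection, and — when exactly three comparisons are run — the
#' signed three-way Venn partition of the significant-gene lists plus an
#' optional reversal-gene report for one comparison pair. All outputs are
#' plain TSV/JSON under \code{out_dir}; the run is a pure function of its
#' inputs (no randomness), so reruns are byte-identical.
#'
#' @param expression an \code{\link{expression_matrix}} (raw scale) or a
#'   path readable by \code{\link{read_expression_matrix}}.
#' @param design a \code{\link{sample_design}} or a path readable by
#'   \code{\link{read_design}}.
#' @param comparisons list of length-2 character vectors \code{c(A, B)}
#'   (A vs control B). Default: every non-first group vs the first design
#'   group (with the study design, mTBI / mTBI_PHEN / PHEN each vs sham).
#' @param thresholds a \code{\link{selection_thresholds}} object.
#' @param gene_sets optional \code{\link{gene_set_collection}} or GMT path;
#'   enables PAGE enrichment per comparison.
#' @param reversal_pair optional indices or labels of two comparisons for
#'   the reversal-gene report.
#' @param out_dir output directory, created if needed.
#' @param log_base,floor log-transform settings.
#' @param min_set_size minimum PAGE set size.
#' @param dialect expression-file dialect when \code{expression} is a path.
#' @return the manifest (also written as \code{manifest.json}), invisibly.
#' @export
run_pipeline <- function(expression, design, comparisons = NULL,
                         thresholds = selection_thresholds(),
                         gene_sets = NULL, reversal_pair = NULL,
                         out_dir = "zratio_run", log_base = 10, floor = 1,
                         min_set_size = 10, dialect = "tsv") {
  if (is.character(expression)) {
    expression <- read_expression_matrix(expression, dialect = dialect)
  }
  if (is.character(design)) design <- read_design(design)
  if (is.character(gene_sets)) gene_sets <- read_gene_sets(gene_sets)
  stopifnot(inherits(expression, "expression_matrix"),
            inherits(design, "sample_design"))
  if (is.null(comparisons)) {
    ctrl <- design$groups[1L]
    comparisons <- lapply(setdiff(design$groups, ctrl), function(g) c(g, ctrl))
  }
  for (cmp in comparisons) {
    if (length(cmp) != 2L || !all(cmp %in% design$groups)) {
      stop("each comparison must be two known group labels")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- vapply(comparisons, paste, character(1), collapse = "_vs_")
  if (anyDuplicated(labels)) stop("duplicate comparisons requested")

  signed <- list()
  counts <- list()
  for (i in seq_along(comparisons)) {
    cmp <- comparisons[[i]]
    res <- compare_groups(expression, design, cmp[1], cmp[2],
                          thresholds = thresholds, log_base = log_base,
                          floor = floor)
    utils::write.table(res, file.path(out_dir,
                                      paste0("diffexp_", labels[i], ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sg <- significant_genes(res, label = labels[i])
    signed[[labels[i]]] <- sg
    counts[[labels[i]]] <- list(
      probes_tested = nrow(res),
      probes_excluded = length(attr(res, "excluded_probes")),
      significant_up = length(sg$up),
      significant_down = length(sg$down))
    if (!is.null(gene_sets)) {
      zr <- stats::setNames(res$z_ratio, res$probe_id)
      enr <- withCallingHandlers(
        page_enrichment(zr, gene_sets, min_size = min_set_size),
        warning = function(w) invokeRestart("muffleWarning"))
      utils::write.table(enr, file.path(out_dir,
                                        paste0("enrichment_", labels[i], ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      counts[[labels[i]]]$sets_scored <- nrow(enr)
      counts[[labels[i]]]$sets_undersized <- attr(enr, "n_undersized")
    }
  }

  venn <- NULL
  if (length(signed) == 3L) {
    venn <- partition_signed(unname(signed))
    jsonlite::write_json(
      list(labels = venn$labels,
           counts = list(up = as.list(venn$counts[, "up"]),
                         down = as.list(venn$counts[, "down"])),
           up = venn$up, down = venn$down),
      file.path(out_dir, "venn_partition.json"), auto_unbox = TRUE,
      pretty = TRUE)
  }
  if (!is.null(reversal_pair)) {
    if (length(reversal_pair) != 2L) stop("reversal_pair needs two comparisons")
    pick <- function(x) {
      if (is.numeric(x)) signed[[as.integer(x)]] else signed[[as.character(x)]]
    }
    a <- pick(reversal_pair[[1]])
    b <- pick(reversal_pair[[2]])
    if (is.null(a) || is.null(b)) stop("reversal_pair references unknown comparison")
    rev_genes <- reversal_genes(a, b)
    utils::write.table(
      data.frame(gene = rev_genes, stringsAsFactors = FALSE),
      file.path(out_dir, paste0("reversal_", a$label, "__", b$label, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "zratioDE",
    version = as.character(utils::packageVersion("zratioDE")),
    n_probes = nrow(expression$values),
    n_samples = ncol(expression$values),
    groups = as.list(stats::setNames(as.integer(design$n_per_group),
                                     design$groups)),
    thresholds = unclass(thresholds),
    log_base = log_base, floor = floor, min_set_size = min_set_size,
    comparisons = counts,
    venn_counts = if (is.null(venn)) NULL else
      list(up = as.list(venn$counts[, "up"]),
           down = as.list(venn$counts[, "down"])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
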