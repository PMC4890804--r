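#' Construct a probe-by-sample expression matrix
#'
#' The central container of the pipeline: a numeric matrix of probe
#' intensities (rows = probes, columns = samples/arrays) together with a
#' scale tag recording whether values are raw scanner intensities or
#' log-intensities. Missing values are stored as \code{NA}; any probe with a
#' missing value in a compared group is excluded from that comparison
#' downstream.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @param probe_ids character vector of unique probe identifiers
#'   (defaults to \code{rownames(values)}).
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to \code{colnames(values)}).
#' @param scale one of \code{"raw"} (non-negative intensities) or
#'   \code{"log"} (log-intensities).
#' @param log_base base of the logarithm when \code{scale = "log"}.
#'
#' @return An object of class \code{"expression_matrix"}: a list with
#'   elements \code{values}, \code{probe_ids}, \code{sample_ids},
#'   \code{scale} and (for log scale) \code{log_base}.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale = c("raw", "log"), log_base = NA_real_) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("probe_ids and sample_ids are required (or set dimnames on 'values')")
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(probe_ids) || ncol(values) != length(sample_ids)) {
    stop("dimensions of 'values' do not match the identifier lists")
  }
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe identifier(s): ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (scale == "raw") {
    finite <- values[is.finite(values)]
    if (any(finite < 0)) stop("raw intensities must be non-negative")
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(values = values, probe_ids = probe_ids,
                 sample_ids = sample_ids, scale = scale,
                 log_base = if (scale == "log") log_base else NA_real_),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a sample design (sample-to-group assignment)
#'
#' @param sample_id character vector of sample identifiers.
#' @param group character vector of group labels, parallel to
#'   \code{sample_id}. Group order is first-appearance order.
#'
#' @return An object of class \code{"sample_design"} with elements
#'   \code{sample_id}, \code{group} (character), \code{groups} (ordered
#'   unique labels) and \code{n_per_group}.
#' @export
sample_design <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group)) {
    stop("sample_id and group must have the same length")
  }
  # exact duplicate rows are idempotent; conflicting assignments are an error
  keep <- !duplicated(paste(sample_id, group, sep = "\r"))
  sample_id <- sample_id[keep]
  group <- group[keep]
  if (anyDuplicated(sample_id)) {
    bad <- unique(sample_id[duplicated(sample_id)])
    stop("sample(s) assigned to more than one group: ",
         paste(bad, collapse = ", "))
  }
  groups <- unique(group)
  n <- vapply(groups, function(g) sum(group == g), integer(1))
  structure(list(sample_id = sample_id, group = group,
                 groups = groups, n_per_group = n),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("sample_design: %d samples, %d groups (%s)\n",
              length(x$sample_id), length(x$groups),
              paste(sprintf("%s n=%d", x$groups, x$n_per_group),
                    collapse = ", ")))
  invisible(x)
}

#' Samples belonging to one design group
#' @param design a \code{sample_design}.
#' @param group a group label present in the design.
#' @return character vector of sample ids.
#' @export
design_samples <- function(design, group) {
  stopifnot(inherits(design, "sample_design"))
  if (!group %in% design$groups) {
    stop("unknown group label: ", group)
  }
  design$sample_id[design$group == group]
}

#' Read a probe-by-sample expression matrix
#'
#' Reads either a plain TSV (header row names the samples, first column the
#' probes) or a GEO series-matrix file, in which metadata lines starting with
#' \code{"!"} are skipped and the table between the
#' \code{!series_matrix_table_begin} / \code{!series_matrix_table_end}
#' markers is parsed.
#'
#' Empty cells and \code{"NA"} become missing values. Any other non-numeric
#' cell is a parse error reporting its row and column coordinates.
#'
#' @param path path to the file.
#' @param dialect \code{"tsv"} or \code{"geo_series_matrix"}.
#' @return an \code{\link{expression_matrix}} with raw scale.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "geo_series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "geo_series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
      stop("series-matrix table markers missing or malformed in ", path)
    }
    lines <- lines[(begin + 1L):(end - 1L)]
    lines <- gsub('"', "", lines, fixed = TRUE)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty expression table in ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  body <- lines[-1L]
  if (length(body) == 0L) stop("expression table has no data rows: ", path)
  # sentinel keeps trailing empty fields that strsplit would drop
  cells <- lapply(strsplit(paste0(body, "\t\x01"), "\t", fixed = TRUE),
                  function(x) x[-length(x)])
  ncol_expected <- length(header)
  bad_len <- which(lengths(cells) != ncol_expected)
  if (length(bad_len)) {
    stop(sprintf("row %d has %d fields, expected %d",
                 bad_len[1L] + 1L, lengths(cells)[bad_len[1L]], ncol_expected))
  }
  probe_ids <- vapply(cells, `[[`, character(1), 1L)
  raw <- vapply(cells, function(x) x[-1L], character(length(sample_ids)))
  raw <- if (is.matrix(raw)) t(raw) else matrix(raw, ncol = length(sample_ids))
  raw[raw == ""] <- NA_character_
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) & !is.na(raw) & raw != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value %s at data row %d, sample column %d (%s)",
                 dQuote(raw[bad[1L, 1L], bad[1L, 2L]]), bad[1L, 1L],
                 bad[1L, 2L], sample_ids[bad[1L, 2L]]))
  }
  expression_matrix(vals, probe_ids = probe_ids, sample_ids = sample_ids,
                    scale = "raw")
}

#' Write an expression matrix as TSV
#'
#' Header is \code{probe_id<TAB>sample1<TAB>...}; one probe per row; missing
#' values written as \code{NA}. Full \code{\%.17g} precision so a read/write
#' round trip preserves values exactly.
#'
#' @param m an \code{expression_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  fmt <- function(v) {
    out <- vapply(v, function(x) {
      if (is.na(x)) "NA" else sprintf("%.17g", x)
    }, character(1))
    out
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("probe_id", m$sample_ids), collapse = "\t"), con)
  body <- vapply(seq_along(m$probe_ids), function(i) {
    paste(c(m$probe_ids[i], fmt(m$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: \code{name<TAB>description<TAB>member1<TAB>member2...}.
#' Duplicate members within a set are removed; a line with fewer than three
#' fields is a format error reporting the line number.
#'
#' @param path path to a GMT file.
#' @return an object of class \code{"gene_set_collection"}: a named list of
#'   character member vectors, with a \code{"descriptions"} attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has %d field(s); need name, description, members",
                 short[1L], lengths(fields)[short[1L]]))
  }
  sets <- lapply(fields, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  gene_set_collection(sets, descriptions = desc)
}

#' Construct a gene-set collection
#' @param sets named list of character member vectors.
#' @param descriptions optional character vector, one per set.
#' @return a \code{"gene_set_collection"}.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      stop("every gene set needs a name")
    }
    if (anyDuplicated(names(sets))) {
      stop("duplicate set name(s): ",
           paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
    }
    sets <- lapply(sets, function(x) unique(as.character(x)))
    if (any(lengths(sets) == 0L)) {
      stop("empty gene set(s): ",
           paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
    }
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#' @param sets a \code{gene_set_collection}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample design table
#'
#' Two-column TSV (\code{sample_id}, \code{group}) with a header row. Group
#' order is first-appearance order. A sample listed under two different
#' groups is a format error; an exactly repeated row is ignored.
#'
#' @param path path to the TSV.
#' @return a \code{\link{sample_design}}.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  if (ncol(tab) < 2L) stop("design file needs two columns: sample_id, group")
  sample_design(tab[[1L]], tab[[2L]])
}

#' Write a sample design table as TSV
#' @param design a \code{sample_design}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "sample_design"))
  utils::write.table(
    data.frame(sample_id = design$sample_id, group = design$group),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level values to gene level
#'
#' Keeps, for each gene, the probe with the highest mean log-intensity
#' across all samples — a deterministic rule for arrays where several probes
#' interrogate one gene. Probes without a mapping are dropped.
#'
#' @param m an \code{expression_matrix} (log scale recommended; raw values
#'   are ranked on \code{log10(value + 1)}).
#' @param probe_to_gene named character vector mapping probe id to gene
#'   symbol.
#' @return an \code{expression_matrix} whose rows are gene symbols, plus a
#'   \code{"chosen_probes"} attribute naming the retained probe per gene.
#' @export
collapse_to_genes <- function(m, probe_to_gene) {
  stopifnot(inherits(m, "expression_matrix"))
  probe_to_gene <- probe_to_gene[names(probe_to_gene) %in% m$probe_ids]
  if (length(probe_to_gene) == 0L) stop("no probe maps to a gene")
  vals <- m$values[names(probe_to_gene), , drop = FALSE]
  rank_vals <- if (m$scale == "raw") log10(vals + 1) else vals
  score <- rowMeans(rank_vals, na.rm = TRUE)
  ord <- order(unname(probe_to_gene), -score, names(probe_to_gene))
  gene <- unname(probe_to_gene)[ord]
  keep <- ord[!duplicated(gene)]
  chosen <- names(probe_to_gene)[keep]
  out <- expression_matrix(m$values[chosen, , drop = FALSE],
                           probe_ids = unname(probe_to_gene)[keep],
                           sample_ids = m$sample_ids,
                           scale = m$scale, log_base = m$log_base)
  attr(out, "chosen_probes") <- stats::setNames(chosen, unname(probe_to_gene)[keep])
  out
}
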