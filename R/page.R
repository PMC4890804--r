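#' Parametric Analysis of Gene set Enrichment (PAGE)
#'
#' For each gene set with at least \code{min_size} members present in the
#' Z-ratio vector, computes the PAGE statistic
#' \deqn{Z = (S_m - \mu) \sqrt{m} / \delta}
#' where \eqn{S_m} is the mean Z-ratio of the m member genes with data and
#' \eqn{\mu}, \eqn{\delta} are the mean and standard deviation (denominator
#' n - 1) of the whole Z-ratio vector of the comparison. Under the null the
#' set mean is approximately normal by the central limit theorem, giving a
#' two-sided p-value \code{2 * (1 - pnorm(|Z|))}; q-values are BH-adjusted
#' across the reported sets.
#'
#' @param zratios named numeric vector of per-gene Z-ratios for one
#'   comparison (names are gene identifiers).
#' @param sets a \code{\link{gene_set_collection}}.
#' @param min_size minimum number of members with data for a set to be
#'   scored (default 10; the normal approximation degrades below that).
#' @return data frame with columns \code{set_name}, \code{m}, \code{s_m},
#'   \code{z_page}, \code{p_page}, \code{q_page}, \code{direction}; the
#'   number of undersized sets is in the \code{"n_undersized"} attribute.
#'   Empty (zero-row) result with a warning if no set qualifies.
#' @export
page_enrichment <- function(zratios, sets, min_size = 10) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (is.null(names(zratios)) || any(!nzchar(names(zratios)))) {
    stop("zratios must be named by gene identifier")
  }
  if (!is.numeric(min_size) || min_size < 2) stop("min_size must be >= 2")
  zratios <- zratios[!is.na(zratios)]
  mu <- mean(zratios)
  delta <- stats::sd(zratios)
  if (!is.finite(delta) || delta == 0) {
    stop("Z-ratio vector has zero variance; PAGE undefined")
  }
  members <- lapply(sets, function(g) intersect(g, names(zratios)))
  m <- lengths(members)
  keep <- m >= min_size
  empty <- data.frame(set_name = character(), m = integer(),
                      s_m = numeric(), z_page = numeric(),
                      p_page = numeric(), q_page = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning("no gene set has >= min_size members with data")
    attr(empty, "n_undersized") <- length(sets)
    return(empty)
  }
  s_m <- vapply(members[keep], function(g) mean(zratios[g]), numeric(1))
  z_page <- (s_m - mu) * sqrt(m[keep]) / delta
  p_page <- 2 * stats::pnorm(abs(z_page), lower.tail = FALSE)
  out <- data.frame(set_name = names(sets)[keep], m = unname(m[keep]),
                    s_m = unname(s_m), z_page = unname(z_page),
                    p_page = unname(p_page),
                    q_page = bh_fdr(unname(p_page)),
                    direction = ifelse(z_page > 0, "up",
                                       ifelse(z_page < 0, "down", "none")),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_undersized") <- sum(!keep)
  attr(out, "mu") <- mu
  attr(out, "delta") <- delta
  out
}

#' Sign-preserving geometric average of signed fold changes
#'
#' Summarizes a set of signed-ratio fold changes (or Z-ratio-like signed
#' values) as a single signed magnitude: the geometric mean of the absolute
#' values, \code{exp(mean(log|v|))}, carrying the sign of the arithmetic
#' mean of the signed log-magnitudes \code{sign(v) * log|v|}. When that mean
#' is exactly zero (perfectly balanced up/down regulation) the result is +1,
#' i.e. no net change. Zero-valued members are excluded with a warning.
#'
#' @param values numeric vector of signed values in the signed-ratio
#'   convention (no values in (-1, 1) other than via sign).
#' @param members optional character vector restricting \code{values}
#'   (which must then be named) to a gene set.
#' @return a single signed geometric-average change.
#' @export
geometric_average_change <- function(values, members = NULL) {
  if (!is.null(members)) {
    if (is.null(names(values))) stop("values must be named to subset by members")
    values <- values[intersect(members, names(values))]
  }
  values <- values[!is.na(values)]
  if (any(values == 0)) {
    warning(sum(values == 0), " zero-valued member(s) excluded")
    values <- values[values != 0]
  }
  if (length(values) == 0L) stop("no usable members")
  log_mag <- log(abs(values))
  signed_mean <- mean(sign(values) * log_mag)
  if (signed_mean == 0) return(1)
  magnitude <- exp(mean(log_mag))
  sign(signed_mean) * magnitude
}
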