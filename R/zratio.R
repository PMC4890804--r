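#' Log-transform raw intensities
#'
#' Applies \code{log_base(max(value, floor))} elementwise. The floor guards
#' zero intensities before the logarithm; the base cancels in downstream
#' Z-scores (standardization is affine-invariant), so it only affects
#' intermediate values.
#'
#' @param m an \code{expression_matrix} with raw scale.
#' @param base logarithm base, must exceed 1. Default 10.
#' @param floor positive lower clamp applied before the log. Default 1.
#' @return an \code{expression_matrix} with log scale.
#' @export
log_transform <- function(m, base = 10, floor = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "raw") stop("log_transform expects a raw-scale matrix")
  if (!is.numeric(base) || base <= 1) stop("log base must be > 1")
  if (!is.numeric(floor) || floor <= 0) stop("floor must be positive")
  vals <- log(pmax(m$values, floor), base = base)
  expression_matrix(vals, probe_ids = m$probe_ids, sample_ids = m$sample_ids,
                    scale = "log", log_base = base)
}

#' Per-array Z-score normalization
#'
#' Standardizes each sample (array) column of a log-intensity matrix to mean
#' 0, standard deviation 1 (denominator n - 1), computed over that sample's
#' non-missing probes. This removes array-wide scale and offset effects: any
#' per-array affine transform of the log intensities leaves the Z-scores
#' unchanged.
#'
#' @param m an \code{expression_matrix} with log scale.
#' @return an object of class \code{"zscore_matrix"}: list with
#'   \code{z} (probes x samples), \code{probe_ids}, \code{sample_ids},
#'   \code{source_log_base}.
#' @export
zscore_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "log") {
    stop("zscore_normalize expects log-scale input; call log_transform first")
  }
  x <- m$values
  n_ok <- colSums(!is.na(x))
  if (any(n_ok < 2L)) {
    stop("sample(s) with fewer than 2 non-missing probes: ",
         paste(m$sample_ids[n_ok < 2L], collapse = ", "))
  }
  mu <- colMeans(x, na.rm = TRUE)
  sd_j <- apply(x, 2L, stats::sd, na.rm = TRUE)
  if (any(sd_j == 0 | !is.finite(sd_j))) {
    stop("zero-variance sample(s): ",
         paste(m$sample_ids[sd_j == 0 | !is.finite(sd_j)], collapse = ", "))
  }
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sd_j, "/")
  structure(list(z = z, probe_ids = m$probe_ids, sample_ids = m$sample_ids,
                 source_log_base = m$log_base),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat(sprintf("zscore_matrix: %d probes x %d samples\n",
              nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' Default significance thresholds for the five-criterion filter
#'
#' A probe is called significant only if all of the following hold:
#' z-test p-value at most \code{p_z_max}, absolute Z-ratio at least
#' \code{z_ratio_min}, Benjamini-Hochberg FDR at most \code{fdr_max},
#' average Z-score over the compared samples non-negative (when
#' \code{require_nonneg_avg_z}), and one-way ANOVA p across all design
#' groups at most \code{p_anova_max}.
#'
#' @param p_z_max z-test p-value ceiling (default 0.05).
#' @param z_ratio_min minimum absolute Z-ratio (default 1.5).
#' @param fdr_max FDR ceiling (default 0.30).
#' @param require_nonneg_avg_z require mean Z-score over the compared
#'   samples to be non-negative (default TRUE).
#' @param p_anova_max ANOVA p-value ceiling (default 0.05).
#' @return a classed list of validated thresholds.
#' @export
selection_thresholds <- function(p_z_max = 0.05, z_ratio_min = 1.5,
                                 fdr_max = 0.30, require_nonneg_avg_z = TRUE,
                                 p_anova_max = 0.05) {
  stopifnot(p_z_max > 0, p_z_max <= 1, z_ratio_min >= 0,
            fdr_max > 0, fdr_max <= 1, is.logical(require_nonneg_avg_z),
            p_anova_max > 0, p_anova_max <= 1)
  structure(list(p_z_max = p_z_max, z_ratio_min = z_ratio_min,
                 fdr_max = fdr_max,
                 require_nonneg_avg_z = require_nonneg_avg_z,
                 p_anova_max = p_anova_max),
            class = "selection_thresholds")
}

# Shared guard: both groups present with >= 2 samples each.
check_comparison_groups <- function(design, group_a, group_b) {
  stopifnot(inherits(design, "sample_design"))
  for (g in c(group_a, group_b)) {
    if (!g %in% design$groups) stop("unknown group label: ", g)
    if (sum(design$group == g) < 2L) {
      stop("group ", g, " has fewer than 2 samples")
    }
  }
  if (group_a == group_b) stop("the two compared groups must differ")
}

#' Z-ratio statistic for one group-vs-group comparison
#'
#' For each probe, the difference of group-mean Z-scores (group A minus
#' group B) is divided by the standard deviation (denominator n - 1) of
#' those differences across all probes in the comparison, yielding a
#' scale-free differential-expression statistic whose distribution across
#' probes has standard deviation 1 by construction. Probes with any missing
#' Z-score in either compared group are excluded and recorded in the
#' \code{"excluded_probes"} attribute.
#'
#' @param z a \code{zscore_matrix}.
#' @param design a \code{sample_design}.
#' @param group_a,group_b group labels; the comparison is A vs B.
#' @return a data frame (one row per retained probe) with columns
#'   \code{probe_id}, \code{mean_z_a}, \code{mean_z_b}, \code{delta_z},
#'   \code{z_ratio}, \code{avg_z} (mean Z-score over all samples of both
#'   groups).
#' @export
zratio <- function(z, design, group_a, group_b) {
  stopifnot(inherits(z, "zscore_matrix"))
  check_comparison_groups(design, group_a, group_b)
  sa <- design_samples(design, group_a)
  sb <- design_samples(design, group_b)
  missing_samples <- setdiff(c(sa, sb), z$sample_ids)
  if (length(missing_samples)) {
    stop("design sample(s) absent from the matrix: ",
         paste(missing_samples, collapse = ", "))
  }
  za <- z$z[, sa, drop = FALSE]
  zb <- z$z[, sb, drop = FALSE]
  complete <- !(rowSums(is.na(za)) > 0 | rowSums(is.na(zb)) > 0)
  if (sum(complete) < 2L) stop("fewer than 2 probes with complete data")
  za <- za[complete, , drop = FALSE]
  zb <- zb[complete, , drop = FALSE]
  mean_a <- rowMeans(za)
  mean_b <- rowMeans(zb)
  delta <- mean_a - mean_b
  denom <- stats::sd(delta)
  if (denom == 0) {
    if (all(delta == 0)) {
      denom <- 1  # no probe differs: every Z-ratio is 0
    } else {
      stop("all probes share one non-zero group-mean difference; Z-ratio undefined")
    }
  }
  res <- data.frame(probe_id = z$probe_ids[complete],
                    mean_z_a = mean_a, mean_z_b = mean_b,
                    delta_z = delta, z_ratio = delta / denom,
                    avg_z = rowMeans(cbind(za, zb)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "excluded_probes") <- z$probe_ids[!complete]
  attr(res, "comparison") <- c(group_a, group_b)
  res
}

#' Signed fold change between group means of raw intensities
#'
#' The ratio r of mean raw intensity in group A over group B, reported in
#' the signed-ratio convention: +r when r >= 1 and -1/r when r < 1, so that
#' e.g. a halving is -2.0 rather than 0.5. A zero mean in the denominator
#' group yields \code{NA}.
#'
#' @param m an \code{expression_matrix} with raw scale.
#' @param design a \code{sample_design}.
#' @param group_a,group_b group labels; the ratio is A over B.
#' @return named numeric vector of signed fold changes, one per probe
#'   (\code{NA} where undefined or where a compared group has missing data).
#' @export
fold_change <- function(m, design, group_a, group_b) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "raw") stop("fold_change expects raw intensities")
  check_comparison_groups(design, group_a, group_b)
  va <- m$values[, design_samples(design, group_a), drop = FALSE]
  vb <- m$values[, design_samples(design, group_b), drop = FALSE]
  ma <- rowMeans(va)
  mb <- rowMeans(vb)
  r <- ma / mb
  r[!is.finite(r) | mb == 0] <- NA_real_
  fc <- ifelse(r >= 1, r, -1 / r)
  stats::setNames(fc, m$probe_ids)
}

#' Two-sided z-test p-values for Z-ratios
#'
#' Treats each probe's Z-ratio as a standard normal deviate (which the
#' Z-ratio construction enforces marginally across probes) and returns
#' \code{2 * (1 - pnorm(|z_ratio|))}.
#'
#' @param z_ratio numeric vector of Z-ratios (or a \code{zratio} result
#'   data frame, in which case a \code{p_z} column is added).
#' @return numeric p-values, or the data frame with \code{p_z} added.
#' @export
ztest_pvalues <- function(z_ratio) {
  if (is.data.frame(z_ratio)) {
    z_ratio$p_z <- ztest_pvalues(z_ratio$z_ratio)
    return(z_ratio)
  }
  2 * stats::pnorm(abs(z_ratio), lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: \code{q_(k) = min_{j >= k} (n p_(j) / j)},
#' capped at 1. Tied p-values receive identical q.
#'
#' @param p numeric vector of p-values, all finite in [0, 1] (\code{NA}
#'   allowed and propagated).
#' @return numeric vector of q-values, same length and order as \code{p}.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-probe one-way ANOVA across all design groups
#'
#' Fixed-effects one-way ANOVA of the Z-scores across every group in the
#' design (not only a compared pair), computed row-wise in closed form.
#' Probes missing a value use their complete observations; a probe left
#' with fewer than 2 observations in any group gets \code{NA}.
#'
#' @param z a \code{zscore_matrix}.
#' @param design a \code{sample_design} with at least 2 groups, each with
#'   at least 2 samples.
#' @return data frame with \code{probe_id}, \code{f_anova}, \code{p_anova}.
#' @export
anova_pvalues <- function(z, design) {
  stopifnot(inherits(z, "zscore_matrix"), inherits(design, "sample_design"))
  if (length(design$groups) < 2L) stop("ANOVA needs at least 2 groups")
  if (any(design$n_per_group < 2L)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(design$groups[design$n_per_group < 2L], collapse = ", "))
  }
  missing_samples <- setdiff(design$sample_id, z$sample_ids)
  if (length(missing_samples)) {
    stop("design sample(s) absent from the matrix: ",
         paste(missing_samples, collapse = ", "))
  }
  x <- z$z[, design$sample_id, drop = FALSE]
  k <- length(design$groups)
  n_g <- matrix(0, nrow(x), k)          # per-probe per-group n
  sum_g <- matrix(0, nrow(x), k)
  ssq_g <- matrix(0, nrow(x), k)
  for (j in seq_len(k)) {
    xg <- x[, design$group == design$groups[j], drop = FALSE]
    n_g[, j] <- rowSums(!is.na(xg))
    sum_g[, j] <- rowSums(xg, na.rm = TRUE)
    ssq_g[, j] <- rowSums(xg^2, na.rm = TRUE)
  }
  n_tot <- rowSums(n_g)
  grand_mean <- rowSums(sum_g) / n_tot
  mean_g <- sum_g / n_g
  ss_between <- rowSums(n_g * (mean_g - grand_mean)^2)
  ss_within <- rowSums(ssq_g - n_g * mean_g^2)
  df1 <- k - 1L
  df2 <- n_tot - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # degenerate probes: any group with < 2 usable values, or zero variance
  bad <- rowSums(n_g < 2L) > 0
  zero_within <- ss_within <= 0
  f[bad] <- NA_real_
  p[bad] <- NA_real_
  p[!bad & zero_within & ss_between > 0] <- 0
  f[!bad & zero_within] <- NA_real_
  p[!bad & zero_within & ss_between <= 0] <- NA_real_
  data.frame(probe_id = z$probe_ids, f_anova = f, p_anova = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the five-criterion significance filter
#'
#' Marks a probe significant when all criteria in
#' \code{\link{selection_thresholds}} hold simultaneously; direction is the
#' sign of the Z-ratio (up for positive). Probes with any missing criterion
#' value are never significant.
#'
#' @param result a comparison-result data frame with columns \code{p_z},
#'   \code{z_ratio}, \code{q}, \code{avg_z}, \code{p_anova} populated.
#' @param thresholds a \code{selection_thresholds} object.
#' @return \code{result} with logical \code{significant} and character
#'   \code{direction} (\code{"up"}, \code{"down"}, \code{"none"}) columns.
#' @export
select_significant <- function(result, thresholds = selection_thresholds()) {
  stopifnot(is.data.frame(result), inherits(thresholds, "selection_thresholds"))
  needed <- c("p_z", "z_ratio", "q", "avg_z", "p_anova")
  missing_cols <- setdiff(needed, names(result))
  if (length(missing_cols)) {
    stop("missing criterion column(s): ", paste(missing_cols, collapse = ", "))
  }
  ok <- (result$p_z <= thresholds$p_z_max) &
    (abs(result$z_ratio) >= thresholds$z_ratio_min) &
    (result$q <= thresholds$fdr_max) &
    (result$p_anova <= thresholds$p_anova_max)
  if (thresholds$require_nonneg_avg_z) ok <- ok & (result$avg_z >= 0)
  ok[is.na(ok)] <- FALSE
  result$significant <- ok
  result$direction <- ifelse(!ok, "none",
                             ifelse(result$z_ratio > 0, "up", "down"))
  result
}

#' Full differential-expression comparison of two groups
#'
#' Convenience chain producing a complete per-probe comparison result from
#' raw intensities: log transform, per-array Z-score normalization, Z-ratio,
#' signed fold change on the raw scale, two-sided z-test p, BH FDR, one-way
#' ANOVA across all design groups, and the five-criterion filter.
#'
#' @param m an \code{expression_matrix} with raw scale.
#' @param design a \code{sample_design}.
#' @param group_a,group_b compared group labels (A vs B; B is typically the
#'   control, e.g. sham).
#' @param thresholds a \code{selection_thresholds} object.
#' @param log_base,floor passed to \code{\link{log_transform}}.
#' @return a data frame with one row per probe retained in the comparison:
#'   \code{probe_id}, \code{fold_change}, \code{mean_z_a}, \code{mean_z_b},
#'   \code{delta_z}, \code{z_ratio}, \code{avg_z}, \code{p_z}, \code{q},
#'   \code{f_anova}, \code{p_anova}, \code{significant}, \code{direction};
#'   comparison labels and excluded probes in attributes.
#' @export
compare_groups <- function(m, design, group_a, group_b,
                           thresholds = selection_thresholds(),
                           log_base = 10, floor = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  logm <- log_transform(m, base = log_base, floor = floor)
  z <- zscore_normalize(logm)
  res <- zratio(z, design, group_a, group_b)
  res <- ztest_pvalues(res)
  res$q <- bh_fdr(res$p_z)
  fc <- fold_change(m, design, group_a, group_b)
  res$fold_change <- unname(fc[res$probe_id])
  an <- anova_pvalues(z, design)
  idx <- match(res$probe_id, an$probe_id)
  res$f_anova <- an$f_anova[idx]
  res$p_anova <- an$p_anova[idx]
  res <- select_significant(res, thresholds)
  cols <- c("probe_id", "fold_change", "mean_z_a", "mean_z_b", "delta_z",
            "z_ratio", "avg_z", "p_z", "q", "f_anova", "p_anova",
            "significant", "direction")
  out <- res[, cols]
  attr(out, "comparison") <- c(group_a, group_b)
  attr(out, "excluded_probes") <- attr(res, "excluded_probes")
  out
}
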