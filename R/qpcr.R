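#' Pfaffl efficiency-corrected relative expression ratio
#'
#' \deqn{R = E_{target}^{\Delta Ct_{target}} / E_{ref}^{\Delta Ct_{ref}}}
#' with \eqn{\Delta Ct} = mean control Ct minus mean treated Ct for each
#' gene, and E the amplification efficiency in fold per cycle (E = 2 is
#' perfect doubling). With E = 2 for both genes this reduces exactly to the
#' classic \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param e_target,e_ref amplification efficiencies, each in (1, 2].
#' @param dct_target,dct_ref Ct differences in cycles (control - treated).
#' @return the relative expression ratio (treated vs control), > 0.
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  if (any(e_target <= 1 | e_target > 2) || any(e_ref <= 1 | e_ref > 2)) {
    stop("amplification efficiencies must lie in (1, 2]")
  }
  e_target^dct_target / e_ref^dct_ref
}

#' Amplification efficiency from a dilution-curve slope
#'
#' Standard-curve estimate: Ct regressed on log10 template input has slope
#' s < 0, and E = 10^(-1/s). The perfect-doubling slope -1/log10(2) =
#' -3.3219 gives E = 2.
#'
#' @param slope slope of Ct vs log10(input), must be negative.
#' @param base log base of the dilution axis (default 10).
#' @return amplification efficiency (fold per cycle).
#' @export
efficiency_from_dilution <- function(slope, base = 10) {
  if (any(slope >= 0)) stop("dilution-curve slope must be negative")
  base^(-1 / slope)
}

#' Convert a positive expression ratio to the signed-ratio convention
#' @param r positive ratio.
#' @return +r when r >= 1, -1/r when r < 1.
#' @export
signed_fold <- function(r) {
  ifelse(r >= 1, r, -1 / r)
}

#' Read a long-format qPCR Ct table
#'
#' TSV with a header and columns \code{gene}, \code{sample}, \code{group},
#' \code{ct} (case-insensitive). Extra columns are kept.
#'
#' @param path path to the TSV.
#' @return data frame of qPCR records.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  needed <- c("gene", "sample", "group", "ct")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("qPCR table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab$ct <- as.numeric(tab$ct)
  tab
}

#' Pfaffl-method group fold change from a qPCR Ct table
#'
#' Computes the treated-vs-control relative expression of a target gene
#' normalized to a reference gene. Group-mean Cts give the point-estimate
#' ratio via \code{\link{pfaffl_ratio}}; per-sample ratios (each sample's
#' Ct against the control-group mean Ct) give the SEM and the per-sample
#' log-ratios feed an unpaired two-sided t-test between groups. Samples
#' missing the reference-gene Ct are excluded with a warning.
#'
#' @param records qPCR data frame as from \code{\link{read_qpcr}}.
#' @param target_gene,reference_gene gene identifiers in \code{records}.
#' @param control_group,treated_group group labels in \code{records}.
#' @param e_target,e_ref amplification efficiencies in (1, 2]; default 2
#'   (perfect doubling) when no standard curve is available.
#' @return an object of class \code{"pfaffl_result"}: list with
#'   \code{gene}, \code{e_target}, \code{e_ref}, \code{dct_target},
#'   \code{dct_ref}, \code{ratio}, \code{fold_change_signed}, \code{sem}
#'   (SEM of treated per-sample ratios), \code{p_ttest}, \code{n_control},
#'   \code{n_treated}.
#' @export
group_fold_change <- function(records, target_gene, reference_gene,
                              control_group, treated_group,
                              e_target = 2, e_ref = 2) {
  stopifnot(is.data.frame(records))
  if (any(e_target <= 1 | e_target > 2) || any(e_ref <= 1 | e_ref > 2)) {
    stop("amplification efficiencies must lie in (1, 2]")
  }
  get_ct <- function(gene, group) {
    sub <- records[records$gene == gene & records$group == group, ]
    stats::setNames(sub$ct, sub$sample)
  }
  ct <- list(
    target_control = get_ct(target_gene, control_group),
    target_treated = get_ct(target_gene, treated_group),
    ref_control = get_ct(reference_gene, control_group),
    ref_treated = get_ct(reference_gene, treated_group))
  # keep only samples with both target and reference Cts
  pair_samples <- function(tgt, ref, what) {
    common <- intersect(names(tgt)[!is.na(tgt)], names(ref)[!is.na(ref)])
    dropped <- setdiff(union(names(tgt), names(ref)), common)
    if (length(dropped)) {
      warning(length(dropped), " ", what,
              " sample(s) excluded for missing Ct: ",
              paste(dropped, collapse = ", "))
    }
    list(target = tgt[common], ref = ref[common])
  }
  ctl <- pair_samples(ct$target_control, ct$ref_control, "control")
  trt <- pair_samples(ct$target_treated, ct$ref_treated, "treated")
  if (length(ctl$target) < 2L || length(trt$target) < 2L) {
    stop("need >= 2 usable samples per group for both genes")
  }
  dct_target <- mean(ctl$target) - mean(trt$target)
  dct_ref <- mean(ctl$ref) - mean(trt$ref)
  ratio <- pfaffl_ratio(e_target, dct_target, e_ref, dct_ref)
  # per-sample ratios against the control-group mean Cts
  per_sample <- function(grp) {
    pfaffl_ratio(e_target, mean(ctl$target) - grp$target,
                 e_ref, mean(ctl$ref) - grp$ref)
  }
  r_treated <- per_sample(trt)
  r_control <- per_sample(ctl)
  sem <- stats::sd(r_treated) / sqrt(length(r_treated))
  p <- tryCatch(
    stats::t.test(log(r_treated), log(r_control),
                  var.equal = TRUE)$p.value,
    error = function(e) NA_real_)
  structure(list(gene = target_gene, e_target = e_target, e_ref = e_ref,
                 dct_target = dct_target, dct_ref = dct_ref,
                 ratio = ratio, fold_change_signed = signed_fold(ratio),
                 sem = sem, p_ttest = p,
                 n_control = length(ctl$target),
                 n_treated = length(trt$target)),
            class = "pfaffl_result")
}

#' @export
print.pfaffl_result <- function(x, ...) {
  cat(sprintf("pfaffl_result %s: ratio %.3f (signed fold %+.2f), SEM %.3f, t-test p %.4g\n",
              x$gene, x$ratio, x$fold_change_signed, x$sem, x$p_ttest))
  invisible(x)
}

#' Compare qPCR and array fold changes for one or more genes
#'
#' @param qpcr_fold,array_fold signed fold changes (vectors, aligned).
#' @param gene optional gene labels.
#' @return data frame with both signed folds, their ratio of linear ratios,
#'   and the absolute log2 difference.
#' @export
compare_platforms <- function(qpcr_fold, array_fold, gene = NULL) {
  if (length(qpcr_fold) != length(array_fold)) {
    stop("fold-change vectors must be aligned")
  }
  to_ratio <- function(f) ifelse(f >= 0, f, -1 / f)
  rq <- to_ratio(qpcr_fold)
  ra <- to_ratio(array_fold)
  data.frame(gene = if (is.null(gene)) seq_along(rq) else gene,
             qpcr_fold = qpcr_fold, array_fold = array_fold,
             ratio = rq / ra, abs_log2_diff = abs(log2(rq) - log2(ra)),
             row.names = NULL, stringsAsFactors = FALSE)
}
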