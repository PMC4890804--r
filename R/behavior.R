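#' Discrimination preference index
#'
#' \code{(t_novel - t_familiar) / (t_novel + t_familiar)}: the normalized
#' preference for the novel object (NOR) or novel arm (Y-maze), in [-1, 1];
#' 0 means no discrimination. Trials with zero total exploration time are
#' undefined and return \code{NA} with a warning.
#'
#' @param t_novel,t_familiar non-negative exploration times (seconds),
#'   vectorized.
#' @return numeric preference indices in [-1, 1].
#' @export
preference_index <- function(t_novel, t_familiar) {
  if (any(t_novel < 0, na.rm = TRUE) || any(t_familiar < 0, na.rm = TRUE)) {
    stop("exploration times must be non-negative")
  }
  total <- t_novel + t_familiar
  zero <- !is.na(total) & total == 0
  if (any(zero)) {
    warning(sum(zero), " trial(s) with zero total exploration time flagged as NA")
  }
  out <- (t_novel - t_familiar) / total
  out[zero] <- NA_real_
  out
}

#' Read a behavioral trial table
#'
#' TSV with header and columns \code{animal}, \code{group},
#' \code{paradigm}, \code{t_novel}, \code{t_familiar}.
#'
#' @param path path to the TSV.
#' @return data frame of trials.
#' @export
read_behavior <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  needed <- c("animal", "group", "t_novel", "t_familiar")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("behavior table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$t_novel <- as.numeric(tab$t_novel)
  tab$t_familiar <- as.numeric(tab$t_familiar)
  tab
}

#' One-way ANOVA with Fisher LSD post hoc tests
#'
#' Omnibus one-way fixed-effects ANOVA across the groups, followed (by
#' default only when the omnibus p is at most \code{alpha} — Fisher's
#' protected procedure) by least-significant-difference pairwise tests:
#' t statistics using the pooled mean squared error with N - k degrees of
#' freedom, unadjusted two-sided p-values.
#'
#' @param values numeric outcome per animal (e.g. preference indices);
#'   \code{NA} values are dropped with their group labels.
#' @param groups group label per value; >= 2 groups with >= 2 usable
#'   values each.
#' @param protected run the post hoc only after a significant omnibus
#'   (default TRUE).
#' @param alpha omnibus significance level gating the protected post hoc
#'   (default 0.05).
#' @return list with \code{f}, \code{df1}, \code{df2}, \code{p},
#'   \code{mse}, \code{group_stats} (n, mean, sem per group) and
#'   \code{lsd} (symmetric matrix of pairwise p-values, or \code{NULL}
#'   when the protected gate is closed). Zero within-group variance makes
#'   the F undefined; the result is flagged via \code{degenerate = TRUE}.
#' @export
group_anova_lsd <- function(values, groups, protected = TRUE, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups)[ok]
  labs <- unique(groups)
  k <- length(labs)
  if (k < 2L) stop("need at least 2 groups")
  n_g <- vapply(labs, function(g) sum(groups == g), integer(1))
  if (any(n_g < 2L)) {
    stop("group(s) with fewer than 2 values: ",
         paste(labs[n_g < 2L], collapse = ", "))
  }
  n_tot <- length(values)
  mean_g <- vapply(labs, function(g) mean(values[groups == g]), numeric(1))
  sem_g <- vapply(labs, function(g) {
    stats::sd(values[groups == g]) / sqrt(sum(groups == g))
  }, numeric(1))
  group_stats <- data.frame(group = labs, n = n_g, mean = mean_g,
                            sem = sem_g, row.names = NULL,
                            stringsAsFactors = FALSE)
  fit <- stats::aov(values ~ factor(groups, levels = labs))
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  ss_within <- sum((values - stats::ave(values, groups))^2)
  if (!is.finite(mse) || ss_within == 0) {
    return(list(f = NA_real_, df1 = k - 1L, df2 = n_tot - k, p = NA_real_,
                mse = mse, group_stats = group_stats, lsd = NULL,
                degenerate = TRUE))
  }
  f <- tab[1, "F value"]
  p <- tab[1, "Pr(>F)"]
  lsd <- NULL
  if (!protected || p <= alpha) {
    lsd <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
    df2 <- n_tot - k
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        tstat <- (mean_g[i] - mean_g[j]) /
          sqrt(mse * (1 / n_g[i] + 1 / n_g[j]))
        pv <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
        lsd[i, j] <- pv
        lsd[j, i] <- pv
      }
    }
  }
  list(f = unname(f), df1 = k - 1L, df2 = n_tot - k, p = unname(p),
       mse = unname(mse), group_stats = group_stats, lsd = lsd,
       degenerate = FALSE)
}
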