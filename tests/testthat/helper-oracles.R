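# Independent brute-force oracles and tiny fixture builders. These
# deliberately restate the definitions from scratch (loops, no reuse of
# package internals) so they can catch implementation errors.

# tiny raw matrix with known values
tiny_matrix <- function(n_probes = 10, n_samples = 8, seed = 42,
                        missing = 0) {
  set.seed(seed)
  vals <- matrix(10^rnorm(n_probes * n_samples, 2.5, 0.4),
                 n_probes, n_samples)
  if (missing > 0) vals[sample(length(vals), missing)] <- NA
  expression_matrix(vals,
                    probe_ids = paste0("p", seq_len(n_probes)),
                    sample_ids = paste0("s", seq_len(n_samples)),
                    scale = "raw")
}

tiny_design <- function(groups = c(A = 4, B = 4), n_samples = sum(groups)) {
  stopifnot(sum(groups) == n_samples)
  sample_design(paste0("s", seq_len(n_samples)),
                rep(names(groups), groups))
}

# from-scratch recomputation of every ComparisonResult field
oracle_comparison <- function(m, design, group_a, group_b,
                              log_base = 10, floor = 1) {
  raw <- m$values
  logx <- log(pmax(raw, floor), base = log_base)
  z <- logx
  for (j in seq_len(ncol(logx))) {
    col <- logx[, j]
    z[, j] <- (col - mean(col, na.rm = TRUE)) / sd(col, na.rm = TRUE)
  }
  sa <- design$sample_id[design$group == group_a]
  sb <- design$sample_id[design$group == group_b]
  ia <- match(sa, m$sample_ids)
  ib <- match(sb, m$sample_ids)
  keep <- apply(z[, c(ia, ib), drop = FALSE], 1L,
                function(r) !anyNA(r))
  delta <- numeric(0); mean_a <- numeric(0); mean_b <- numeric(0)
  avg <- numeric(0); fc <- numeric(0); ids <- character(0)
  for (i in which(keep)) {
    ma <- mean(z[i, ia]); mb <- mean(z[i, ib])
    mean_a <- c(mean_a, ma); mean_b <- c(mean_b, mb)
    delta <- c(delta, ma - mb)
    avg <- c(avg, mean(z[i, c(ia, ib)]))
    r <- mean(raw[i, ia]) / mean(raw[i, ib])
    fc <- c(fc, if (r >= 1) r else -1 / r)
    ids <- c(ids, m$probe_ids[i])
  }
  zr <- delta / sd(delta)
  p_z <- 2 * pnorm(-abs(zr))
  # BH step-up by hand
  q <- oracle_bh(p_z)
  # per-probe ANOVA via stats::oneway.test on z-scores, all groups
  p_anova <- vapply(which(keep), function(i) {
    df <- data.frame(v = z[i, match(design$sample_id, m$sample_ids)],
                     g = design$group)
    df <- df[!is.na(df$v), ]
    oneway.test(v ~ g, data = df, var.equal = TRUE)$p.value
  }, numeric(1))
  data.frame(probe_id = ids, mean_z_a = mean_a, mean_z_b = mean_b,
             delta_z = delta, z_ratio = zr, avg_z = avg, fold_change = fc,
             p_z = p_z, q = q, p_anova = p_anova,
             stringsAsFactors = FALSE)
}

# literal Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- n * p[o] / seq_len(n)
  for (k in rev(seq_len(n - 1))) {
    q_sorted[k] <- min(q_sorted[k], q_sorted[k + 1])
  }
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# PAGE from the formula, one set at a time
oracle_page <- function(zratios, sets, min_size) {
  mu <- mean(zratios)
  delta <- sd(zratios)
  out <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], names(zratios))
    m <- length(members)
    if (m < min_size) next
    s_m <- mean(zratios[members])
    z <- (s_m - mu) * sqrt(m) / delta
    out[[nm]] <- c(m = m, s_m = s_m, z_page = z,
                   p_page = 2 * (1 - pnorm(abs(z))))
  }
  out
}

# per-gene membership scan for the 3-set Venn, one direction
oracle_venn <- function(a, b, c_) {
  genes <- unique(c(a, b, c_))
  out <- list()
  for (g in genes) {
    key <- paste0(as.integer(g %in% a), as.integer(g %in% b),
                  as.integer(g %in% c_))
    out[[key]] <- c(out[[key]], g)
  }
  lapply(out, sort)
}
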