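test_that("log_transform floors, transforms, and inverts cleanly", {
  m <- expression_matrix(matrix(c(100, 0, 1000, 2), 2, 2),
                         c("p1", "p2"), c("s1", "s2"), "raw")
  lt <- log_transform(m, base = 10, floor = 1)
  expect_equal(lt$values["p1", "s1"], 2)    # log10(100)
  expect_equal(lt$values["p2", "s1"], 0)    # floor engages at 0
  expect_identical(lt$scale, "log")
  expect_error(log_transform(m, base = 1), "base")
  expect_error(log_transform(lt), "raw")

  # inverse-function oracle on a random matrix
  r <- tiny_matrix(n_probes = 30, n_samples = 4, seed = 7)
  back <- 10^log_transform(r, 10, 1)$values
  expect_equal(back, pmax(r$values, 1), tolerance = 1e-12)
})

test_that("per-array Z-scoring standardizes, ignores location, is idempotent", {
  m <- expression_matrix(matrix(c(1, 2, 3), 3, 1),
                         c("a", "b", "c"), "s1", "log", log_base = 10)
  z <- zscore_normalize(m)
  expect_equal(unname(z$z[, 1]), c(-1, 0, 1))

  r <- log_transform(tiny_matrix(n_probes = 100, n_samples = 4, seed = 3))
  z1 <- zscore_normalize(r)
  expect_equal(unname(colMeans(z1$z)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(z1$z, 2, sd)), rep(1, 4), tolerance = 1e-9)

  # adding a constant to one sample column leaves its z column unchanged
  shifted <- r
  shifted$values[, 2] <- shifted$values[, 2] + 5
  expect_equal(zscore_normalize(shifted)$z, z1$z, tolerance = 1e-9)

  # idempotence: standardizing an already-standard matrix changes nothing
  zz <- zscore_normalize(
    expression_matrix(z1$z, r$probe_ids, r$sample_ids, "log", 10))
  expect_equal(zz$z, z1$z, tolerance = 1e-9)

  const <- expression_matrix(matrix(2, 3, 2), c("a", "b", "c"),
                             c("s1", "s2"), "log", 10)
  expect_error(zscore_normalize(const), "zero-variance.*s1")
})

test_that("Z-ratio has unit spread, is antisymmetric, and matches its definition", {
  m <- tiny_matrix(n_probes = 10, n_samples = 8, seed = 11)
  d <- tiny_design(c(A = 4, B = 4))
  z <- zscore_normalize(log_transform(m))
  ab <- zratio(z, d, "A", "B")
  ba <- zratio(z, d, "B", "A")
  expect_equal(sd(ab$z_ratio), 1, tolerance = 1e-12)
  expect_equal(ab$z_ratio, -ba$z_ratio)
  expect_equal(ab$delta_z, ab$mean_z_a - ab$mean_z_b)

  # brute-force recomputation from the definition
  manual_delta <- sapply(seq_len(10), function(i) {
    mean(z$z[i, 1:4]) - mean(z$z[i, 5:8])
  })
  expect_equal(ab$z_ratio, manual_delta / sd(manual_delta), tolerance = 1e-12)

  # identical group means for every probe -> all Z-ratios are zero
  vals <- cbind(z$z[, 1:4], z$z[, 1:4])
  zz <- structure(list(z = `colnames<-`(vals, paste0("s", 1:8)),
                       probe_ids = z$probe_ids,
                       sample_ids = paste0("s", 1:8), source_log_base = 10),
                  class = "zscore_matrix")
  expect_equal(zratio(zz, d, "A", "B")$z_ratio, rep(0, 10))

  expect_error(zratio(z, d, "A", "C"), "unknown group")
})

test_that("signed fold change follows the +r / -1/r convention", {
  vals <- rbind(c(200, 200, 100, 100),
                c(100, 100, 200, 200),
                c(150, 150, 150, 150),
                c(10, 10, 0, 0))
  m <- expression_matrix(vals, paste0("p", 1:4), paste0("s", 1:4), "raw")
  d <- tiny_design(c(A = 2, B = 2), 4)
  fc <- fold_change(m, d, "A", "B")
  expect_equal(unname(fc[1:3]), c(2, -2, 1))
  expect_true(is.na(fc[["p4"]]))             # zero denominator mean
  expect_true(all(abs(fc) >= 1, na.rm = TRUE))
})

test_that("z-test p-values are two-sided normal tails, monotone in |Z|", {
  expect_equal(ztest_pvalues(0), 1)
  expect_equal(ztest_pvalues(1.959964), 0.05, tolerance = 1e-6)
  zs <- seq(0, 5, by = 0.25)
  expect_true(all(diff(ztest_pvalues(zs)) < 0))
  expect_equal(ztest_pvalues(-2), ztest_pvalues(2))
})

test_that("BH adjustment matches the literal step-up and its properties", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:5) {
    p <- runif(50)^2
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # ties get identical q
    p2 <- c(p, p[1])
    q2 <- bh_fdr(p2)
    expect_equal(q2[51], q2[1])
  }
})

test_that("row-wise ANOVA agrees with stats::oneway.test and detects separation", {
  m <- tiny_matrix(n_probes = 12, n_samples = 20, seed = 21, missing = 3)
  d <- tiny_design(c(sham = 5, PHEN = 5, mTBI = 5, mTBI_PHEN = 5), 20)
  z <- zscore_normalize(log_transform(m))
  got <- anova_pvalues(z, d)
  for (i in seq_len(12)) {
    df <- data.frame(v = z$z[i, d$sample_id], g = d$group)
    df <- df[!is.na(df$v), ]
    ref <- oneway.test(v ~ g, data = df, var.equal = TRUE)
    expect_equal(got$p_anova[i], ref$p.value, tolerance = 1e-9)
    expect_equal(got$f_anova[i], unname(ref$statistic), tolerance = 1e-9)
  }

  # hand-entered textbook one-way ANOVA, 3 groups x 3
  vals <- c(1, 2, 3, 7, 8, 9, 4, 5, 6)
  zc <- structure(list(z = matrix(vals, 1, 9,
                                  dimnames = list("p1", paste0("s", 1:9))),
                       probe_ids = "p1", sample_ids = paste0("s", 1:9),
                       source_log_base = 10),
                  class = "zscore_matrix")
  dd <- sample_design(paste0("s", 1:9), rep(c("g1", "g2", "g3"), each = 3))
  got1 <- anova_pvalues(zc, dd)
  # SSB = 3*((2-5)^2 + (8-5)^2 + (5-5)^2) = 54; SSW = 6; F = 27/1 = 27
  expect_equal(got1$f_anova, 27)
  expect_equal(got1$p_anova, pf(27, 2, 6, lower.tail = FALSE))

  # one probe shifted far out in one group -> tiny p
  m2 <- tiny_matrix(n_probes = 50, n_samples = 20, seed = 8)
  lm2 <- log_transform(m2)
  lm2$values[1, 11:15] <- lm2$values[1, 11:15] + 4
  d50 <- tiny_design(c(sham = 5, PHEN = 5, mTBI = 5, mTBI_PHEN = 5), 20)
  got2 <- anova_pvalues(zscore_normalize(lm2), d50)
  expect_lt(got2$p_anova[1], 1e-6)

  expect_error(anova_pvalues(z, sample_design(c("s1", "s2", "s3"),
                                              c("A", "A", "B"))),
               "fewer than 2")
})

test_that("null ANOVA p-values are uniform (KS) across simulated probes", {
  set.seed(99)
  n <- 400
  z <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(paste0("p", 1:n), paste0("s", 1:20)))
  zs <- structure(list(z = z, probe_ids = rownames(z),
                       sample_ids = colnames(z), source_log_base = 10),
                  class = "zscore_matrix")
  d <- tiny_design(c(A = 5, B = 5, C = 5, D = 5), 20)
  p <- anova_pvalues(zs, d)$p_anova
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("the five-criterion filter is a strict conjunction with direction", {
  base <- data.frame(probe_id = paste0("p", 1:6),
                     z_ratio = c(2, 2, 2, -2, 1.0, 2),
                     p_z = c(0.01, 0.2, 0.01, 0.01, 0.01, 0.01),
                     q = c(0.1, 0.1, 0.5, 0.1, 0.1, 0.1),
                     avg_z = c(0.5, 0.5, 0.5, 0.5, 0.5, -0.1),
                     p_anova = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01))
  got <- select_significant(base)
  # p1 passes all five; p2 fails p_z; p3 fails FDR only; p4 passes (down);
  # p5 fails |Z| >= 1.5; p6 fails the avg-Z expression filter
  expect_identical(got$significant, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(got$direction,
                   c("up", "none", "none", "down", "none", "none"))

  # switchable expression filter
  relaxed <- select_significant(base,
                                selection_thresholds(require_nonneg_avg_z = FALSE))
  expect_true(relaxed$significant[6])

  expect_error(select_significant(base[, -3]), "p_z")
})

test_that("compare_groups matches the brute-force oracle on small fixtures", {
  for (seed in c(1, 2)) {
    m <- tiny_matrix(n_probes = 20, n_samples = 8, seed = seed,
                     missing = if (seed == 2) 4 else 0)
    d <- tiny_design(c(A = 4, B = 4))
    got <- compare_groups(m, d, "A", "B")
    ref <- oracle_comparison(m, d, "A", "B")
    expect_identical(got$probe_id, ref$probe_id)
    for (col in c("mean_z_a", "mean_z_b", "delta_z", "z_ratio", "avg_z",
                  "fold_change", "p_z", "q", "p_anova")) {
      expect_equal(got[[col]], ref[[col]], tolerance = 1e-9,
                   label = paste("field", col, "seed", seed))
    }
  }
})

test_that("probes with missing values in a compared group are excluded, not guessed", {
  m <- tiny_matrix(n_probes = 15, n_samples = 8, seed = 13)
  m$values[3, 2] <- NA   # group A sample
  m$values[7, 6] <- NA   # group B sample
  d <- tiny_design(c(A = 4, B = 4))
  res <- compare_groups(m, d, "A", "B")
  expect_identical(sort(attr(res, "excluded_probes")), c("p3", "p7"))
  expect_false(any(c("p3", "p7") %in% res$probe_id))
  expect_equal(nrow(res), 13)
})
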