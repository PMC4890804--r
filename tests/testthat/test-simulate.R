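test_that("the expression simulator is seed-deterministic", {
  cfg <- simulation_config(n_probes = 200, seed = 12)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  c_ <- simulate_expression(simulation_config(n_probes = 200, seed = 13))
  expect_false(identical(a$matrix$values, c_$matrix$values))
  # written fixtures are byte-identical across reruns
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_expression_matrix(a$matrix, p1)
  write_expression_matrix(b$matrix, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the simulated design and defaults mirror the 4 x 5 study layout", {
  cfg <- simulation_config(n_probes = 50)
  sim <- simulate_expression(cfg)
  expect_identical(sim$design$groups, c("sham", "PHEN", "mTBI", "mTBI_PHEN"))
  expect_identical(unname(sim$design$n_per_group), rep(5L, 4))
  expect_equal(dim(sim$matrix), c(50L, 20L))
  expect_identical(sim$matrix$scale, "raw")
  expect_true(all(sim$matrix$values > 0))
  expect_equal(simulation_config()$n_probes, 25000)
})

test_that("planted effects land in the right group at the right magnitude", {
  eff <- data.frame(probe_id = c("probe_00001", "probe_00002"),
                    group = c("mTBI", "PHEN"),
                    fold = c(4, 0.25), baseline = 3)
  cfg <- simulation_config(n_probes = 500, noise_sd = 0.02,
                           array_offset_sd = 0, array_scale_sd = 0,
                           effects = eff, seed = 6)
  sim <- simulate_expression(cfg)
  fc_mtbi <- fold_change(sim$matrix, sim$design, "mTBI", "sham")
  expect_equal(unname(fc_mtbi["probe_00001"]), 4, tolerance = 0.3)
  expect_lt(abs(unname(fc_mtbi["probe_00002"])), 1.3) # planted elsewhere
  fc_phen <- fold_change(sim$matrix, sim$design, "PHEN", "sham")
  expect_equal(unname(fc_phen["probe_00002"]), -4, tolerance = 0.3)

  tr <- truth_for_comparison(sim$truth, "mTBI", "sham")
  expect_identical(tr$probe_id, "probe_00001")
  expect_identical(tr$direction, "up")
  tr2 <- truth_for_comparison(sim$truth, "mTBI", "PHEN")
  expect_setequal(tr2$direction, c("up", "up"))   # 4/1 and 1/0.25

  expect_error(simulate_expression(
    simulation_config(n_probes = 10,
                      effects = data.frame(probe_id = "probe_99999",
                                           group = "mTBI", fold = 2))),
    "outside")
})

test_that("null simulations yield no discoveries through the filter on average", {
  n_disc <- vapply(1:6, function(s) {
    sim <- simulate_expression(simulation_config(n_probes = 2000,
                                                 seed = 50 + s))
    sum(compare_groups(sim$matrix, sim$design, "mTBI", "sham")$significant)
  }, numeric(1))
  # near-zero: a tiny fraction of probes, most seeds exactly zero
  expect_lte(mean(n_disc), 1)
  expect_gte(mean(n_disc == 0), 0.5)
})

test_that("simulated gene sets carry their planted enrichment truth", {
  universe <- sprintf("probe_%05d", 1:500)
  gs <- simulate_gene_sets(universe, planted_up = universe[1:40],
                           planted_down = universe[41:80],
                           n_null_sets = 5, set_size = 20, seed = 3)
  expect_length(gs$sets, 9L)   # 2 per direction + 5 null
  expect_identical(sort(unique(gs$truth$direction)),
                   c("down", "none", "up"))
  up_set <- gs$sets[["enriched_up_01"]]
  expect_gte(length(intersect(up_set, universe[1:40])), 16) # >= 80%
  expect_length(up_set, 20L)
  gs2 <- simulate_gene_sets(universe, planted_up = universe[1:40],
                            planted_down = universe[41:80],
                            n_null_sets = 5, set_size = 20, seed = 3)
  expect_identical(unclass(gs$sets), unclass(gs2$sets))
  expect_error(simulate_gene_sets(universe[1:5], set_size = 20), "universe")
})

test_that("planted set enrichment is detected and null sets stay quiet", {
  eff <- data.frame(probe_id = sprintf("probe_%05d", 1:60),
                    group = "mTBI", fold = 2, baseline = 3)
  sim <- simulate_expression(simulation_config(n_probes = 2000,
                                               noise_sd = 0.05,
                                               effects = eff, seed = 8))
  res <- compare_groups(sim$matrix, sim$design, "mTBI", "sham")
  zr <- setNames(res$z_ratio, res$probe_id)
  gs <- simulate_gene_sets(res$probe_id, planted_up = eff$probe_id,
                           n_null_sets = 10, set_size = 20, seed = 8)
  enr <- page_enrichment(zr, gs$sets, min_size = 10)
  planted <- enr$z_page[grepl("^enriched_up", enr$set_name)]
  nulls <- enr$z_page[grepl("^null", enr$set_name)]
  expect_true(all(planted > 3))
  expect_true(all(abs(nulls) < 3.5))
})

test_that("behavior simulation back-converts indices exactly", {
  tab <- simulate_behavior(c(a = 0, b = 0.5), sd = 0.1, n_per_group = 30,
                           total_time = 40, seed = 21)
  idx <- preference_index(tab$t_novel, tab$t_familiar)
  expect_equal(idx, tab$true_index, tolerance = 1e-12)
  expect_equal(tab$t_novel + tab$t_familiar, rep(40, 60))
  a_rows <- tab$group == "a"
  # index mean 0 -> mean novel time ~ mean familiar time
  expect_equal(mean(tab$t_novel[a_rows]), mean(tab$t_familiar[a_rows]),
               tolerance = 1.5)
})
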