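#' Configuration for the synthetic expression study
#'
#' Describes a 4-group (sham, PHEN, mTBI, mTBI_PHEN), n = 5 per group
#' microarray-style experiment: approximately log-normal raw intensities
#' with per-array affine effects on the log10 scale, within-group
#' biological noise, and an optional table of planted differential effects.
#'
#' @param n_probes number of probes (default 25000).
#' @param groups named integer vector of group sizes in design order
#'   (default \code{c(sham = 5, PHEN = 5, mTBI = 5, mTBI_PHEN = 5)}).
#' @param baseline_mean,baseline_sd mean and sd of per-probe baseline
#'   log10 intensity (defaults 2.5 and 0.5 — intensities centred near
#'   a few hundred scanner units).
#' @param array_offset_sd sd of the per-array additive offset on the log10
#'   scale (default 0.1); removed exactly by per-array Z-scoring.
#' @param array_scale_sd sd of the per-array multiplicative gain applied to
#'   log10 values around 1 (default 0.05); also removed by Z-scoring.
#' @param noise_sd within-group biological/technical noise sd on the log10
#'   scale (default 0.1).
#' @param effects optional data frame with columns \code{probe_id},
#'   \code{group}, \code{fold} (> 0): raw-scale fold change of that probe
#'   in that group relative to its baseline. Probes/groups absent from the
#'   table have fold 1. An optional \code{baseline} column pins the probe's
#'   baseline log10 intensity (planted effects usually emulate expressed
#'   transcripts — the non-negative average-Z criterion is an expression
#'   filter, so effects planted on low-abundance probes are discarded by
#'   design, not missed).
#' @param seed integer seed; a fixed seed makes outputs byte-identical.
#' @return a classed list of validated settings.
#' @export
simulation_config <- function(n_probes = 25000,
                              groups = c(sham = 5, PHEN = 5, mTBI = 5,
                                         mTBI_PHEN = 5),
                              baseline_mean = 2.5, baseline_sd = 0.5,
                              array_offset_sd = 0.1, array_scale_sd = 0.05,
                              noise_sd = 0.1, effects = NULL, seed = 1) {
  stopifnot(n_probes >= 2, length(groups) >= 2, all(groups >= 2),
            !is.null(names(groups)), baseline_sd >= 0,
            array_offset_sd >= 0, array_scale_sd >= 0, noise_sd >= 0)
  if (!is.null(effects)) {
    stopifnot(is.data.frame(effects),
              all(c("probe_id", "group", "fold") %in% names(effects)))
    if (any(effects$fold <= 0)) stop("planted fold changes must be > 0")
    if (!all(effects$group %in% names(groups))) {
      stop("planted effect references unknown group(s)")
    }
  }
  structure(list(n_probes = n_probes, groups = groups,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 array_offset_sd = array_offset_sd,
                 array_scale_sd = array_scale_sd, noise_sd = noise_sd,
                 effects = effects, seed = as.integer(seed)),
            class = "simulation_config")
}

probe_names <- function(n) sprintf("probe_%05d", seq_len(n))

#' Simulate a raw expression matrix with known truth
#'
#' Raw intensity of probe i on array j is
#' \code{10 ^ (offset_j + scale_j * (baseline_i + log10(fold_ig) + noise_ij))}:
#' a log-normal baseline per probe, a planted group effect for probes in
#' the effect table, per-array affine distortions of the log10 values
#' (which per-array Z-score normalization removes exactly), and i.i.d.
#' normal noise.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @return list with \code{matrix} (raw-scale
#'   \code{\link{expression_matrix}}), \code{design}
#'   (\code{\link{sample_design}}), and \code{truth} (the planted-effect
#'   table, possibly empty, with probe ids resolved).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  probes <- probe_names(cfg$n_probes)
  group_of <- rep(names(cfg$groups), cfg$groups)
  samples <- paste0(group_of, "_", unlist(lapply(cfg$groups, seq_len)))
  n_s <- length(samples)
  baseline <- stats::rnorm(cfg$n_probes, cfg$baseline_mean, cfg$baseline_sd)
  log_fold <- matrix(0, cfg$n_probes, n_s)
  truth <- cfg$effects
  if (!is.null(truth) && nrow(truth)) {
    bad <- setdiff(truth$probe_id, probes)
    if (length(bad)) {
      stop("planted probe id(s) outside the simulated range: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    for (r in seq_len(nrow(truth))) {
      i <- match(truth$probe_id[r], probes)
      j <- group_of == truth$group[r]
      log_fold[i, j] <- log10(truth$fold[r])
      if (!is.null(truth$baseline) && !is.na(truth$baseline[r])) {
        baseline[i] <- truth$baseline[r]
      }
    }
  } else {
    truth <- data.frame(probe_id = character(), group = character(),
                        fold = numeric(), stringsAsFactors = FALSE)
  }
  noise <- matrix(stats::rnorm(cfg$n_probes * n_s, 0, cfg$noise_sd),
                  cfg$n_probes, n_s)
  offset <- stats::rnorm(n_s, 0, cfg$array_offset_sd)
  gain <- stats::rnorm(n_s, 1, cfg$array_scale_sd)
  log10x <- sweep(sweep(baseline + log_fold + noise, 2L, gain, "*"),
                  2L, offset, "+")
  m <- expression_matrix(10^log10x, probe_ids = probes,
                         sample_ids = samples, scale = "raw")
  list(matrix = m, design = sample_design(samples, group_of), truth = truth)
}

#' Expected per-comparison truth from a planted-effect table
#'
#' Resolves the planted fold of each probe in comparison A vs B (fold in A
#' divided by fold in B, absent entries count as 1) and the expected call
#' direction.
#'
#' @param truth planted-effect table from \code{\link{simulate_expression}}.
#' @param group_a,group_b compared group labels.
#' @return data frame with \code{probe_id}, \code{fold} (ratio A/B) and
#'   \code{direction} for every probe with fold != 1.
#' @export
truth_for_comparison <- function(truth, group_a, group_b) {
  probes <- unique(truth$probe_id)
  get_fold <- function(g) {
    f <- rep(1, length(probes))
    sub <- truth[truth$group == g, ]
    f[match(sub$probe_id, probes)] <- sub$fold
    f
  }
  fold <- get_fold(group_a) / get_fold(group_b)
  out <- data.frame(probe_id = probes, fold = fold,
                    direction = ifelse(fold > 1, "up",
                                       ifelse(fold < 1, "down", "none")),
                    stringsAsFactors = FALSE)
  out[out$fold != 1, , drop = FALSE]
}

#' Simulate gene sets with planted coherent enrichment
#'
#' Draws null sets uniformly from the probe universe and enriched sets
#' mostly (fraction \code{frac_planted}) from planted up- or down-regulated
#' probes of one direction, topping up with random universe members.
#'
#' @param universe character vector of all probe/gene identifiers.
#' @param planted_up,planted_down identifiers of planted up-/down-regulated
#'   probes (may be empty, in which case no enriched set of that direction
#'   is produced).
#' @param n_null_sets number of null sets (default 20).
#' @param set_size members per set (default 20).
#' @param n_enriched enriched sets per available direction (default 2).
#' @param frac_planted fraction of an enriched set drawn from planted
#'   probes (default 0.8).
#' @param seed integer seed.
#' @return list with \code{sets} (a \code{\link{gene_set_collection}}) and
#'   \code{truth} (data frame \code{set_name}, \code{direction} with
#'   \code{"none"} for null sets).
#' @export
simulate_gene_sets <- function(universe, planted_up = character(),
                               planted_down = character(),
                               n_null_sets = 20, set_size = 20,
                               n_enriched = 2, frac_planted = 0.8,
                               seed = 1) {
  stopifnot(set_size >= 2, frac_planted > 0, frac_planted <= 1)
  if (set_size > length(universe)) stop("set size exceeds the universe")
  set.seed(as.integer(seed))
  sets <- list()
  truth <- data.frame(set_name = character(), direction = character(),
                      stringsAsFactors = FALSE)
  add_set <- function(name, members, direction) {
    sets[[name]] <<- members
    truth <<- rbind(truth, data.frame(set_name = name, direction = direction,
                                      stringsAsFactors = FALSE))
  }
  n_core <- ceiling(frac_planted * set_size)
  for (dir in c("up", "down")) {
    pool <- if (dir == "up") planted_up else planted_down
    if (length(pool) == 0L) next
    for (i in seq_len(n_enriched)) {
      core <- sample(pool, min(n_core, length(pool)))
      fill <- sample(setdiff(universe, core), set_size - length(core))
      add_set(sprintf("enriched_%s_%02d", dir, i), c(core, fill), dir)
    }
  }
  for (i in seq_len(n_null_sets)) {
    add_set(sprintf("null_set_%02d", i), sample(universe, set_size), "none")
  }
  list(sets = gene_set_collection(sets), truth = truth)
}

#' Simulate long-format qPCR Ct records from true expression ratios
#'
#' Control-group Cts are drawn around a base cycle number; treated-group
#' Cts are shifted by \code{-log_E(ratio)} so that the Pfaffl method with
#' the same efficiencies recovers the planted ratio (exactly when
#' \code{sd_ct = 0}). The reference gene has true ratio 1.
#'
#' @param true_ratios named numeric vector: treated/control expression
#'   ratio per target gene (> 0).
#' @param e_target,e_ref amplification efficiencies in (1, 2].
#' @param n_per_group samples per group (default 5).
#' @param sd_ct technical Ct noise sd in cycles (default 0.1).
#' @param control_group,treated_group group labels.
#' @param reference_gene reference gene name (default "GAPDH").
#' @param base_ct mean target Ct in the control group (default 24).
#' @param ref_ct mean reference-gene Ct (default 18).
#' @param seed integer seed.
#' @return long data frame: \code{gene}, \code{sample}, \code{group},
#'   \code{ct}, \code{role} (\code{"target"}/\code{"reference"}).
#' @export
simulate_qpcr <- function(true_ratios, e_target = 2, e_ref = 2,
                          n_per_group = 5, sd_ct = 0.1,
                          control_group = "sham", treated_group = "mTBI",
                          reference_gene = "GAPDH", base_ct = 24,
                          ref_ct = 18, seed = 1) {
  stopifnot(!is.null(names(true_ratios)), all(true_ratios > 0),
            n_per_group >= 2, sd_ct >= 0)
  if (any(e_target <= 1 | e_target > 2) || any(e_ref <= 1 | e_ref > 2)) {
    stop("amplification efficiencies must lie in (1, 2]")
  }
  set.seed(as.integer(seed))
  rows <- list()
  groups <- c(control_group, treated_group)
  samp <- function(g) paste0(g, "_", seq_len(n_per_group))
  for (gene in names(true_ratios)) {
    shift <- log(true_ratios[[gene]], base = e_target)
    for (g in groups) {
      mu <- if (g == treated_group) base_ct - shift else base_ct
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, sample = samp(g), group = g,
        ct = mu + stats::rnorm(n_per_group, 0, sd_ct), role = "target",
        stringsAsFactors = FALSE)
    }
  }
  for (g in groups) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = reference_gene, sample = samp(g), group = g,
      ct = ref_ct + stats::rnorm(n_per_group, 0, sd_ct), role = "reference",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate behavioral trials with planted group mean indices
#'
#' Draws per-animal preference indices from normal distributions (clamped
#' to (-1, 1)) and back-converts them to novel/familiar exploration times
#' with a fixed total exploration time, so that
#' \code{\link{preference_index}} recovers the drawn index exactly.
#'
#' @param group_means named numeric vector: true mean preference index per
#'   group, each in (-1, 1).
#' @param sd within-group sd of the index (default 0.2).
#' @param n_per_group animals per group (default 18).
#' @param total_time total exploration time per trial in seconds
#'   (default 40).
#' @param paradigm label stored in the table (default "NOR").
#' @param seed integer seed.
#' @return data frame: \code{animal}, \code{group}, \code{paradigm},
#'   \code{t_novel}, \code{t_familiar}, \code{true_index}.
#' @export
simulate_behavior <- function(group_means, sd = 0.2, n_per_group = 18,
                              total_time = 40, paradigm = "NOR", seed = 1) {
  stopifnot(!is.null(names(group_means)), all(abs(group_means) < 1),
            sd >= 0, n_per_group >= 2, total_time > 0)
  set.seed(as.integer(seed))
  rows <- lapply(names(group_means), function(g) {
    idx <- pmin(pmax(stats::rnorm(n_per_group, group_means[[g]], sd),
                     -0.999), 0.999)
    data.frame(animal = paste0(g, "_", seq_len(n_per_group)), group = g,
               paradigm = paradigm,
               t_novel = total_time * (1 + idx) / 2,
               t_familiar = total_time * (1 - idx) / 2,
               true_index = idx, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
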