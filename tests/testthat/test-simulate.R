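test_that("simulated trees are rooted, binary, positive-length and deterministic", {
  tr <- simulate_tree(2, 1)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(tr$Nnode, 1)
  expect_true(all(tr$edge.length > 0))

  t1 <- ape::write.tree(simulate_tree(100, 7))
  t2 <- ape::write.tree(simulate_tree(100, 7))
  expect_identical(t1, t2)

  # clade tip-counts recomputed from a newick re-parse agree
  tr3 <- simulate_tree(50, 3)
  reparsed <- ape::read.tree(text = ape::write.tree(tr3))
  count_clades <- function(tree) {
    tree <- stats::reorder(tree, "postorder")
    nt <- length(tree$tip.label)
    sz <- c(rep(1, nt), rep(0, tree$Nnode))
    for (e in seq_len(nrow(tree$edge)))
      sz[tree$edge[e, 1]] <- sz[tree$edge[e, 1]] + sz[tree$edge[e, 2]]
    sum(sz[(nt + 1):(nt + tree$Nnode)])
  }
  expect_equal(count_clades(tr3), count_clades(reparsed))
  expect_error(simulate_tree(1, 1), "n_asvs")
})

test_that("config validation enforces module and probability invariants", {
  expect_error(sim_config(module_spec = list(c(2, 0.5))), "module sizes")
  expect_error(sim_config(n_asvs = 10, module_spec = list(c(6, 0.5), c(6, 0.5))),
               "more than n_asvs")
  expect_error(sim_config(dmt_prob = 1.5), "probability")
  expect_error(sim_config(depth_min = 2e5, sequencing_depth_mean = 1e5),
               "depth_min")
  expect_error(sim_config(module_spec = list(c(5, 1.2))), "correlations")
})

test_that("count simulation respects depth, dimensions and block correlation", {
  cfg0 <- sim_config(n_subjects = 200, n_asvs = 30, module_spec = list(),
                     sequencing_depth_mean = 12000, depth_min = 10000, seed = 4)
  sim0 <- simulate_counts(cfg0)
  m <- unclass(sim0$table)
  expect_equal(dim(m), c(200, 30))
  expect_true(all(rowSums(m) >= 10000))

  # rho = 0 everywhere: CLR off-diagonal correlation small on average
  cc <- cor(clr_transform(sim0$table))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.1)

  # planted block: within-block correlation dominates between-block
  cfg1 <- sim_config(n_subjects = 300, n_asvs = 30,
                     module_spec = list(c(5, 0.9)),
                     sequencing_depth_mean = 12000, depth_min = 10000, seed = 5)
  sim1 <- simulate_counts(cfg1)
  cc1 <- cor(clr_transform(sim1$table))
  inb <- cc1[1:5, 1:5][upper.tri(diag(5))]
  outb <- cc1[1:5, 6:30]
  expect_gt(mean(inb), mean(outb))

  # determinism
  expect_identical(unclass(simulate_counts(cfg1)$table),
                   unclass(simulate_counts(cfg1)$table))
})

test_that("timelines honour zero hazards, refractory gaps and integer days", {
  cfg <- sim_config(n_subjects = 30, n_asvs = 10, module_spec = list(),
                    baseline_relapse_hazard = 0, baseline_lesion_hazard = 0,
                    sequencing_depth_mean = 1000, depth_min = 900, seed = 2)
  tls <- simulate_timelines(cfg)
  expect_true(all(vapply(tls, function(t) length(t$relapse_days) == 0, logical(1))))
  expect_true(all(vapply(tls, function(t)
    all(t$mri_scans$gad_event == 0) && all(t$mri_scans$t2_event == 0),
    logical(1))))

  for (s in 1:20) {
    cfg2 <- sim_config(n_subjects = 20, n_asvs = 10, module_spec = list(),
                       baseline_relapse_hazard = 0.01,
                       sequencing_depth_mean = 1000, depth_min = 900, seed = s)
    tls2 <- simulate_timelines(cfg2)
    for (t in tls2) {
      if (length(t$relapse_days) > 1)
        expect_gte(min(diff(t$relapse_days)), 30)
      expect_true(all(t$relapse_days == round(t$relapse_days)))
      base <- t$mri_scans$day[t$mri_scans$is_baseline == 1]
      expect_true(base >= -180 && base <= -1)
    }
  }
})

test_that("planted binary effect doubles the stratum-1 event rate at log-HR = log 2", {
  cfg <- sim_config(n_subjects = 2000, n_asvs = 10, module_spec = list(),
                    baseline_relapse_hazard = 0.002,
                    planted_effects = c(ASV0001 = log(2)),
                    sequencing_depth_mean = 1000, depth_min = 900, seed = 31)
  x <- rep(c(0, 1), length.out = 2000)
  feats <- matrix(x, ncol = 1, dimnames = list(NULL, "ASV0001"))
  tls <- simulate_timelines(cfg, feats)
  # stratum-1 exposure: day 0 to first relapse or censoring
  rate <- function(keep) {
    tt <- tls[keep]
    ev <- vapply(tt, function(t) length(t$relapse_days) > 0, logical(1))
    expo <- vapply(tt, function(t)
      if (length(t$relapse_days)) t$relapse_days[1] else t$last_visit_day,
      numeric(1))
    sum(ev) / sum(expo)
  }
  ratio <- rate(x == 1) / rate(x == 0)
  expect_gte(ratio, 1.8)
  expect_lte(ratio, 2.2)
})

test_that("cohorts are internally consistent and reproducible", {
  cfg <- sim_config(n_subjects = 12, n_asvs = 25,
                    module_spec = list(c(4, 0.7)),
                    sequencing_depth_mean = 3000, depth_min = 2500,
                    planted_effects = c(module1 = 0.5), seed = 9)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(unclass(co1$table), unclass(co2$table))
  expect_identical(ape::write.tree(co1$tree), ape::write.tree(co2$tree))
  expect_identical(co1$timelines, co2$timelines)
  expect_setequal(co1$tree$tip.label, colnames(co1$table))
  expect_equal(nrow(co1$truth$features), 12)
  expect_true("module1" %in% colnames(co1$truth$features))
  expect_error(
    simulate_counts(sim_config(n_subjects = 5, n_asvs = 10,
                               module_spec = list(),
                               sequencing_depth_mean = 1000, depth_min = 900,
                               planted_effects = c(nonsense = 1), seed = 1)),
    "not in cohort")
})

test_that("dimension emulation matches the study's table shape", {
  cfg <- sim_config(seed = 20)
  sim <- simulate_counts(cfg)
  expect_equal(dim(unclass(sim$table)), c(55, 1482))
  expect_true(all(rowSums(unclass(sim$table)) >= 84818))
})
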