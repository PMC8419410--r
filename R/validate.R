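#' Simulation studies validating the recurrent-event machinery
#'
#' These functions run the package's own generative model against its own
#' estimators and report operating characteristics: estimation bias and
#' confidence-interval coverage for a planted effect, type-I error for
#' null features, proportional-hazards test calibration, module recovery,
#' and PERMANOVA null calibration.  They power the acceptance checks and
#' are exported so users can rerun them at any size.
#'
#' @name validation_studies
NULL

# shared core: simulate one relapse cohort with a per-subject binary
# feature carrying log-HR `true_loghr`, fit the adjusted PWP model
fit_one_binary_cohort <- function(n_subjects, true_loghr, seed) {
  cfg <- sim_config(n_subjects = n_subjects, n_asvs = 2, module_spec = list(),
                    sequencing_depth_mean = 1000, depth_min = 900,
                    planted_effects = c(feature = true_loghr), seed = seed)
  set.seed(child_seed(seed, 7))
  x <- stats::rbinom(n_subjects, 1, 0.5)
  feats <- matrix(x, ncol = 1, dimnames = list(NULL, "feature"))
  tls <- simulate_timelines(cfg, feats)
  ids <- vapply(tls, function(t) t$subject_id, character(1))
  iv <- attach_covariates(
    bind_intervals(lapply(tls, build_relapse_intervals)), tls,
    feature = stats::setNames(x, ids))
  covs <- c("feature", "sex", "age", "dmt")
  covs <- covs[vapply(covs, function(cv) stats::sd(iv[[cv]]) > 0, logical(1))]
  if (!"feature" %in% covs) return(NULL)
  fit <- tryCatch(fit_pwp_cox(iv, covs), error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  hr <- hazard_ratio(fit, "feature")
  list(est = hr$log_hr, se = hr$robust_se, p = hr$p,
       lo = log(hr$ci_low), hi = log(hr$ci_high))
}

#' @rdname validation_studies
#' @param n_rep number of simulation replicates.
#' @param n_subjects subjects per simulated cohort.
#' @param true_loghr planted log hazard ratio of the binary feature.
#' @param seed master seed.
#' @return `pwp_recovery_study`: list with `mean_bias` (mean of
#'   estimate minus truth), `abs_mean_bias`, `coverage` (robust 95% CI),
#'   `n_converged`.
#' @export
pwp_recovery_study <- function(n_rep = 200, n_subjects = 150,
                               true_loghr = log(2), seed = 1) {
  est <- lo <- hi <- numeric(0)
  for (r in seq_len(n_rep)) {
    one <- fit_one_binary_cohort(n_subjects, true_loghr,
                                 child_seed(seed, r))
    if (is.null(one)) next
    est <- c(est, one$est); lo <- c(lo, one$lo); hi <- c(hi, one$hi)
  }
  list(mean_bias = mean(est) - true_loghr,
       abs_mean_bias = abs(mean(est) - true_loghr),
       coverage = mean(lo <= true_loghr & true_loghr <= hi),
       n_converged = length(est))
}

#' @rdname validation_studies
#' @param n_fits number of independent null-feature fits.
#' @param family_size null features per BH family when summarizing false
#'   families.
#' @return `pwp_null_study`: list with `type1_error` (robust Wald at
#'   0.05), `p_values`, `false_families` (families of `family_size` with
#'   any BH discovery at q < 0.05), `n_families`, `n_converged`.
#' @export
pwp_null_study <- function(n_fits = 1000, n_subjects = 150, seed = 2,
                           family_size = 200) {
  p <- numeric(0)
  for (r in seq_len(n_fits)) {
    one <- fit_one_binary_cohort(n_subjects, 0, child_seed(seed, r))
    if (is.null(one)) next
    p <- c(p, one$p)
  }
  n_fam <- floor(length(p) / family_size)
  false_fam <- 0L
  for (f in seq_len(n_fam)) {
    fam <- p[((f - 1) * family_size + 1):(f * family_size)]
    if (any(bh_fdr(fam) < 0.05)) false_fam <- false_fam + 1L
  }
  list(type1_error = mean(p < 0.05), p_values = p,
       false_families = false_fam, n_families = n_fam,
       n_converged = length(p))
}

#' @rdname validation_studies
#' @param n_events_per_rep sample size (all-event exponential cohort) of
#'   each proportional-hazards null replicate.
#' @return `ph_null_study`: list with `rejection_rate` at 0.05 and
#'   `n_converged`.
#' @export
ph_null_study <- function(n_rep = 500, n_events_per_rep = 60, seed = 3) {
  rej <- c()
  set.seed(as.integer(seed))
  for (r in seq_len(n_rep)) {
    n <- n_events_per_rep
    x <- stats::rbinom(n, 1, 0.5)
    t <- stats::rexp(n, 0.1 * exp(0.5 * x))
    d <- data.frame(subject = as.character(seq_len(n)), stratum = 1,
                    start = 0, stop = round(t * 100) + 1, event = 1, x = x)
    fit <- tryCatch(fit_pwp_cox(d, "x"), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    rej <- c(rej, ph_test(fit)$p[1] < 0.05)
  }
  list(rejection_rate = mean(rej), n_converged = length(rej))
}

#' @rdname validation_studies
#' @param module_sizes planted block sizes (all >= 3).
#' @param rho within-block latent correlation.
#' @param n_samples samples per replicate for module recovery.
#' @return `module_recovery_study`: list with `mean_ari` (adjusted Rand
#'   index of the assignment against the planted blocks, background taxa
#'   included as their own class), `max_eigengene_cor` (largest post-merge
#'   pairwise eigengene correlation observed), per-replicate `ari`.
#' @export
module_recovery_study <- function(n_rep = 10, n_samples = 100,
                                  module_sizes = c(10, 7, 5), rho = 0.7,
                                  n_asvs = 40, seed = 4) {
  aris <- numeric(n_rep)
  max_cor <- 0
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_subjects = n_samples, n_asvs = n_asvs,
                      module_spec = lapply(module_sizes, function(s) c(s, rho)),
                      sequencing_depth_mean = 20000, depth_min = 15000,
                      seed = child_seed(seed, r))
    sim <- simulate_counts(cfg)
    ms <- cooccurrence_modules(sim$table, min_prevalence = 0.1)
    truth <- sim$truth$modules[names(ms$assignment)]
    aris[r] <- adjusted_rand_index(ms$assignment, truth)
    if (!is.null(ms$eigengenes) && ncol(ms$eigengenes) > 1) {
      cc <- stats::cor(ms$eigengenes)
      max_cor <- max(max_cor, max(cc[upper.tri(cc)]))
    }
  }
  list(mean_ari = mean(aris), ari = aris, max_eigengene_cor = max_cor)
}

#' @rdname validation_studies
#' @param true_loghr_per_sd planted per-SD log hazard ratio carried by the
#'   first module's latent factor.
#' @return `module_detection_study`: list with `detection_rate` (fraction
#'   of replicates where the eigengene best tracking the planted factor
#'   reaches q < 0.05 in the module family) and `n_rep`.
#' @export
module_detection_study <- function(n_rep = 100, n_subjects = 300,
                                   true_loghr_per_sd = 0.5, seed = 5) {
  hit <- logical(0)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_subjects = n_subjects, n_asvs = 40,
                      module_spec = list(c(8, 0.7), c(6, 0.7), c(5, 0.7)),
                      sequencing_depth_mean = 20000, depth_min = 15000,
                      planted_effects = c(module1 = true_loghr_per_sd),
                      seed = child_seed(seed, r))
    sim <- simulate_counts(cfg)
    tls <- simulate_timelines(cfg, sim$truth$features)
    ms <- cooccurrence_modules(sim$table, min_prevalence = 0.1)
    if (is.null(ms$eigengenes)) { hit <- c(hit, FALSE); next }
    res <- run_module_association(ms$eigengenes, tls, "relapse")
    target <- colnames(ms$eigengenes)[
      which.max(abs(stats::cor(ms$eigengenes,
                               sim$truth$features[, "module1"])))]
    q <- res$q[res$feature_id == target]
    hit <- c(hit, length(q) == 1 && !is.na(q) && q < 0.05)
  }
  list(detection_rate = mean(hit), n_rep = length(hit))
}

#' @rdname validation_studies
#' @param n_samples samples per PERMANOVA replicate.
#' @param n_perm permutations per replicate.
#' @return `permanova_null_study`: list with `ks_stat` (Kolmogorov-Smirnov
#'   distance of the null p-values from uniform), `max_partition_error`
#'   (largest deviation of the R-squared partition from 1), `p_values`.
#' @export
permanova_null_study <- function(n_rep = 500, n_samples = 30, n_perm = 199,
                                 seed = 6) {
  p <- numeric(n_rep)
  max_err <- 0
  for (r in seq_len(n_rep)) {
    set.seed(child_seed(seed, r))
    coords <- matrix(stats::rnorm(n_samples * 3), n_samples)
    D <- as.matrix(stats::dist(coords))
    ids <- sprintf("s%03d", seq_len(n_samples))
    dimnames(D) <- list(ids, ids)
    covs <- data.frame(sex = stats::rbinom(n_samples, 1, 0.5),
                       age = stats::rnorm(n_samples, 15, 2))
    y <- stats::rbinom(n_samples, 1, 0.5)
    if (length(unique(y)) < 2 || length(unique(covs$sex)) < 2) {
      y <- rep_len(c(0, 1), n_samples)
    }
    pm <- permanova(D, covs, y, n_perm = n_perm,
                    seed = child_seed(seed, r) %% 100000 + 1)
    p[r] <- pm$p[pm$term == "outcome"]
    max_err <- max(max_err, abs(sum(pm$r2[pm$term != "total"]) - 1))
  }
  ks <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
  list(ks_stat = unname(ks), max_partition_error = max_err, p_values = p)
}

# adjusted Rand index (labels of any type; 0 treated as its own class)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  ex <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - ex
  if (denom == 0) return(1)
  (sij - ex) / denom
}
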