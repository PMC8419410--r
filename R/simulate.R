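#' Configuration for synthetic cohort generation
#'
#' Defaults emulate the target study design: ~55 pediatric-onset MS cases
#' (mean age 15.9 y, IQR 2.5, 72.7% female), ~1,482 ASVs sequenced to a
#' minimum depth of 84,818 reads/sample, block-correlated taxa forming
#' co-occurrence modules of at least 3 members, recurrent relapses with a
#' 30-day refractory period over roughly 2.2 years of follow-up, MRI scans
#' at ~6-month intervals with binary new-lesion flags, and time-varying
#' DMT exposure.  Baseline hazards are calibrated so that about 44% of
#' subjects relapse at least once over follow-up; they are configuration,
#' not estimates.
#'
#' @param n_subjects number of subjects.
#' @param n_asvs number of ASVs.
#' @param module_spec list of `c(size, rho)` pairs: module sizes (>= 3,
#'   disjoint memberships assigned to the first ASVs) and within-block
#'   latent correlations in \[0, 1\].
#' @param sequencing_depth_mean mean reads per sample.
#' @param depth_min minimum reads per sample (all row sums >= this).
#' @param baseline_relapse_hazard baseline relapse hazard, events/day.
#' @param baseline_lesion_hazard baseline new-lesion hazard, events/day
#'   (applied to gadolinium and T2 lesions independently).
#' @param planted_effects named numeric vector mapping feature ids to true
#'   log hazard ratios.  Feature ids are either `"module<k>"` (the k-th
#'   module's latent factor, per SD) or an ASV id (a balanced binary
#'   indicator of its latent abundance).
#' @param followup_days nominal clinical follow-up, days.
#' @param mri_interval_mean mean inter-scan interval, days.
#' @param first_scan_early_frac fraction of subjects whose first post-stool
#'   scan is drawn early (10-80 days), so that an event there can have a
#'   pre-stool midpoint and exercise the exclusion rule.
#' @param dmt_prob probability a subject has DMT exposure.
#' @param sex_prob_female probability of female sex.
#' @param age_mean,age_iqr age distribution at stool collection (normal
#'   with sd = IQR/1.349).
#' @param seed master integer seed; expanded into per-component child
#'   seeds via [child_seed()].
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 55,
                       n_asvs = 1482,
                       module_spec = list(c(8, 0.7), c(6, 0.7), c(5, 0.7)),
                       sequencing_depth_mean = 100000,
                       depth_min = 84818,
                       baseline_relapse_hazard = 0.00073,
                       baseline_lesion_hazard = 0.0006,
                       planted_effects = numeric(0),
                       followup_days = 800,
                       mri_interval_mean = 180,
                       first_scan_early_frac = 0.15,
                       dmt_prob = 0.6,
                       sex_prob_female = 0.727,
                       age_mean = 15.9,
                       age_iqr = 2.5,
                       seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_asvs = as.integer(n_asvs),
              module_spec = module_spec,
              sequencing_depth_mean = sequencing_depth_mean,
              depth_min = depth_min,
              baseline_relapse_hazard = baseline_relapse_hazard,
              baseline_lesion_hazard = baseline_lesion_hazard,
              planted_effects = planted_effects,
              followup_days = followup_days,
              mri_interval_mean = mri_interval_mean,
              first_scan_early_frac = first_scan_early_frac,
              dmt_prob = dmt_prob, sex_prob_female = sex_prob_female,
              age_mean = age_mean, age_iqr = age_iqr,
              seed = as.integer(seed))
  # accept list-of-lists (e.g. parsed YAML) as well as list of c(size, rho)
  cfg$module_spec <- lapply(cfg$module_spec,
                            function(m) as.numeric(unlist(m)))
  sizes <- vapply(cfg$module_spec, `[`, numeric(1), 1)
  rhos <- vapply(cfg$module_spec, `[`, numeric(1), 2)
  if (length(sizes) && any(sizes < 3))
    stop_invalid("all module sizes must be >= 3")
  if (length(rhos) && any(rhos < 0 | rhos > 1))
    stop_invalid("module correlations must lie in [0, 1]")
  if (sum(sizes) > cfg$n_asvs)
    stop_invalid("module sizes sum to more than n_asvs")
  if (cfg$depth_min > cfg$sequencing_depth_mean)
    stop_invalid("depth_min must be <= sequencing_depth_mean")
  check_prob(cfg$dmt_prob, "dmt_prob")
  check_prob(cfg$sex_prob_female, "sex_prob_female")
  check_prob(cfg$first_scan_early_frac, "first_scan_early_frac")
  if (cfg$baseline_relapse_hazard < 0 || cfg$baseline_lesion_hazard < 0)
    stop_invalid("baseline hazards must be >= 0")
  if (length(cfg$planted_effects) && is.null(names(cfg$planted_effects)))
    stop_invalid("planted_effects must be a named numeric vector")
  structure(cfg, class = "sim_config")
}

asv_ids <- function(n) sprintf("ASV%04d", seq_len(n))

#' Simulate a random rooted phylogeny over ASVs
#'
#' Random rooted binary tree with positive branch lengths and tip labels
#' equal to the ASV ids; substrate for Faith's phylogenetic diversity and
#' UniFrac.  Deterministic for a given seed.
#'
#' @param n_asvs number of tips (>= 2).
#' @param seed integer seed.
#' @return an `ape::phylo` tree.
#' @export
simulate_tree <- function(n_asvs, seed) {
  if (n_asvs < 2) stop_invalid("n_asvs must be >= 2")
  set.seed(as.integer(seed))
  tr <- ape::rtree(n_asvs, rooted = TRUE)
  # rtree labels tips t1..tn in random order; assign ASV ids in tip order
  tr$tip.label <- asv_ids(n_asvs)
  tr$edge.length <- pmax(tr$edge.length, 1e-6)
  tr
}

#' Simulate an ASV count table with planted co-occurrence blocks
#'
#' Logistic-normal-multinomial generator: per-subject latent Gaussian
#' factors with block covariance per `module_spec` are added to a fixed
#' log-scale baseline abundance profile, softmaxed to relative abundances,
#' and read counts are drawn multinomially at a subject-specific depth
#' (`depth_min` plus a Poisson excess, so every row sum >= `depth_min`).
#' Block members load on a shared factor with loading sqrt(rho), giving a
#' within-block latent correlation of rho.
#'
#' @param config a [sim_config()].
#' @return list with `table` (an [asv_table()]) and `truth` (list:
#'   `features` per-subject values for every planted feature, `modules`
#'   ASV -> module map, `log_hr` the planted log hazard ratios, `factors`
#'   the latent module factors).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 2))
  n <- config$n_subjects
  p <- config$n_asvs
  ids <- asv_ids(p)
  sizes <- vapply(config$module_spec, `[`, numeric(1), 1)
  rhos <- vapply(config$module_spec, `[`, numeric(1), 2)
  n_mod <- length(sizes)
  membership <- integer(p)
  idx <- 1L
  for (m in seq_len(n_mod)) {
    membership[idx:(idx + sizes[m] - 1L)] <- m
    idx <- idx + as.integer(sizes[m])
  }
  names(membership) <- ids

  alpha <- stats::rnorm(p, 0, 2)             # baseline log-abundance profile
  factors <- matrix(stats::rnorm(n * max(n_mod, 1L)), n, max(n_mod, 1L))
  z <- matrix(stats::rnorm(n * p), n, p)
  for (m in seq_len(n_mod)) {
    cols <- which(membership == m)
    z[, cols] <- sqrt(rhos[m]) * factors[, m] +
      sqrt(1 - rhos[m]) * z[, cols]
  }
  eta <- sweep(z, 2L, alpha, `+`)
  rel <- exp(eta)
  rel <- rel / rowSums(rel)

  extra <- config$sequencing_depth_mean - config$depth_min
  depths <- config$depth_min + stats::rpois(n, extra)
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1, depths[i], rel[i, ])[, 1],
                     integer(p)))
  subj <- sprintf("S%03d", seq_len(n))
  dimnames(counts) <- list(subj, ids)

  feats <- matrix(numeric(0), n, 0, dimnames = list(subj, NULL))
  for (f in names(config$planted_effects)) {
    v <- if (grepl("^module[0-9]+$", f)) {
      m <- as.integer(sub("module", "", f))
      if (m > n_mod) stop_invalid("planted feature ", f, ": no such module")
      factors[, m]
    } else if (f %in% ids) {
      as.numeric(z[, match(f, ids)] > 0)
    } else stop_invalid("planted feature id not in cohort: ", f)
    feats <- cbind(feats, v)
    colnames(feats)[ncol(feats)] <- f
  }
  list(table = asv_table(counts),
       truth = list(features = feats, modules = membership,
                    log_hr = config$planted_effects, factors = factors))
}

#' Simulate subject event timelines under proportional hazards
#'
#' Event histories are generated by inverting the analysis model: relapse
#' gap times are exponential with hazard
#' `baseline_relapse_hazard * exp(sum planted log-HR x feature)`, the first
#' measured from day 0 and each later one from 30 days after the previous
#' relapse (the refractory period).  MRI scans are scheduled at jittered
#' `mri_interval_mean` intervals with a baseline scan in \[-180, -1\];
#' each inter-scan interval carries a new-lesion flag with probability
#' `1 - exp(-hazard x interval length)`, gadolinium and T2 independently.
#' DMT exposure is a single interval per exposed subject.  All days are
#' integers; output is deterministic given `(config, features)`.
#'
#' @param config a [sim_config()].
#' @param features data.frame/matrix of per-subject feature values (rows =
#'   subjects, in order; columns named as in `planted_effects`), or NULL
#'   when no effects are planted.
#' @return list of [subject_timeline()] objects.
#' @export
simulate_timelines <- function(config, features = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 3))
  n <- config$n_subjects
  eff <- config$planted_effects
  if (length(eff)) {
    if (is.null(features)) stop_invalid("planted effects require 'features'")
    features <- as.matrix(features)
    miss <- setdiff(names(eff), colnames(features))
    if (length(miss))
      stop_invalid("unknown planted feature id(s): ", paste(miss, collapse = ", "))
    lp <- drop(features[, names(eff), drop = FALSE] %*% eff)
  } else lp <- rep(0, n)

  lapply(seq_len(n), function(i) {
    sid <- sprintf("S%03d", i)
    sex <- stats::rbinom(1, 1, config$sex_prob_female)
    age <- stats::rnorm(1, config$age_mean, config$age_iqr / 1.349)
    L <- max(60, round(config$followup_days + stats::rnorm(1, 0, 45)))

    h_rel <- config$baseline_relapse_hazard * exp(lp[i])
    relapses <- numeric(0)
    t <- 0
    first <- TRUE
    while (h_rel > 0) {
      gap <- ceiling(stats::rexp(1, h_rel)) + if (first) 0 else 30
      t <- t + gap
      if (t > L) break
      relapses <- c(relapses, t)
      first <- FALSE
    }

    base_day <- -sample.int(180, 1)
    early <- stats::runif(1) < config$first_scan_early_frac
    scan_days <- numeric(0)
    t <- 0
    repeat {
      step <- if (!length(scan_days) && early) sample(10:80, 1) else
        max(14, round(config$mri_interval_mean * stats::runif(1, 0.5, 1.5)))
      t <- t + step
      if (t > L) break
      scan_days <- c(scan_days, t)
    }
    h_les <- config$baseline_lesion_hazard * exp(lp[i])
    all_days <- c(base_day, scan_days)
    lens <- diff(all_days)
    gad <- t2 <- integer(length(scan_days))
    if (length(scan_days)) {
      pe <- 1 - exp(-h_les * lens)
      gad <- stats::rbinom(length(scan_days), 1, pe)
      t2 <- stats::rbinom(length(scan_days), 1, pe)
    }
    mri <- data.frame(day = all_days,
                      gad_event = c(0L, gad), t2_event = c(0L, t2),
                      is_baseline = c(1L, integer(length(scan_days))))
    dmt <- if (stats::runif(1) < config$dmt_prob) {
      data.frame(start_day = round(stats::runif(1, -90, L / 2)), end_day = L)
    } else empty_dmt()
    subject_timeline(sid, sex, age, relapse_days = relapses,
                     last_visit_day = L, mri_scans = mri,
                     dmt_intervals = dmt)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Bundles [simulate_tree()], [simulate_counts()] and
#' [simulate_timelines()] into a consistent cohort: count table, rooted
#' phylogeny over the same ASV ids, per-subject event timelines driven by
#' the planted features, and the ground truth.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `table`, `tree`,
#'   `timelines`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cnt <- simulate_counts(config)
  tree <- simulate_tree(config$n_asvs, child_seed(config$seed, 1))
  tls <- simulate_timelines(config, cnt$truth$features)
  structure(list(table = cnt$table, tree = tree, timelines = tls,
                 truth = cnt$truth, config = config),
            class = "sim_cohort")
}
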