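#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate correction:
#' \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j}, capped at 1 and mapped
#' back to input order.  Delegates to `stats::p.adjust(method = "BH")`
#' after validating the inputs.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, monotone in p.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stop_invalid("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Analysis run configuration
#'
#' Thresholds and knobs for the association pipeline: prevalence filters
#' (20% for ASV-level analyses, 10% for network construction), the FDR
#' significance threshold 0.05 and the less stringent secondary threshold
#' 0.2, event-truncation caps (3 relapses, 2 lesions), tie handling,
#' permutation count, rarefaction draws and the master seed.
#'
#' @param prevalence_asv ASV-level prevalence filter.
#' @param prevalence_network network prevalence filter.
#' @param fdr_alpha primary FDR significance threshold.
#' @param fdr_secondary secondary (less stringent) threshold.
#' @param max_relapses relapse truncation cap.
#' @param max_lesions lesion truncation cap.
#' @param ties Cox tie handling.
#' @param n_perm PERMANOVA permutations.
#' @param rarefy_draws representative-rarefaction draws.
#' @param min_fraction total-reads ASV filter.
#' @param soft_power soft-thresholding power.
#' @param merge_r eigengene merge threshold.
#' @param eigengene_scale HR scaling unit for eigengenes (and evenness).
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(prevalence_asv = 0.20, prevalence_network = 0.10,
                       fdr_alpha = 0.05, fdr_secondary = 0.2,
                       max_relapses = 3, max_lesions = 2,
                       ties = "efron", n_perm = 999, rarefy_draws = 100,
                       min_fraction = 1e-5, soft_power = 6, merge_r = 0.5,
                       eigengene_scale = 0.1, seed = 1) {
  cfg <- as.list(environment())
  for (nm in c("prevalence_asv", "prevalence_network", "fdr_alpha",
               "fdr_secondary"))
    check_prob(cfg[[nm]], nm)
  if (max_relapses < 1 || max_lesions < 1)
    stop_invalid("truncation caps must be >= 1")
  structure(cfg, class = "run_config")
}

# which subjects can contribute to an outcome's analytic cohort
outcome_cohort <- function(timelines, outcome) {
  keep <- vapply(timelines, function(tl) {
    if (outcome == "relapse") tl$last_visit_day > 0
    else {
      any(tl$mri_scans$is_baseline == 1 & tl$mri_scans$day <= 0) &&
        any(tl$mri_scans$day > 0)
    }
  }, logical(1))
  timelines[keep]
}

# build + covariate-attach the outcome's interval table once per cohort
outcome_intervals <- function(timelines, outcome, config) {
  tabs <- lapply(timelines, function(tl) {
    if (outcome == "relapse")
      build_relapse_intervals(tl, max_events = config$max_relapses)
    else
      suppressWarnings(build_mri_intervals(tl, lesion_type = outcome,
                                           max_events = config$max_lesions))
  })
  attach_covariates(bind_intervals(tabs), timelines)
}

# fit one feature against a prepared interval table; returns a result row
fit_feature <- function(intervals, values, feature_id, level, outcome,
                        config, scale = 1, ph_fallback = FALSE) {
  intervals$feature <- as.numeric(values[intervals$subject])
  n_subj <- length(unique(intervals$subject))
  covs <- c("feature", "sex", "age", "dmt")
  # drop non-identifiable adjusters (e.g. all-male cohort)
  covs <- covs[vapply(covs, function(cv)
    stats::sd(intervals[[cv]]) > 0, logical(1))]
  if (!"feature" %in% covs)
    return(result_row(feature_id, level, outcome, n_subj,
                      sum(intervals$event), flag = "constant-feature"))
  fit <- tryCatch(fit_pwp_cox(intervals, covs, ties = config$ties),
                  error = function(e) e)
  if (inherits(fit, "error"))
    return(result_row(feature_id, level, outcome, n_subj,
                      sum(intervals$event), flag = "fit-error"))
  if (!fit$converged)
    return(result_row(feature_id, level, outcome, n_subj, fit$n_events,
                      flag = "non-converged"))
  hr <- hazard_ratio(fit, "feature", scale = scale)
  php <- tryCatch(ph_test(fit)$p[1], error = function(e) NA_real_)
  flag <- ""
  if (ph_fallback && !is.na(php) && php < 0.05) {
    ti <- tryCatch(add_time_interaction(intervals, "feature", covs,
                                        ties = config$ties),
                   error = function(e) NULL)
    if (!is.null(ti) && ti$fit$converged) {
      if (ti$interaction_p >= 0.05) {
        flag <- "time-interaction-tested"       # main-effect model retained
      } else {
        flag <- "time-interaction-used"
        hr <- hazard_ratio(ti$fit, "feature", scale = scale)
      }
    }
  }
  data.frame(feature_id = feature_id, feature_level = level,
             outcome = outcome, log_hr = hr$log_hr, hr = hr$hr,
             ci_low = hr$ci_low, ci_high = hr$ci_high,
             robust_se = hr$robust_se, p = hr$p, q = NA_real_,
             n_subjects = n_subj, n_events = fit$n_events,
             ph_test_p = php, flags = flag, stringsAsFactors = FALSE)
}

result_row <- function(feature_id, level, outcome, n_subj, n_events, flag) {
  data.frame(feature_id = feature_id, feature_level = level,
             outcome = outcome, log_hr = NA_real_, hr = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, robust_se = NA_real_,
             p = NA_real_, q = NA_real_, n_subjects = n_subj,
             n_events = n_events, ph_test_p = NA_real_, flags = flag,
             stringsAsFactors = FALSE)
}

# BH within the family of converged fits; non-converged stay q = NA
finalize_family <- function(rows) {
  if (!nrow(rows)) return(rows)
  ok <- !is.na(rows$p)
  rows$q[ok] <- bh_fdr(rows$p[ok])
  rows[order(rows$q, rows$p, rows$feature_id, na.last = TRUE), , drop = FALSE]
}

#' ASV-level association analysis
#'
#' For every ASV at >= 20% prevalence in the outcome's analytic cohort:
#' dichotomize by prevalence class, build the outcome's PWP risk
#' intervals, adjust for sex, age at event and time-varying DMT use, fit
#' the stratified Cox model with cluster-robust variance, and apply BH
#' FDR across the outcome's ASV family.  Non-converged fits are flagged
#' and excluded from the FDR family.
#'
#' @param table rarefied [asv_table()] (rows must cover the cohort).
#' @param timelines list of [subject_timeline()].
#' @param outcome `"relapse"`, `"gad"` or `"t2"`.
#' @param config a [run_config()].
#' @return data.frame of association results sorted by q then p.
#' @export
run_asv_association <- function(table, timelines, outcome, config = run_config()) {
  outcome <- match.arg(outcome, c("relapse", "gad", "t2"))
  timelines <- outcome_cohort(timelines, outcome)
  ids <- vapply(timelines, function(t) t$subject_id, character(1))
  counts <- counts_of(table)
  miss <- setdiff(ids, rownames(counts))
  if (length(miss))
    stop_invalid("count table lacks cohort subject(s): ",
                 paste(miss, collapse = ", "))
  cohort_tab <- retable(table, counts[ids, , drop = FALSE])
  cohort_tab <- prevalence_filter(cohort_tab, config$prevalence_asv)
  if (!ncol(counts_of(cohort_tab)))
    stop_invalid("no ASVs pass the prevalence filter")
  intervals <- outcome_intervals(timelines, outcome, config)
  rows <- lapply(colnames(counts_of(cohort_tab)), function(aid) {
    feat <- dichotomize(cohort_tab, aid)
    fit_feature(intervals, feat$values, aid, "asv", outcome, config)
  })
  res <- finalize_family(do.call(rbind, rows))
  if (all(is.na(res$p)))
    stop_invalid("all ASV fits failed for outcome ", outcome, "; flags: ",
                 paste(unique(res$flags), collapse = ", "))
  res
}

#' Module-eigengene association analysis
#'
#' Each module eigengene is modelled as a continuous covariate; hazard
#' ratios are reported per 0.1-unit eigengene increase.  The proportional-
#' hazards assumption is tested for every model; on failure a
#' time-by-eigengene interaction model is fitted, the main-effect model is
#' retained when the interaction is not significant (p >= 0.05), and the
#' interaction model is reported (flagged) otherwise.  BH FDR across the
#' outcome's modules.
#'
#' @param eigengenes samples-by-modules matrix (from
#'   [cooccurrence_modules()]).
#' @param timelines list of [subject_timeline()].
#' @param outcome `"relapse"`, `"gad"` or `"t2"`.
#' @param config a [run_config()].
#' @return data.frame of association results.
#' @export
run_module_association <- function(eigengenes, timelines, outcome,
                                   config = run_config()) {
  outcome <- match.arg(outcome, c("relapse", "gad", "t2"))
  timelines <- outcome_cohort(timelines, outcome)
  ids <- vapply(timelines, function(t) t$subject_id, character(1))
  miss <- setdiff(ids, rownames(eigengenes))
  if (length(miss))
    stop_invalid("eigengene matrix lacks cohort subject(s): ",
                 paste(miss, collapse = ", "))
  intervals <- outcome_intervals(timelines, outcome, config)
  rows <- lapply(colnames(eigengenes), function(m) {
    v <- stats::setNames(eigengenes[ids, m], ids)
    fit_feature(intervals, v, m, "module", outcome, config,
                scale = config$eigengene_scale, ph_fallback = TRUE)
  })
  finalize_family(do.call(rbind, rows))
}

#' Pathway-abundance association analysis
#'
#' Pathways (supplied externally, e.g. predicted metabolic pathway
#' abundances) present in at least 20% of samples are dichotomized at
#' their median (strictly greater = "high") and fitted only for the
#' outcomes previously linked to the parent module; BH FDR within each
#' outcome's pathway family.
#'
#' @param pathways samples-by-pathways abundance matrix.
#' @param timelines list of [subject_timeline()].
#' @param outcomes outcomes to fit (the significant-module outcomes).
#' @param config a [run_config()].
#' @return data.frame of association results (zero rows, with a warning,
#'   when no pathway passes the filter or `outcomes` is empty).
#' @export
run_pathway_association <- function(pathways, timelines, outcomes,
                                    config = run_config()) {
  pathways <- as.matrix(pathways)
  keep <- colMeans(pathways > 0) >= 0.20 - 1e-12
  if (!length(outcomes) || !any(keep)) {
    warning("empty pathway family: nothing to fit")
    return(result_row("x", "pathway", "none", 0L, 0L, "")[0, ])
  }
  pathways <- pathways[, keep, drop = FALSE]
  out <- lapply(outcomes, function(oc) {
    tls <- outcome_cohort(timelines, oc)
    ids <- vapply(tls, function(t) t$subject_id, character(1))
    intervals <- outcome_intervals(tls, oc, config)
    rows <- lapply(colnames(pathways), function(pw) {
      feat <- dichotomize_pathway(stats::setNames(pathways[ids, pw], ids), pw)
      fit_feature(intervals, feat$values, pw, "pathway", oc, config)
    })
    finalize_family(do.call(rbind, rows))
  })
  do.call(rbind, out)
}

#' Alpha-diversity association analysis
#'
#' Chao1, Faith's phylogenetic diversity and Pielou evenness (computed on
#' the rarefied table) as continuous covariates; evenness hazard ratios
#' are scaled per 0.1-unit change, richness metrics per 1 unit.  Subjects
#' with undefined metric values are dropped with a message.
#'
#' @param alpha data.frame from [alpha_diversity()] (column `sample` =
#'   subject id).
#' @param timelines list of [subject_timeline()].
#' @param outcome `"relapse"`, `"gad"` or `"t2"`.
#' @param config a [run_config()].
#' @return data.frame of association results (one row per metric; no FDR
#'   family is formed across metrics).
#' @export
run_alpha_association <- function(alpha, timelines, outcome,
                                  config = run_config()) {
  outcome <- match.arg(outcome, c("relapse", "gad", "t2"))
  timelines <- outcome_cohort(timelines, outcome)
  ids <- vapply(timelines, function(t) t$subject_id, character(1))
  rows <- lapply(c("chao1", "faith_pd", "pielou"), function(metric) {
    v <- stats::setNames(alpha[[metric]][match(ids, alpha$sample)], ids)
    drop <- is.na(v)
    if (any(drop))
      message(sum(drop), " subject(s) dropped for undefined ", metric)
    tls <- timelines[!drop]
    intervals <- outcome_intervals(tls, outcome, config)
    fit_feature(intervals, v[!drop], metric, "alpha", outcome, config,
                scale = if (metric == "pielou") config$eigengene_scale else 1)
  })
  res <- do.call(rbind, rows)
  res$q <- res$p   # single-metric families: q = p
  res
}

#' Cross-outcome effect-size comparison
#'
#' Features associated with at least one outcome at p < 0.05 are laid out
#' with one HR column per outcome; `NA` marks outcomes in which the
#' feature was never tested (e.g. removed by a cohort-specific prevalence
#' filter).
#'
#' @param results_list named list of association result data.frames, one
#'   per outcome (names = outcomes).
#' @return data.frame with columns `feature_id`, `hr_<outcome>`,
#'   `p_<outcome>` per outcome and `n_outcomes_significant` (count of
#'   outcomes with p < 0.05); zero rows when nothing reaches p < 0.05.
#' @export
cross_outcome_summary <- function(results_list) {
  stopifnot(is.list(results_list), !is.null(names(results_list)))
  hits <- unique(unlist(lapply(results_list, function(r)
    r$feature_id[!is.na(r$p) & r$p < 0.05])))
  ocs <- names(results_list)
  out <- data.frame(feature_id = sort(hits), stringsAsFactors = FALSE)
  for (oc in ocs) {
    r <- results_list[[oc]]
    out[[paste0("hr_", oc)]] <- r$hr[match(out$feature_id, r$feature_id)]
    out[[paste0("p_", oc)]] <- r$p[match(out$feature_id, r$feature_id)]
  }
  sig <- vapply(ocs, function(oc) {
    pv <- out[[paste0("p_", oc)]]
    !is.na(pv) & pv < 0.05
  }, logical(nrow(out)))
  out$n_outcomes_significant <- if (nrow(out)) rowSums(matrix(sig, nrow = nrow(out))) else integer(0)
  out
}

#' Run the full analysis pipeline on a cohort
#'
#' End-to-end orchestration: total-reads filter, representative
#' rarefaction, alpha diversity, UniFrac + PERMANOVA against the binary
#' activity summaries, co-occurrence modules on the unrarefied table,
#' and ASV-, module- and alpha-level PWP associations for all three
#' outcomes, with BH FDR within each (level x outcome) family.
#'
#' @param table unrarefied [asv_table()].
#' @param tree rooted `phylo` covering the table's ASVs.
#' @param timelines list of [subject_timeline()].
#' @param config a [run_config()].
#' @param pathways optional samples-by-pathways matrix; fitted for
#'   outcomes where some module reaches `fdr_alpha`.
#' @return list with `rarefied`, `alpha`, `permanova` (per metric x
#'   outcome), `modules`, `associations` (named per level), `summary`
#'   (ASV cross-outcome table), `provenance` (feature counts per stage).
#' @export
run_pipeline <- function(table, tree, timelines, config = run_config(),
                         pathways = NULL) {
  filt <- filter_min_fraction(table, config$min_fraction)
  rare <- representative_rarefaction(filt, n_draws = config$rarefy_draws,
                                     seed = child_seed(config$seed, 11))
  alpha <- alpha_diversity(rare, tree)

  flags <- t(vapply(timelines, activity_flags, logical(3)))
  rownames(flags) <- vapply(timelines, function(t) t$subject_id, character(1))
  covs <- data.frame(
    sex = vapply(timelines, function(t) t$sex, numeric(1)),
    age = vapply(timelines, function(t) t$age_at_stool, numeric(1)),
    dmt = vapply(timelines, function(t)
      dmt_overlap(t$dmt_intervals, 0, 0), numeric(1)),
    row.names = rownames(flags))
  perma <- list()
  for (w in c(FALSE, TRUE)) {
    D <- unifrac_matrix(rare, tree, weighted = w)
    for (oc in colnames(flags)) {
      y <- flags[rownames(D), oc]
      key <- paste0(if (w) "weighted" else "unweighted", "_", oc)
      perma[[key]] <- if (length(unique(y)) < 2) NULL else
        permanova(D, covs[rownames(D), ], y, n_perm = config$n_perm,
                  seed = child_seed(config$seed, 12))
    }
  }

  modules <- cooccurrence_modules(filt,
                                  min_prevalence = config$prevalence_network,
                                  beta = config$soft_power,
                                  r_threshold = config$merge_r)

  assoc <- list()
  for (oc in c("relapse", "gad", "t2")) {
    assoc[[paste0("asv_", oc)]] <-
      run_asv_association(rare, timelines, oc, config)
    if (!is.null(modules$eigengenes))
      assoc[[paste0("module_", oc)]] <-
        run_module_association(modules$eigengenes, timelines, oc, config)
    assoc[[paste0("alpha_", oc)]] <-
      run_alpha_association(alpha, timelines, oc, config)
  }
  if (!is.null(pathways) && !is.null(modules$eigengenes)) {
    sig_oc <- Filter(function(oc) {
      r <- assoc[[paste0("module_", oc)]]
      any(!is.na(r$q) & r$q < config$fdr_alpha)
    }, c("relapse", "gad", "t2"))
    if (length(sig_oc))
      assoc$pathway <- run_pathway_association(pathways, timelines,
                                               sig_oc, config)
  }
  summary_tab <- cross_outcome_summary(list(
    relapse = assoc$asv_relapse, gad = assoc$asv_gad, t2 = assoc$asv_t2))

  list(rarefied = rare, alpha = alpha, permanova = perma, modules = modules,
       associations = assoc, summary = summary_tab,
       provenance = list(
         n_asvs_input = ncol(counts_of(table)),
         n_asvs_after_fraction_filter = ncol(counts_of(filt)),
         n_modules = sum(unique(modules$assignment) > 0),
         seed = config$seed))
}
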