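#' Read / write ASV count tables
#'
#' Counts travel as TSV with samples in rows: first column `sample_id`,
#' remaining columns ASV ids.  BIOM files are accepted on read when the
#' `biomformat` package is available.
#'
#' @param table an [asv_table()].
#' @param path file path (`.tsv` or, for reading, `.biom`).
#' @return `read_counts()` returns an [asv_table()];
#'   `write_counts()` returns `path` invisibly.
#' @name counts_io
NULL

#' @rdname counts_io
#' @export
write_counts <- function(table, path) {
  counts <- counts_of(table)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname counts_io
#' @export
read_counts <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_invalid("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))   # biom stores taxa x samples
    return(asv_table(m))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  asv_table(m)
}

#' Read / write phylogenies
#'
#' Thin newick wrappers around `ape`.
#'
#' @param tree a `phylo`.
#' @param path newick file path.
#' @name tree_io
NULL

#' @rdname tree_io
#' @export
write_tree_file <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' @rdname tree_io
#' @export
read_tree_file <- function(path) ape::read.tree(path)

#' Write subject timelines to four CSV files
#'
#' Emits `subjects.csv` (subject_id, sex, age_at_stool, last_visit_day),
#' `relapses.csv` (subject_id, day), `mri.csv` (subject_id, day,
#' gad_event, t2_event, is_baseline) and `dmt.csv` (subject_id,
#' start_day, end_day) into `dir`.
#'
#' @param timelines list of [subject_timeline()] objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_timelines <- function(timelines, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  subj <- do.call(rbind, lapply(timelines, function(t)
    data.frame(subject_id = t$subject_id, sex = t$sex,
               age_at_stool = t$age_at_stool,
               last_visit_day = t$last_visit_day)))
  rel <- do.call(rbind, lapply(timelines, function(t)
    if (length(t$relapse_days))
      data.frame(subject_id = t$subject_id, day = t$relapse_days)))
  mri <- do.call(rbind, lapply(timelines, function(t)
    if (nrow(t$mri_scans)) cbind(subject_id = t$subject_id, t$mri_scans)))
  dmt <- do.call(rbind, lapply(timelines, function(t)
    if (nrow(t$dmt_intervals)) cbind(subject_id = t$subject_id, t$dmt_intervals)))
  utils::write.csv(subj, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(rel %||% data.frame(subject_id = character(0), day = numeric(0)),
                   file.path(dir, "relapses.csv"), row.names = FALSE)
  utils::write.csv(mri %||% cbind(subject_id = character(0), empty_mri()),
                   file.path(dir, "mri.csv"), row.names = FALSE)
  utils::write.csv(dmt %||% cbind(subject_id = character(0), empty_dmt()),
                   file.path(dir, "dmt.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read subject timelines from the four-CSV layout
#'
#' @param dir directory holding `subjects.csv`, `relapses.csv`, `mri.csv`,
#'   `dmt.csv` (see [write_timelines()]).
#' @return list of [subject_timeline()] objects, in `subjects.csv` order.
#' @export
read_timelines <- function(dir) {
  subj <- utils::read.csv(file.path(dir, "subjects.csv"))
  rel <- utils::read.csv(file.path(dir, "relapses.csv"))
  mri <- utils::read.csv(file.path(dir, "mri.csv"))
  dmt <- utils::read.csv(file.path(dir, "dmt.csv"))
  lapply(seq_len(nrow(subj)), function(i) {
    id <- subj$subject_id[i]
    subject_timeline(
      id, subj$sex[i], subj$age_at_stool[i],
      relapse_days = rel$day[rel$subject_id == id],
      last_visit_day = subj$last_visit_day[i],
      mri_scans = mri[mri$subject_id == id,
                      c("day", "gad_event", "t2_event", "is_baseline"),
                      drop = FALSE],
      dmt_intervals = dmt[dmt$subject_id == id,
                          c("start_day", "end_day"), drop = FALSE])
  })
}

#' Write / read simulation ground truth as JSON
#'
#' Stores the planted log hazard ratios, the ASV -> module map and the
#' per-subject planted feature values.
#'
#' @param truth the `truth` element of [simulate_counts()] /
#'   [simulate_cohort()].
#' @param path JSON path.
#' @name truth_io
NULL

#' @rdname truth_io
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    log_hr = as.list(truth$log_hr),
    modules = as.list(truth$modules),
    features = if (ncol(truth$features)) {
      stats::setNames(lapply(seq_len(ncol(truth$features)),
                             function(j) unname(truth$features[, j])),
                      colnames(truth$features))
    } else stats::setNames(list(), character(0)),
    subjects = rownames(truth$features)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname truth_io
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- if (length(obj$features)) {
    m <- do.call(cbind, obj$features)
    rownames(m) <- obj$subjects
    m
  } else matrix(numeric(0), length(obj$subjects), 0,
                dimnames = list(obj$subjects, NULL))
  list(log_hr = unlist(obj$log_hr) %||% numeric(0),
       modules = unlist(obj$modules),
       features = feats)
}

#' Write an association result table as TSV
#'
#' @param results data.frame of association results (see
#'   [run_asv_association()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Machine-readable provenance record for a run
#'
#' Serializes the run configuration, the seeds in use and arbitrary
#' counter values (e.g. features surviving each filter) as JSON, together
#' with an md5 digest of the configuration.
#'
#' @param config a [run_config()] (or any list).
#' @param counts named list/vector of counters to record.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(config, counts = list(), path) {
  config <- unclass(config)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  jsonlite::write_json(
    list(config = config,
         config_md5 = unname(tools::md5sum(tmp)),
         counts = counts,
         r_version = as.character(getRversion())),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
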