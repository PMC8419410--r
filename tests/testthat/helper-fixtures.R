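# shared fixtures, built in code

# small count table with controllable structure
toy_table <- function(n_samples = 10, n_asvs = 6, seed = 1, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_asvs, lambda), n_samples, n_asvs,
              dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                              sprintf("ASV%04d", seq_len(n_asvs))))
  m[rowSums(m) == 0, 1] <- 1L
  asv_table(m)
}

# the 4-row instance whose partial-likelihood score equation solves in
# closed form: u/(u+2) = 1/(u+1) with u = exp(beta), so beta = log(2)/2
four_row_intervals <- function() {
  data.frame(subject = c("a", "b", "c", "d"), stratum = 1,
             start = 0, stop = c(1, 3, 2, 4), event = c(1, 0, 1, 0),
             x = c(1, 1, 0, 0))
}

# random small counting-process instance for oracle comparisons
random_intervals <- function(n = 8, seed = 1, p = 2) {
  set.seed(seed)
  d <- data.frame(subject = sample(letters[1:4], n, TRUE),
                  stratum = sample(1:2, n, TRUE),
                  stop = round(runif(n, 2, 20)),
                  event = rbinom(n, 1, 0.6))
  d$start <- pmax(0, d$stop - sample(1:10, n, TRUE))
  d$x1 <- rnorm(n)
  if (p >= 2) d$x2 <- rbinom(n, 1, 0.5)
  d
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  ex <- si * sj / choose(n, 2)
  (sij - ex) / ((si + sj) / 2 - ex)
}

# timeline builders
simple_timeline <- function(id = "s1", relapses = c(100, 250), L = 400,
                            sex = 1, age = 15,
                            mri = NULL, dmt = NULL) {
  subject_timeline(id, sex, age, relapse_days = relapses,
                   last_visit_day = L,
                   mri_scans = mri %||% recurmicro:::empty_mri(),
                   dmt_intervals = dmt %||% recurmicro:::empty_dmt())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
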