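#' Fit a stratified Prentice-Williams-Petersen Cox model
#'
#' Maximizes the stratified Cox partial likelihood over counting-process
#' risk intervals, with risk sets formed within each event-order stratum
#' from the `(start, stop]` entry/exit times.  This is the conditional
#' recurrent-event model of Prentice, Williams and Petersen: a subject is
#' at risk for the k-th event only after experiencing the (k-1)-th, and the
#' baseline hazard is stratum-specific.  Total-time and gap-time variants
#' differ only in how the interval table was built (see
#' [build_relapse_intervals()] and [build_mri_intervals()]).
#'
#' Newton-Raphson with step-halving; a step is accepted only if it does not
#' decrease the log partial likelihood.  Monotone-likelihood divergence
#' (|beta| running away, typical for sparse binary features) is reported via
#' `converged = FALSE` rather than an error.
#'
#' @param intervals a risk-interval table: data.frame with columns
#'   `subject`, `stratum`, `start`, `stop`, `event` plus the covariate
#'   columns named in `covariates`.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"` tie handling.
#' @param tol convergence tolerance on the max-norm of the score vector.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `pwp_cox` with elements `coef`, `var`
#'   (model-based, inverse information), `loglik` (initial, final),
#'   `iterations`, `converged`, `n`, `n_events`, `score_resid` (n x p matrix
#'   of per-row score residuals), `schoenfeld` (per-event residuals used by
#'   [ph_test()]), `info` (observed information at the estimate).
#' @seealso [robust_variance()], [ph_test()], [hazard_ratio()]
#' @export
fit_pwp_cox <- function(intervals, covariates, ties = c("efron", "breslow"),
                        tol = 1e-9, max_iter = 50) {
  ties <- match.arg(ties)
  dat <- validate_intervals(intervals, covariates)
  X <- dat$X
  p <- ncol(X)
  n <- nrow(X)
  if (sum(dat$event) < 1) stop_invalid("no events in the interval table")

  # collinearity / constant-covariate check: the partial likelihood only
  # identifies within-risk-set contrasts, so center before the rank test
  Xc <- sweep(X, 2L, colMeans(X))
  if (qr(Xc)$rank < p)
    stop_invalid("covariates are collinear (or constant) within the data")

  beta <- rep(0, p)
  ll <- pwp_eval(beta, dat, ties)
  loglik0 <- ll$loglik
  converged <- FALSE
  iter <- 0L
  diverged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(ll$grad)) < tol) { converged <- TRUE; break }
    step <- solve(ll$hess, ll$grad)
    new_beta <- beta + step
    new_ll <- pwp_eval(new_beta, dat, ties)
    # accept any step that does not decrease the likelihood beyond float
    # noise; otherwise halve
    ll_floor <- ll$loglik - 1e-10 * (abs(ll$loglik) + 1)
    halvings <- 0L
    while ((!is.finite(new_ll$loglik) || new_ll$loglik < ll_floor) &&
           halvings < 20L) {
      halvings <- halvings + 1L
      new_beta <- beta + step / 2^halvings
      new_ll <- pwp_eval(new_beta, dat, ties)
    }
    beta <- new_beta
    ll <- new_ll
    if (max(abs(beta)) > 15) { diverged <- TRUE; break }
  }
  if (!converged && max(abs(ll$grad)) < tol) converged <- TRUE
  if (diverged) converged <- FALSE

  info <- ll$hess
  vmat <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  resid <- pwp_residuals(beta, dat, ties)
  names(beta) <- covariates
  dimnames(vmat) <- list(covariates, covariates)
  structure(list(
    coef = beta,
    var = vmat,
    info = info,
    loglik = c(loglik0, ll$loglik),
    iterations = iter,
    converged = converged,
    diverged = diverged,
    n = n,
    n_events = sum(dat$event),
    score_resid = resid$score,
    schoenfeld = resid$schoenfeld,
    subject = dat$subject,
    covariates = covariates,
    ties = ties
  ), class = "pwp_cox")
}

#' @export
print.pwp_cox <- function(x, ...) {
  cat("Stratified PWP Cox fit (", x$ties, " ties)\n", sep = "")
  cat("  n rows:", x$n, " events:", x$n_events,
      " iterations:", x$iterations,
      " converged:", x$converged, "\n")
  se <- sqrt(diag(x$var))
  print(data.frame(coef = x$coef, `exp(coef)` = exp(x$coef), se = se,
                   check.names = FALSE))
  invisible(x)
}

# ---- internals --------------------------------------------------------------

validate_intervals <- function(intervals, covariates) {
  req <- c("subject", "stratum", "start", "stop", "event")
  miss <- setdiff(c(req, covariates), names(intervals))
  if (length(miss))
    stop_invalid("interval table is missing columns: ", paste(miss, collapse = ", "))
  if (any(intervals$stop <= intervals$start))
    stop_invalid("all intervals must satisfy start < stop")
  if (!all(intervals$event %in% c(0, 1)))
    stop_invalid("'event' must be 0/1")
  X <- as.matrix(intervals[covariates])
  if (!is.numeric(X)) stop_invalid("covariates must be numeric")
  storage.mode(X) <- "double"
  list(
    X = X,
    start = as.numeric(intervals$start),
    stop = as.numeric(intervals$stop),
    event = as.integer(intervals$event),
    stratum = intervals$stratum,
    subject = as.character(intervals$subject)
  )
}

# log partial likelihood, score and observed information
pwp_eval <- function(beta, dat, ties) {
  X <- dat$X
  p <- ncol(X)
  eta <- drop(X %*% beta)
  r <- exp(eta)
  ll <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  for (s in unique(dat$stratum)) {
    in_s <- which(dat$stratum == s)
    ev <- in_s[dat$event[in_s] == 1L]
    if (!length(ev)) next
    for (t in sort(unique(dat$stop[ev]))) {
      at <- in_s[dat$start[in_s] < t & dat$stop[in_s] >= t]
      D <- at[dat$stop[at] == t & dat$event[at] == 1L]
      d <- length(D)
      rr <- r[at]
      Xr <- X[at, , drop = FALSE]
      S0 <- sum(rr)
      S1 <- colSums(Xr * rr)
      S2 <- crossprod(Xr, Xr * rr)
      ll <- ll + sum(eta[D])
      grad <- grad + colSums(X[D, , drop = FALSE])
      if (ties == "breslow" || d == 1L) {
        xbar <- S1 / S0
        ll <- ll - d * log(S0)
        grad <- grad - d * xbar
        hess <- hess + d * (S2 / S0 - tcrossprod(xbar))
      } else {
        rD <- r[D]
        XD <- X[D, , drop = FALSE]
        S0D <- sum(rD)
        S1D <- colSums(XD * rD)
        S2D <- crossprod(XD, XD * rD)
        for (j in seq_len(d) - 1L) {
          f <- j / d
          S0j <- S0 - f * S0D
          S1j <- S1 - f * S1D
          xbar <- S1j / S0j
          ll <- ll - log(S0j)
          grad <- grad - xbar
          hess <- hess + (S2 - f * S2D) / S0j - tcrossprod(xbar)
        }
      }
    }
  }
  list(loglik = ll, grad = grad, hess = hess)
}

# per-row score residuals (martingale decomposition of the score) and
# per-event Schoenfeld residuals, both with Efron tie correction
pwp_residuals <- function(beta, dat, ties) {
  X <- dat$X
  p <- ncol(X)
  n <- nrow(X)
  eta <- drop(X %*% beta)
  r <- exp(eta)
  U <- matrix(0, n, p, dimnames = list(NULL, colnames(X)))
  sch_time <- numeric(0)
  sch_stratum <- character(0)
  sch <- NULL
  sch_v <- list()
  for (s in unique(dat$stratum)) {
    in_s <- which(dat$stratum == s)
    ev <- in_s[dat$event[in_s] == 1L]
    if (!length(ev)) next
    for (t in sort(unique(dat$stop[ev]))) {
      at <- in_s[dat$start[in_s] < t & dat$stop[in_s] >= t]
      D <- at[dat$stop[at] == t & dat$event[at] == 1L]
      d <- length(D)
      rr <- r[at]
      Xr <- X[at, , drop = FALSE]
      S0 <- sum(rr)
      S1 <- colSums(Xr * rr)
      is_death <- at %in% D
      if (ties == "breslow" || d == 1L) {
        xbar_steps <- matrix(S1 / S0, 1L, p)
        S0j <- rep(S0, d)
        frac_death <- matrix(0, length(at), d)  # share removed per sub-step
      } else {
        rD <- r[D]
        XD <- X[D, , drop = FALSE]
        S0D <- sum(rD)
        S1D <- colSums(XD * rD)
        f <- (seq_len(d) - 1L) / d
        S0j <- S0 - f * S0D
        xbar_steps <- (matrix(S1, d, p, byrow = TRUE) -
                         outer(f, S1D)) / S0j
      }
      xbar_mean <- colMeans(xbar_steps)
      # death contributions
      U[D, ] <- U[D, , drop = FALSE] +
        sweep(X[D, , drop = FALSE], 2L, xbar_mean)
      sch_rows <- sweep(X[D, , drop = FALSE], 2L, xbar_mean)
      sch <- rbind(sch, sch_rows)
      sch_time <- c(sch_time, rep(t, d))
      sch_stratum <- c(sch_stratum, rep(as.character(s), d))
      # per-death conditional covariance of X in the risk set (averaged
      # over tie sub-steps), used by the proportional-hazards score test
      S2 <- crossprod(Xr, Xr * rr)
      Vt <- matrix(0, p, p)
      if (ties == "breslow" || d == 1L) {
        Vt <- S2 / S0 - tcrossprod(xbar_steps[1L, ])
      } else {
        S2D <- crossprod(X[D, , drop = FALSE], X[D, , drop = FALSE] * r[D])
        for (jj in seq_len(nrow(xbar_steps))) {
          fj <- (jj - 1L) / d
          Vt <- Vt + ((S2 - fj * S2D) / S0j[jj] -
                        tcrossprod(xbar_steps[jj, ])) / d
        }
      }
      sch_v <- c(sch_v, rep(list(Vt), d))
      # at-risk (compensator) contributions per sub-step
      nsub <- if (ties == "breslow") d else nrow(xbar_steps)
      for (j in seq_len(nsub)) {
        if (ties == "breslow" || d == 1L) {
          a <- rr
          S0_here <- S0
          xbar_here <- xbar_steps[1L, ]
        } else {
          fj <- (j - 1L) / d
          a <- rr * ifelse(is_death, 1 - fj, 1)
          S0_here <- S0j[j]
          xbar_here <- xbar_steps[j, ]
        }
        U[at, ] <- U[at, , drop = FALSE] -
          (a / S0_here) * sweep(Xr, 2L, xbar_here)
      }
    }
  }
  list(score = U,
       schoenfeld = list(time = sch_time, stratum = sch_stratum,
                         resid = sch, v = sch_v))
}

#' Cluster-robust (sandwich) covariance for a PWP Cox fit
#'
#' Computes the sandwich estimator
#' \eqn{I^{-1} (\sum_g U_g U_g^\top) I^{-1}} where \eqn{U_g} is the sum of
#' per-row score residuals over cluster \eqn{g} (normally the subject), and
#' \eqn{I} the observed information at the estimate.  Aggregating within
#' subject absorbs the dependence between a subject's recurrent events.
#'
#' @param fit a converged [fit_pwp_cox()] object.
#' @param cluster cluster ids, one per interval row; defaults to the
#'   table's `subject` column captured by the fit.
#' @return symmetric positive semi-definite covariance matrix.
#' @export
robust_variance <- function(fit, cluster = fit$subject) {
  stopifnot(inherits(fit, "pwp_cox"))
  if (!fit$converged)
    stop_invalid("robust variance requires a converged fit")
  if (length(cluster) != nrow(fit$score_resid))
    stop_invalid("'cluster' must have one value per interval row")
  Ug <- rowsum(fit$score_resid, group = as.character(cluster))
  meat <- crossprod(Ug)
  v <- fit$var %*% meat %*% fit$var
  # enforce exact symmetry against rounding
  v <- (v + t(v)) / 2
  dimnames(v) <- dimnames(fit$var)
  v
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' Score test of Grambsch and Therneau: the Schoenfeld residuals at the
#' event times are correlated with a transform \eqn{g(t)} of event time;
#' under proportional hazards the expected slope is zero.  The statistic is
#' the score test of the slope in \eqn{\beta(t) = \beta + \theta (g(t) -
#' \bar g)}, with variance built from the per-event risk-set covariances
#' \eqn{V(t_k)} and a Schur-complement correction for the estimated main
#' effects: per covariate \eqn{T_j = U_j^2 / Var(U)_{jj}} on 1 df, and
#' globally \eqn{U' Var(U)^{-1} U} on p df.
#'
#' @param fit a converged [fit_pwp_cox()] object.
#' @param intervals the interval table the fit used (kept in the signature
#'   for API symmetry; event times are taken from the fit's residuals).
#' @param transform `"km"` (rank-based Kaplan-Meier-style survival
#'   transform of event time, the default of the standard diagnostic and
#'   well calibrated under heavy-tailed event times) or `"identity"` (raw
#'   event time).
#' @return data.frame with rows per covariate plus `GLOBAL`: columns
#'   `chisq`, `df`, `p`.
#' @export
ph_test <- function(fit, intervals = NULL, transform = c("km", "identity")) {
  stopifnot(inherits(fit, "pwp_cox"))
  transform <- match.arg(transform)
  if (!fit$converged) stop_invalid("ph_test requires a converged fit")
  sch <- fit$schoenfeld
  d <- length(sch$time)
  if (d < 2) stop_invalid("ph_test requires at least 2 events")
  g <- switch(transform,
    identity = sch$time,
    km = {
      # survival-fraction transform: rank-based KM-style decreasing scale
      tt <- sch$time
      1 - (rank(tt, ties.method = "average") - 0.5) / length(tt)
    })
  gc_ <- g - mean(g)
  s <- sch$resid
  p <- ncol(s)
  U <- drop(crossprod(gc_, s))            # score for the interaction slope
  # information blocks with per-event risk-set covariances V(t_k), with the
  # Schur-complement correction for the estimated main effects
  M <- Reduce(`+`, sch$v)
  Igg <- Reduce(`+`, Map(function(v, gk) gk^2 * v, sch$v, gc_))
  Igb <- Reduce(`+`, Map(function(v, gk) gk * v, sch$v, gc_))
  VarU <- Igg - Igb %*% solve(M, Igb)
  VarU <- (VarU + t(VarU)) / 2
  chisq_each <- U^2 / diag(VarU)
  p_each <- stats::pchisq(chisq_each, df = 1, lower.tail = FALSE)
  chisq_glob <- drop(t(U) %*% solve(VarU, U))
  p_glob <- stats::pchisq(chisq_glob, df = p, lower.tail = FALSE)
  out <- data.frame(
    covariate = c(fit$covariates, "GLOBAL"),
    chisq = c(chisq_each, chisq_glob),
    df = c(rep(1L, length(chisq_each)), ncol(s)),
    p = c(p_each, p_glob),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Refit with a feature-by-time interaction
#'
#' Adds `feature * time` as an extra (time-varying) covariate and refits;
#' used as the fallback when the proportional-hazards diagnostic fails for
#' a feature.  Each interval is first episode-split at the event times of
#' its stratum, so the product `feature * stop` evaluates the interaction
#' at every risk set it enters rather than conditioning on the row's own
#' future follow-up.  The caller keeps the main-effect model when the
#' interaction is not significant (p >= 0.05).
#'
#' @param intervals interval table with covariate columns.
#' @param feature name of the feature covariate column.
#' @param covariates covariates of the base model (must include `feature`).
#' @param ... passed to [fit_pwp_cox()].
#' @return list with the interaction `fit`, the interaction coefficient
#'   name, and `interaction_p` (robust Wald, clustered on subject).
#' @export
add_time_interaction <- function(intervals, feature,
                                 covariates = feature, ...) {
  if (!feature %in% names(intervals))
    stop_invalid("feature column '", feature, "' not in interval table")
  int_name <- paste0(feature, "_x_time")
  split <- episode_split(intervals)
  split[[int_name]] <- split[[feature]] * split$stop
  fit <- fit_pwp_cox(split, c(union(covariates, feature), int_name), ...)
  rv <- robust_variance(fit)
  se <- sqrt(diag(rv))[int_name]
  z <- fit$coef[int_name] / se
  list(fit = fit, interaction = int_name,
       interaction_p = unname(2 * stats::pnorm(-abs(z))))
}

# split every interval at the distinct event times of its stratum, so that
# row-level products with `stop` behave as true time-varying covariates
episode_split <- function(intervals) {
  pieces <- lapply(seq_len(nrow(intervals)), function(i) {
    row <- intervals[i, , drop = FALSE]
    ev_times <- sort(unique(intervals$stop[
      intervals$stratum == row$stratum & intervals$event == 1]))
    cuts <- ev_times[ev_times > row$start & ev_times < row$stop]
    bounds <- c(row$start, cuts, row$stop)
    out <- row[rep(1L, length(bounds) - 1L), , drop = FALSE]
    out$start <- bounds[-length(bounds)]
    out$stop <- bounds[-1L]
    out$event <- c(rep(0L, nrow(out) - 1L), row$event)
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "outcome_type") <- attr(intervals, "outcome_type")
  out
}

#' Hazard ratio with robust confidence interval
#'
#' @param fit a converged [fit_pwp_cox()] object.
#' @param covariate covariate name.
#' @param scale report the HR per `scale` units of the covariate (e.g. 0.1
#'   for module eigengenes and evenness).
#' @param robust_var optional precomputed [robust_variance()] matrix; if
#'   missing, computed with subject clusters.
#' @param conf_level confidence level (normal quantile 1.959964 at 0.95).
#' @return list with `log_hr` (unscaled coefficient), `hr`, `ci_low`,
#'   `ci_high`, `robust_se` (unscaled), `p` (robust Wald).
#' @export
hazard_ratio <- function(fit, covariate, scale = 1.0, robust_var = NULL,
                         conf_level = 0.95) {
  stopifnot(inherits(fit, "pwp_cox"))
  if (is.null(robust_var)) robust_var <- robust_variance(fit)
  b <- fit$coef[covariate]
  se <- sqrt(diag(robust_var))[covariate]
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- b / se
  list(
    log_hr = unname(b),
    hr = unname(exp(scale * b)),
    ci_low = unname(exp(scale * (b - zq * se))),
    ci_high = unname(exp(scale * (b + zq * se))),
    robust_se = unname(se),
    p = unname(2 * stats::pnorm(-abs(z)))
  )
}
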