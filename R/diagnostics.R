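# Model diagnostics: goodness-of-fit tables, visual predictive check,
# nonparametric subject-level bootstrap.

#' Goodness-of-fit table
#'
#' Per-observation population predictions (`PRED`, at eta = 0),
#' individual predictions (`IPRED`, at the empirical Bayes etas),
#' individual weighted residuals `IWRES = (log DV - log IPRED) / sigma`,
#' and conditional weighted residuals `CWRES` from the
#' first-order-conditional linearization around the EBEs: per subject
#' the linearized residual vector is decorrelated by the inverse matrix
#' square root of `sigma2 I + G Omega G'`.
#'
#' @param dataset a `pk_dataset`.
#' @param fit a `neocef_fit` from [fit_population()].
#' @return data frame with columns `subject_id`, `time`, `dv`, `pred`,
#'   `ipred`, `iwres`, `cwres` (one row per observation).
#' @export
gof_table <- function(dataset, fit) {
  flat <- .flatten_dataset(dataset)
  params <- fit$params
  d <- .foce_ofv(flat, params, fit$terms,
                 if (length(fit$betas)) fit$betas else NULL,
                 detail = TRUE)
  if (is.null(d)) stop("model predictions are invalid", call. = FALSE)
  pred_log <- .logconc(flat, d$base$cl, d$base$v)
  if (any(!is.finite(pred_log)) || any(!is.finite(d$m)))
    stop("zero or non-finite prediction in goodness-of-fit table",
         call. = FALSE)
  sig <- sqrt(params$sigma2)
  iwres <- (flat$ldv - d$m) / sig
  omega <- diag(c(max(params$omega2_cl, 0), max(params$omega2_v, 0)))
  cwres <- numeric(flat$n_obs)
  for (i in seq_len(flat$n_subj)) {
    rows <- which(flat$obs_subj == i)
    if (!length(rows)) next
    G <- cbind(d$J1[rows], d$J2[rows])
    C <- params$sigma2 * diag(length(rows)) + G %*% omega %*% t(G)
    e <- d$r[rows] + G %*% d$eta[i, ]
    eg <- eigen(C, symmetric = TRUE)
    Cmhalf <- eg$vectors %*% diag(1 / sqrt(eg$values),
                                  length(rows)) %*% t(eg$vectors)
    cwres[rows] <- Cmhalf %*% e
  }
  data.frame(subject_id = flat$ids[flat$obs_subj],
             time = flat$obs_time,
             dv = exp(flat$ldv),
             pred = exp(pred_log),
             ipred = exp(d$m),
             iwres = iwres,
             cwres = cwres)
}

# Assign observation times to bins given as a list of c(lo, hi) windows;
# times outside every window go to the nearest window midpoint. Bins
# that catch no observation are merged into their nearest non-empty
# neighbour with a warning.
.assign_bins <- function(time, windows) {
  mids <- vapply(windows, mean, numeric(1))
  bin <- integer(length(time))
  for (w in seq_along(windows)) {
    inside <- time >= windows[[w]][1] & time <= windows[[w]][2]
    bin[inside] <- w
  }
  out <- bin == 0L
  if (any(out))
    bin[out] <- vapply(time[out],
                       function(t) which.min(abs(t - mids)), integer(1))
  empty <- setdiff(seq_along(windows), unique(bin))
  if (length(empty)) {
    warning("empty VPC bins merged with nearest neighbour",
            call. = FALSE)
    keep <- sort(unique(bin))
    bin <- vapply(bin, function(b) which.min(abs(mids[keep] - mids[b])),
                  integer(1))
    mids <- mids[keep]
  }
  list(bin = bin, mids = mids)
}

#' Default VPC bins: the sparse-design sampling windows
#' @return list of time windows (h post-dose).
#' @export
design_windows <- function() list(c(0, 0.5), c(2, 3), c(4, 6))

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset at its own design (same
#' subjects, covariates, doses and sampling times; fresh eta and
#' residual draws), and compares observed 5/50/95% concentration
#' quantiles per time bin with the simulated quantile distribution.
#' Coverage is the percentage of observations lying inside their own
#' simulated 90% prediction interval (per observation across
#' replicates).
#'
#' @param dataset a `pk_dataset`.
#' @param params a [pop_params()] object (typically fitted estimates).
#' @param n_sim number of simulation replicates, >= 1.
#' @param seed integer seed; results are reproducible given
#'   `(seed, n_sim)`.
#' @param bins list of time windows, default [design_windows()].
#' @param terms,betas optional covariate terms as in [foce_objective()].
#' @return object of class `neocef_vpc`: `observed` and `simulated`
#'   binned quantile tables, `coverage` (%), `n_sim`, `seed`, and the
#'   per-observation simulation matrix dimensions.
#' @export
vpc <- function(dataset, params, n_sim = 1000, seed = 1,
                bins = design_windows(), terms = NULL, betas = NULL) {
  stopifnot(n_sim >= 1)
  flat <- .flatten_dataset(dataset)
  base <- .base_cl_v(flat, params, terms, betas)
  ba <- .assign_bins(flat$obs_time, bins)
  qs <- c(0.05, 0.5, 0.95)
  set.seed(seed)
  sims <- matrix(NA_real_, flat$n_obs, n_sim)
  for (s in seq_len(n_sim)) {
    eta1 <- stats::rnorm(flat$n_subj, 0, sqrt(params$omega2_cl))
    eta2 <- stats::rnorm(flat$n_subj, 0, sqrt(params$omega2_v))
    lm <- .logconc(flat, base$cl * exp(eta1), base$v * exp(eta2))
    sims[, s] <- exp(lm + stats::rnorm(flat$n_obs, 0,
                                       sqrt(params$sigma2)))
  }
  obs_q <- do.call(rbind, lapply(sort(unique(ba$bin)), function(b) {
    data.frame(bin = b, mid = ba$mids[b],
               q = qs,
               conc = as.numeric(stats::quantile(exp(flat$ldv[ba$bin == b]),
                                                 qs)))
  }))
  sim_q <- do.call(rbind, lapply(sort(unique(ba$bin)), function(b) {
    rows <- ba$bin == b
    per_sim <- apply(sims[rows, , drop = FALSE], 2, stats::quantile, qs)
    band <- apply(per_sim, 1, stats::quantile, c(0.025, 0.5, 0.975))
    data.frame(bin = b, mid = ba$mids[b], q = qs,
               lo = band[1, ], med = band[2, ], hi = band[3, ])
  }))
  pi_lo <- apply(sims, 1, stats::quantile, 0.05)
  pi_hi <- apply(sims, 1, stats::quantile, 0.95)
  dv <- exp(flat$ldv)
  coverage <- 100 * mean(dv >= pi_lo & dv <= pi_hi)
  structure(list(observed = obs_q, simulated = sim_q,
                 coverage = coverage, n_sim = n_sim, seed = seed,
                 n_obs = flat$n_obs),
            class = "neocef_vpc")
}

#' @export
print.neocef_vpc <- function(x, ...) {
  cat("<neocef_vpc> ", x$n_sim, " simulations, ", x$n_obs,
      " observations\n", sep = "")
  cat(sprintf("  coverage of 90%% prediction interval: %.1f%%\n",
              x$coverage))
  invisible(x)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement to the original subject count,
#' refits each replicate, and reports per-parameter medians, percentile
#' 95% confidence intervals, and relative standard errors over the
#' converged replicates, together with the convergence fraction. A
#' replicate counts as converged when the optimizer succeeded and no
#' variance sat on the boundary.
#'
#' @param dataset a `pk_dataset`.
#' @param init starting [pop_params()] for every refit (typically the
#'   original estimates).
#' @param n_replicates number of bootstrap resamples, >= 1.
#' @param seed integer seed.
#' @param terms optional covariate terms (refitted in each replicate).
#' @param control optimizer control, see [fit_population()].
#' @return object of class `neocef_boot`: `summary` data frame
#'   (parameter, median, lower, upper, rse %), `estimates` matrix over
#'   converged replicates, `convergence_fraction` (%), `n_replicates`,
#'   `seed`.
#' @export
bootstrap_fit <- function(dataset, init, n_replicates = 1000, seed = 1,
                          terms = NULL, control = list()) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  ns <- length(dataset$subjects)
  res <- matrix(NA_real_, n_replicates, 5,
                dimnames = list(NULL, c("tvcl", "tvv", "omega2_cl",
                                        "omega2_v", "sigma2")))
  ok <- logical(n_replicates)
  for (b in seq_len(n_replicates)) {
    pick <- sample.int(ns, ns, replace = TRUE)
    subs <- lapply(seq_along(pick), function(i) {
      s <- dataset$subjects[[pick[i]]]
      s$subject_id <- paste0(s$subject_id, "#", i)
      s
    })
    ds_b <- pk_dataset(subs, source = "bootstrap")
    f <- tryCatch(fit_population(ds_b, init, terms = terms,
                                 control = control),
                  error = function(e) NULL)
    if (is.null(f)) next
    res[b, ] <- c(f$params$tvcl, f$params$tvv, f$params$omega2_cl,
                  f$params$omega2_v, f$params$sigma2)
    ok[b] <- f$convergence && !f$boundary
  }
  fitted_ok <- stats::complete.cases(res)
  if (!any(fitted_ok))
    stop("all bootstrap replicates failed", call. = FALSE)
  if (!any(ok)) {
    warning("no bootstrap replicate met the convergence criterion; ",
            "summarizing all successful fits", call. = FALSE)
    ok <- fitted_ok
  }
  est <- res[ok, , drop = FALSE]
  qs <- apply(est, 2, stats::quantile, c(0.025, 0.5, 0.975))
  summary <- data.frame(parameter = colnames(res),
                        median = qs[2, ], lower = qs[1, ],
                        upper = qs[3, ],
                        rse = 100 * apply(est, 2, stats::sd) /
                          abs(apply(est, 2, stats::median)))
  rownames(summary) <- NULL
  structure(list(summary = summary, estimates = est,
                 convergence_fraction = 100 * mean(ok),
                 n_replicates = n_replicates, seed = seed),
            class = "neocef_boot")
}

#' @export
print.neocef_boot <- function(x, ...) {
  cat("<neocef_boot> ", x$n_replicates, " replicates, ",
      sprintf("%.1f%%", x$convergence_fraction), " converged\n",
      sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}
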