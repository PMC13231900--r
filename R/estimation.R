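# First-order conditional (FOCE-type) estimation for the
# one-compartment neonatal model. Observations are log-transformed so
# the exponential residual model becomes additive Gaussian; with a
# constant log-domain sigma the eta-residual interaction of FOCE-I is
# automatically exact. The per-subject conditional-mode search and the
# marginal-likelihood approximation live in compiled code
# (src/foce_core.cpp); this file owns the data flattening, the
# covariate model, the outer optimization, and reporting.

#' Coefficient of variation of a log-normal variance component
#'
#' `CV% = 100 * sqrt(exp(omega2) - 1)`, the exact coefficient of
#' variation of a log-normal random effect with log-scale variance
#' `omega2`.
#'
#' @param omega2 variance on the log scale, >= 0. Vectorized.
#' @return CV in percent.
#' @export
cv_percent <- function(omega2) {
  if (any(omega2 < 0)) stop("omega2 must be >= 0", call. = FALSE)
  100 * sqrt(exp(omega2) - 1)
}

#' Inverse of [cv_percent()]
#' @param cv coefficient of variation in percent, >= 0.
#' @return log-scale variance.
#' @export
cv_to_omega2 <- function(cv) {
  if (any(cv < 0)) stop("cv must be >= 0", call. = FALSE)
  log(1 + (cv / 100)^2)
}

#' Covariate-effect term for stepwise screening
#'
#' Continuous covariates enter as power functions normalized to the
#' dataset median, `(x / median(x))^theta`; categorical (0/1) covariates
#' enter proportionally, `1 + theta * x`.
#'
#' @param param `"cl"` or `"v"`: the parameter the covariate acts on.
#' @param cov covariate name: one of `"wt"`, `"pma"`, `"ga"`, `"pna"`,
#'   `"scr"`, `"sex"` (`sex` is the male indicator).
#' @param form `"power"` (continuous) or `"proportional"` (categorical).
#' @return a list of class `covariate_term`.
#' @export
covariate_term <- function(param = c("cl", "v"),
                           cov = c("scr", "pna", "ga", "wt", "pma", "sex"),
                           form = c("power", "proportional")) {
  structure(list(param = match.arg(param), cov = match.arg(cov),
                 form = match.arg(form),
                 label = paste0(toupper(match.arg(cov)), " on ",
                                toupper(match.arg(param)))),
            class = "covariate_term")
}

# ---- internal flattened representation ----------------------------------

# Precomputes vector forms of a dataset: observation table, the
# (observation x dose) pair expansion, per-subject covariates, and
# candidate-covariate medians. Everything downstream works off this.
.flatten_dataset <- function(dataset) {
  subs <- dataset$subjects
  ns <- length(subs)
  ids <- vapply(subs, function(s) s$subject_id, character(1))
  cov <- data.frame(
    wt = vapply(subs, function(s) s$covariates$wt, numeric(1)),
    pma = vapply(subs, function(s) s$covariates$pma, numeric(1)),
    ga = vapply(subs, function(s) s$covariates$ga, numeric(1)),
    pna = vapply(subs, function(s) s$covariates$pna, numeric(1)),
    scr = vapply(subs, function(s) s$covariates$scr, numeric(1)),
    sex = vapply(subs, function(s) as.numeric(s$covariates$sex == "male"),
                 numeric(1)))
  obs_subj <- integer(0); obs_time <- numeric(0); ldv <- numeric(0)
  p_obs <- integer(0); p_t0 <- numeric(0); p_dur <- numeric(0)
  p_rate <- numeric(0)
  for (i in seq_len(ns)) {
    o <- subs[[i]]$observations
    d <- subs[[i]]$doses
    if (!nrow(o)) next
    idx <- length(obs_subj) + seq_len(nrow(o))
    obs_subj <- c(obs_subj, rep.int(i, nrow(o)))
    obs_time <- c(obs_time, o$time)
    ldv <- c(ldv, log(o$conc))
    p_obs <- c(p_obs, rep(idx, each = nrow(d)))
    p_t0 <- c(p_t0, rep.int(d$time, nrow(o)))
    p_dur <- c(p_dur, rep.int(d$infusion_duration, nrow(o)))
    p_rate <- c(p_rate, rep.int(d$amount / d$infusion_duration, nrow(o)))
  }
  # group-boundary indices for fast cumsum aggregation: observations are
  # stored subject-by-subject and pairs observation-by-observation
  n_i <- tabulate(obs_subj, ns)
  subj_with_obs <- which(n_i > 0L)
  obs_ends <- cumsum(n_i[subj_with_obs])
  p_ends <- cumsum(tabulate(p_obs, length(obs_subj)))
  flat <- list(n_subj = ns, ids = ids, cov = cov,
               obs_subj = obs_subj, obs_time = obs_time, ldv = ldv,
               n_i = n_i, n_obs = length(obs_subj),
               subj_with_obs = subj_with_obs, obs_ends = obs_ends,
               p_ends = p_ends,
               p_obs = p_obs, p_subj = obs_subj[p_obs],
               p_time = obs_time[p_obs], p_t0 = p_t0, p_dur = p_dur,
               p_rate = p_rate,
               pair_count = diff(c(0L, p_ends)),
               cov_median = vapply(cov, stats::median, numeric(1)))
  flat
}

# Sum a per-observation vector into a per-subject vector.
.by_subj <- function(x, flat) {
  out <- numeric(flat$n_subj)
  s <- cumsum(x)[flat$obs_ends]
  out[flat$subj_with_obs] <- s - c(0, s[-length(s)])
  out
}

# Sum a per-pair vector into a per-observation vector.
.by_obs <- function(x, flat) {
  s <- cumsum(x)[flat$p_ends]
  s - c(0, s[-length(s)])
}

# log predicted concentration at per-subject (cl, v)
.logconc <- function(flat, cl, v) {
  k <- cl / v
  contrib <- .infusion_contrib(flat$p_time, flat$p_t0, flat$p_dur,
                               flat$p_rate, cl[flat$p_subj],
                               k[flat$p_subj])
  log(.by_obs(contrib, flat))
}

# Typical-value (eta = 0) CL and V per subject, including any selected
# covariate-effect terms with coefficients `betas` (same order as terms).
.base_cl_v <- function(flat, params, terms = NULL, betas = NULL) {
  cl <- params$tvcl * (flat$cov$wt / 70)^0.75 *
    maturation_fraction(flat$cov$pma, params$tm50, params$hill)
  v <- params$tvv * (flat$cov$wt / 70)
  if (length(terms)) {
    for (j in seq_along(terms)) {
      tm <- terms[[j]]
      x <- flat$cov[[tm$cov]]
      fac <- if (tm$form == "power")
        (x / flat$cov_median[[tm$cov]])^betas[j]
      else 1 + betas[j] * x
      if (tm$param == "cl") cl <- cl * fac else v <- v * fac
    }
  }
  list(cl = cl, v = v)
}

# Conditional-estimation -2 log marginal likelihood from flattened
# data. method "laplace" (default) expands around each subject's
# conditional mode with the exact analytic curvature of log C; method
# "foce" uses the classical first-order linearization, whose marginal
# covariance sigma2*I + G Omega G' is handled through its 2x2 Woodbury
# complement.
#
# Fixed multistart points of the conditional-mode search: the penalized
# inner problem can be multimodal under very sparse data (a single
# post-infusion sample constrains only a curve in the eta plane), so
# the compiled core runs a damped Gauss-Newton descent from each of
# these and keeps the global optimum per subject, which keeps the
# objective a continuous, deterministic function of the population
# parameters.
.eta_starts <- cbind(c(0, 0.8, -0.8, 0, 0),
                     c(0, -0.8, 0.8, 0.8, -0.8))

.foce_ofv <- function(flat, params, terms = NULL, betas = NULL,
                      detail = FALSE, method = "laplace") {
  base <- .base_cl_v(flat, params, terms, betas)
  if (any(!is.finite(base$cl) | base$cl <= 0 |
          !is.finite(base$v) | base$v <= 0))
    return(if (detail) NULL else 1e10)
  core <- .foce_core(flat$n_i, flat$obs_time, flat$ldv,
                     flat$pair_count, flat$p_t0, flat$p_dur,
                     flat$p_rate, base$cl, base$v,
                     params$omega2_cl, params$omega2_v,
                     params$sigma2, .eta_starts,
                     identical(method, "laplace"), 1e-8, 60L)
  if (core$bad_obs > 0)
    stop("non-finite model prediction for subject ",
         flat$ids[flat$obs_subj[core$bad_obs]], " at t = ",
         flat$obs_time[core$bad_obs], " h", call. = FALSE)
  if (!detail) return(core$ofv)
  list(ofv = core$ofv, ofv_i = core$ofv_i,
       eta = cbind(eta_cl = core$eta1, eta_v = core$eta2),
       base = base, m = core$m, r = core$r,
       J1 = core$J1, J2 = core$J2)
}

#' Conditional-estimation objective function value
#'
#' Minus twice the conditional (subject-mode) approximation to the
#' marginal log-likelihood of the mixed-effects model. Observations are
#' modeled on the log scale, where the exponential residual becomes
#' additive Gaussian (which also makes the eta-residual interaction of
#' FOCE-I exact); each subject's conditional mode of `(eta_cl, eta_v)`
#' is located by a penalized Gauss-Newton search and a Gaussian
#' expansion around the mode is accumulated over subjects. The default
#' `"laplace"` expansion uses the exact analytic curvature of the
#' log-prediction; `"foce"` selects the classical first-order
#' linearization instead. Deterministic given the dataset and
#' parameters.
#'
#' @param dataset a `pk_dataset`.
#' @param params a [pop_params()] object.
#' @param terms optional list of [covariate_term()]s included in the
#'   structural model.
#' @param betas coefficients for `terms`, same length.
#' @param method `"laplace"` (default) or `"foce"`.
#' @return the objective function value (OFV), a scalar.
#' @export
foce_objective <- function(dataset, params, terms = NULL, betas = NULL,
                           method = c("laplace", "foce")) {
  .foce_ofv(.flatten_dataset(dataset), params, terms, betas,
            method = match.arg(method))
}

#' Empirical Bayes estimates of the random effects
#'
#' Conditional modes of `(eta_cl, eta_v)` given each subject's data and
#' the population parameters. A subject with no observations sits at the
#' prior mode `(0, 0)`.
#'
#' @inheritParams foce_objective
#' @return data frame with columns `subject_id`, `eta_cl`, `eta_v`.
#' @export
empirical_bayes <- function(dataset, params, terms = NULL, betas = NULL) {
  flat <- .flatten_dataset(dataset)
  d <- .foce_ofv(flat, params, terms, betas, detail = TRUE)
  if (is.null(d))
    stop("invalid structural parameters", call. = FALSE)
  data.frame(subject_id = flat$ids, eta_cl = d$eta[, 1],
             eta_v = d$eta[, 2])
}

# ---- population fit ------------------------------------------------------

#' Fit the population model by FOCE
#'
#' Minimizes [foce_objective()] over `(tvcl, tvv, omega2_cl, omega2_v,
#' sigma2)` plus any covariate-term coefficients, with positivity
#' enforced by log-parameterization of the first five. `tm50` and `hill`
#' are held fixed. Non-convergence and variances shrinking to the
#' boundary are flagged on the result rather than raised as errors.
#'
#' @param dataset a `pk_dataset`.
#' @param init a [pop_params()] object of starting values (its
#'   `tm50`/`hill` are the fixed values used).
#' @param terms optional list of [covariate_term()]s to estimate.
#' @param beta_init starting coefficients for `terms` (default 0).
#' @param control passed to [stats::nlminb()]; defaults
#'   `list(rel.tol = 1e-6, iter.max = 300, eval.max = 1000)`.
#' @param method objective flavor, see [foce_objective()].
#' @return An object of class `neocef_fit`: estimated [pop_params()],
#'   `ofv`, per-subject empirical Bayes `ebes`, eta/epsilon shrinkages
#'   (%), `convergence` and `boundary` flags, covariate-term estimates,
#'   and bookkeeping (`n_subjects`, `n_obs`).
#' @export
fit_population <- function(dataset, init, terms = NULL, beta_init = NULL,
                           control = list(),
                           method = c("laplace", "foce")) {
  method <- match.arg(method)
  flat <- .flatten_dataset(dataset)
  ctl <- utils::modifyList(list(rel.tol = 1e-6, iter.max = 300,
                                eval.max = 1000), control)
  nb <- length(terms)
  if (is.null(beta_init)) beta_init <- rep(0, nb)
  par0 <- c(log(init$tvcl), log(init$tvv), log(init$omega2_cl),
            log(init$omega2_v), log(init$sigma2), beta_init)
  unpack <- function(p) {
    pop_params(tvcl = exp(p[1]), tvv = exp(p[2]),
               omega2_cl = exp(p[3]), omega2_v = exp(p[4]),
               sigma2 = exp(p[5]), tm50 = init$tm50, hill = init$hill)
  }
  obj <- function(p) {
    if (any(!is.finite(p)) || any(p[1:5] > 50)) return(1e10)
    pr <- unpack(p)
    ofv <- .foce_ofv(flat, pr, terms,
                     if (nb) p[5 + seq_len(nb)] else NULL,
                     method = method)
    if (is.null(ofv) || !is.finite(ofv)) return(1e10)
    ofv
  }
  # retry from the stopping point when the optimizer reports a
  # non-clean stop; accept when a restart no longer improves the OFV
  opt <- stats::nlminb(par0, obj, control = ctl)
  for (retry in 1:2) {
    if (opt$convergence == 0) break
    opt2 <- stats::nlminb(opt$par, obj, control = ctl)
    improved <- opt$objective - opt2$objective
    opt <- opt2
    if (improved < 1e-3) {
      opt$convergence <- 0L
      opt$message <- paste(opt$message, "(stable under restart)")
      break
    }
  }
  est <- unpack(opt$par)
  betas <- if (nb) opt$par[5 + seq_len(nb)] else numeric(0)
  d <- .foce_ofv(flat, est, terms, if (nb) betas else NULL,
                 detail = TRUE, method = method)
  shr <- .shrinkage_from_detail(d, est, flat)
  structure(list(
    params = est,
    betas = stats::setNames(betas,
                            vapply(terms, function(x) x$label,
                                   character(1))[seq_len(nb)]),
    terms = terms,
    ofv = opt$objective,
    ebes = data.frame(subject_id = flat$ids,
                      eta_cl = d$eta[, 1], eta_v = d$eta[, 2]),
    eta_shrinkage_cl = shr[["eta_cl"]],
    eta_shrinkage_v = shr[["eta_v"]],
    eps_shrinkage = shr[["eps"]],
    convergence = opt$convergence == 0,
    boundary = any(c(est$omega2_cl, est$omega2_v) < 1e-6) ||
      est$sigma2 < 1e-8,
    rse = NULL,
    n_subjects = flat$n_subj,
    n_obs = flat$n_obs,
    optimizer = list(convergence = opt$convergence,
                     message = opt$message,
                     iterations = opt$iterations)),
    class = "neocef_fit")
}

.shrinkage_from_detail <- function(d, params, flat) {
  sd_or_na <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  shr <- function(sd_eta, omega2) {
    if (omega2 < 1e-12) return(NA_real_)
    100 * (1 - sd_eta / sqrt(omega2))
  }
  ipred_log <- d$m       # log prediction at the EBEs
  iwres <- (flat$ldv - ipred_log) / sqrt(params$sigma2)
  c(eta_cl = shr(sd_or_na(d$eta[, 1]), params$omega2_cl),
    eta_v = shr(sd_or_na(d$eta[, 2]), params$omega2_v),
    eps = 100 * (1 - sd_or_na(iwres)))
}

#' Eta and epsilon shrinkage of a fit
#'
#' Eta shrinkage is `100 (1 - sd(EBE) / omega)` per random effect;
#' epsilon shrinkage is `100 (1 - sd(IWRES))`. Values near 100% signal
#' that the data carry little individual-level information.
#'
#' @param fit a `neocef_fit`.
#' @return named numeric vector `eta_cl`, `eta_v`, `eps` (percent).
#' @export
shrinkage <- function(fit) {
  c(eta_cl = fit$eta_shrinkage_cl, eta_v = fit$eta_shrinkage_v,
    eps = fit$eps_shrinkage)
}

#' @export
print.neocef_fit <- function(x, ...) {
  cat("<neocef_fit> ", x$n_subjects, " subjects, ", x$n_obs,
      " observations\n", sep = "")
  cat(sprintf("  OFV %.3f   converged: %s%s\n", x$ofv,
              x$convergence, if (x$boundary) " (variance at boundary)"
              else ""))
  print(x$params)
  if (length(x$betas)) {
    cat("  covariate terms:\n")
    for (nm in names(x$betas))
      cat(sprintf("    %s: %.4g\n", nm, x$betas[[nm]]))
  }
  cat(sprintf("  shrinkage %%: eta(CL) %.1f, eta(V) %.1f, eps %.1f\n",
              x$eta_shrinkage_cl, x$eta_shrinkage_v, x$eps_shrinkage))
  invisible(x)
}

# ---- stepwise covariate screening ---------------------------------------

#' Stepwise covariate selection by likelihood-ratio screening
#'
#' Forward inclusion adds, one at a time, the candidate term giving the
#' largest drop in OFV, provided the drop is at least
#' `qchisq(1 - forward_p, 1)` (3.84 at p < 0.05). Backward elimination
#' then removes any selected term whose removal raises the OFV by less
#' than `qchisq(1 - backward_p, 1)` (6.63 at p < 0.01). The a priori
#' allometric weight and maturation terms are structural and never
#' touched. Candidates whose fit fails are skipped with a warning.
#'
#' @param dataset a `pk_dataset`.
#' @param init starting [pop_params()] for every fit.
#' @param candidates list of [covariate_term()]s to screen.
#' @param forward_p,backward_p inclusion / elimination significance
#'   levels (defaults 0.05 and 0.01).
#' @param control optimizer control, see [fit_population()].
#' @return list with `fit` (final model), `selected` (terms kept),
#'   `base_fit`, and `trace` (data frame logging every decision).
#' @export
stepwise_covariate_selection <- function(dataset, init, candidates,
                                         forward_p = 0.05,
                                         backward_p = 0.01,
                                         control = list()) {
  fwd_cut <- stats::qchisq(1 - forward_p, df = 1)
  bwd_cut <- stats::qchisq(1 - backward_p, df = 1)
  base_fit <- fit_population(dataset, init, control = control)
  trace <- data.frame(step = character(), term = character(),
                      dofv = numeric(), decision = character())
  log_row <- function(step, term, dofv, decision) {
    trace[nrow(trace) + 1L, ] <<- list(step, term, dofv, decision)
  }
  selected <- list()
  current <- base_fit
  pool <- candidates
  repeat {
    if (!length(pool)) break
    dofvs <- rep(NA_real_, length(pool))
    fits <- vector("list", length(pool))
    for (j in seq_along(pool)) {
      trial_terms <- c(selected, pool[j])
      f <- tryCatch(fit_population(dataset, init, terms = trial_terms,
                                   control = control),
                    error = function(e) NULL)
      if (is.null(f) || !is.finite(f$ofv)) {
        warning("candidate ", pool[[j]]$label,
                " skipped: fit failed", call. = FALSE)
        log_row("forward", pool[[j]]$label, NA_real_, "skipped")
        next
      }
      fits[[j]] <- f
      dofvs[j] <- current$ofv - f$ofv
    }
    if (all(is.na(dofvs))) break
    best <- which.max(dofvs)
    if (is.na(dofvs[best]) || dofvs[best] < fwd_cut) {
      for (j in seq_along(pool)) {
        if (!is.na(dofvs[j]))
          log_row("forward", pool[[j]]$label, dofvs[j], "not included")
      }
      break
    }
    log_row("forward", pool[[best]]$label, dofvs[best], "included")
    for (j in seq_along(pool)) {
      if (j != best && !is.na(dofvs[j]))
        log_row("forward", pool[[j]]$label, dofvs[j], "not included")
    }
    selected <- c(selected, pool[best])
    current <- fits[[best]]
    pool <- pool[-best]
  }
  # backward elimination on the selected (non-structural) terms
  repeat {
    if (!length(selected)) break
    removed <- FALSE
    for (j in seq_along(selected)) {
      reduced <- selected[-j]
      f <- tryCatch(fit_population(dataset, init, terms = reduced,
                                   control = control),
                    error = function(e) NULL)
      if (is.null(f)) next
      dofv <- f$ofv - current$ofv
      if (dofv < bwd_cut) {
        log_row("backward", selected[[j]]$label, dofv, "removed")
        selected <- reduced
        current <- f
        removed <- TRUE
        break
      } else {
        log_row("backward", selected[[j]]$label, dofv, "retained")
      }
    }
    if (!removed) break
  }
  list(fit = current, selected = selected, base_fit = base_fit,
       trace = trace)
}
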