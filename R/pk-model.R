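# One-compartment IV-infusion structural model with allometric weight
# scaling and sigmoidal maturation of clearance.

#' Population model parameters
#'
#' Fixed effects are expressed at the 70 kg reference weight under full
#' maturation; variance components are log-normal interindividual
#' variances on clearance and volume and the log-domain residual
#' variance. The maturation midpoint `tm50` and Hill coefficient are
#' structural constants taken from the renal-maturation literature and
#' are not estimated.
#'
#' @param tvcl typical clearance (L/h per 70 kg), > 0.
#' @param tvv typical volume of distribution (L per 70 kg), > 0.
#' @param omega2_cl variance of the log-normal random effect on CL.
#' @param omega2_v variance of the log-normal random effect on V.
#' @param sigma2 variance of the additive residual on the log scale
#'   (exponential residual model).
#' @param tm50 PMA (weeks) at 50% clearance maturation; fixed, default
#'   47.7.
#' @param hill Hill coefficient of the maturation sigmoid; fixed,
#'   default 3.4.
#' @return A list of class `pop_params`.
#' @export
pop_params <- function(tvcl, tvv, omega2_cl, omega2_v, sigma2,
                       tm50 = 47.7, hill = 3.4) {
  stopifnot(tvcl > 0, tvv > 0, omega2_cl >= 0, omega2_v >= 0,
            sigma2 >= 0, tm50 > 0, hill > 0)
  structure(list(tvcl = tvcl, tvv = tvv, omega2_cl = omega2_cl,
                 omega2_v = omega2_v, sigma2 = sigma2,
                 tm50 = tm50, hill = hill),
            class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat("<pop_params>\n")
  cat(sprintf("  TVCL %.4g L/h/70kg   TVV %.4g L/70kg\n", x$tvcl, x$tvv))
  cat(sprintf("  omega2(CL) %.4g (CV %.1f%%)   omega2(V) %.4g (CV %.1f%%)\n",
              x$omega2_cl, cv_percent(x$omega2_cl),
              x$omega2_v, cv_percent(x$omega2_v)))
  cat(sprintf("  sigma2 %.4g (CV %.1f%%)   TM50 %.4g wk (fixed)   Hill %.4g (fixed)\n",
              x$sigma2, cv_percent(x$sigma2), x$tm50, x$hill))
  invisible(x)
}

#' Published neonatal ceftazidime model parameters
#'
#' The reference parameter set for the whole-blood (qDBS) one-compartment
#' neonatal ceftazidime model: TVCL 19.6 L/h/70 kg, TVV 70.6 L/70 kg,
#' interindividual CV 28.1% (CL) and 42.4% (V), residual CV 22.3%,
#' with maturation constants TM50 = 47.7 weeks and Hill = 3.4.
#'
#' @return a [pop_params()] object.
#' @export
ceftazidime_neonatal_params <- function() {
  pop_params(tvcl = 19.6, tvv = 70.6,
             omega2_cl = cv_to_omega2(28.1),
             omega2_v = cv_to_omega2(42.4),
             sigma2 = cv_to_omega2(22.3))
}

#' Sigmoidal maturation fraction of clearance
#'
#' `pma^hill / (pma^hill + tm50^hill)`: the fraction of adult clearance
#' attained at postmenstrual age `pma`. Strictly increasing in `pma`,
#' equal to 0.5 at `pma = tm50`.
#'
#' @param pma postmenstrual age (weeks), > 0. Vectorized.
#' @param tm50 maturation half-time (weeks), > 0.
#' @param hill Hill coefficient, > 0.
#' @return maturation fraction in (0, 1).
#' @export
maturation_fraction <- function(pma, tm50 = 47.7, hill = 3.4) {
  if (any(pma <= 0) || tm50 <= 0 || hill <= 0)
    stop("maturation_fraction: pma, tm50 and hill must be positive",
         call. = FALSE)
  1 / (1 + (tm50 / pma)^hill)
}

#' Individual clearance under the covariate model
#'
#' `CL = TVCL * (WT/70)^0.75 * maturation(PMA) * exp(eta_cl)`. The
#' allometric exponent 0.75 is a structural constant.
#'
#' @param params a [pop_params()] object.
#' @param covariates a [pk_covariates()] object, or any list with `wt`
#'   (kg) and `pma` (weeks).
#' @param eta_cl random-effect realization (default 0: typical subject).
#' @return clearance in L/h.
#' @export
individual_clearance <- function(params, covariates, eta_cl = 0) {
  if (any(covariates$wt <= 0) || any(covariates$pma <= 0))
    stop("individual_clearance: wt and pma must be positive",
         call. = FALSE)
  params$tvcl * (covariates$wt / 70)^0.75 *
    maturation_fraction(covariates$pma, params$tm50, params$hill) *
    exp(eta_cl)
}

#' Individual volume of distribution under the covariate model
#'
#' `V = TVV * (WT/70) * exp(eta_v)` (linear allometry, exponent 1).
#'
#' @inheritParams individual_clearance
#' @param eta_v random-effect realization (default 0).
#' @return volume in L.
#' @export
individual_volume <- function(params, covariates, eta_v = 0) {
  if (any(covariates$wt <= 0))
    stop("individual_volume: wt must be positive", call. = FALSE)
  params$tvv * (covariates$wt / 70) * exp(eta_v)
}

# Vectorized contribution of (observation, dose) pairs; shared by the
# estimator and the public profile function. All arguments recycled
# elementwise; dt <= 0 (before infusion start) contributes zero.
.infusion_contrib <- function(time, t0, dur, rate, cl, k) {
  dt <- time - t0
  te <- pmin(pmax(dt, 0), dur)          # elapsed infusion time
  tail <- pmax(dt - dur, 0)             # post-infusion decay time
  (rate / cl) * (1 - exp(-k * te)) * exp(-k * tail)
}

#' Whole-blood concentration under superposed IV infusions
#'
#' Closed-form one-compartment solution: each dose with infusion rate
#' `R = amount / infusion_duration` starting at `t0` contributes
#' `(R/CL) (1 - e^(-k (t - t0)))` during the infusion and
#' `(R/CL) (1 - e^(-k dur)) e^(-k (t - t0 - dur))` afterwards, with
#' `k = CL/V`; contributions over doses sum.
#'
#' @param t evaluation times (h since first dose), >= 0. Vectorized.
#' @param cl clearance (L/h).
#' @param v volume of distribution (L).
#' @param doses data frame with columns `time`, `amount`,
#'   `infusion_duration` (as in [pk_subject()]).
#' @return concentrations (mg/L), same length as `t`.
#' @export
conc_onecpt_infusion <- function(t, cl, v, doses) {
  if (any(t < 0)) stop("negative evaluation time", call. = FALSE)
  stopifnot(cl > 0, v > 0)
  if (nrow(doses) == 0L) return(numeric(length(t)))
  k <- cl / v
  rate <- doses$amount / doses$infusion_duration
  out <- numeric(length(t))
  for (j in seq_len(nrow(doses))) {
    out <- out + .infusion_contrib(t, doses$time[j],
                                   doses$infusion_duration[j],
                                   rate[j], cl, k)
  }
  out
}

#' Dosing regimen
#'
#' @param dose_per_kg dose (mg/kg) per administration.
#' @param interval dosing interval (h).
#' @param infusion_duration infusion length (h), default 0.5 (30 min).
#' @param label optional display label; defaults to e.g. `"25 mg/kg q8h"`.
#' @return a list of class `pk_regimen`.
#' @export
regimen <- function(dose_per_kg, interval, infusion_duration = 0.5,
                    label = NULL) {
  stopifnot(dose_per_kg > 0, interval > 0, infusion_duration > 0,
            infusion_duration < interval)
  if (is.null(label))
    label <- sprintf("%g mg/kg q%gh", dose_per_kg, interval)
  structure(list(dose_per_kg = dose_per_kg, interval = interval,
                 infusion_duration = infusion_duration, label = label),
            class = "pk_regimen")
}

#' The standard evaluation grid of neonatal ceftazidime regimens
#'
#' Four dose levels (25, 50, 75, 100 mg/kg) crossed with three intervals
#' (q6h, q8h, q12h), all as 30-minute infusions.
#'
#' @return list of [regimen()] objects, length 12.
#' @export
standard_regimen_grid <- function() {
  g <- expand.grid(dose = c(25, 50, 75, 100), interval = c(6, 8, 12))
  lapply(seq_len(nrow(g)),
         function(i) regimen(g$dose[i], g$interval[i]))
}

#' Time offset at which repeated dosing has reached steady state
#'
#' Returns the start time of the first dosing interval after which the
#' pre-dose (trough) concentration changes by less than `rel_tol`
#' between consecutive intervals. With negligible accumulation the first
#' interval qualifies and the offset is 0.
#'
#' For trough concentrations proportional to `1 - x^m` with
#' `x = exp(-k tau)` after `m` doses, the relative change criterion has
#' the closed-form solution
#' `m = ceiling(log(rel_tol / (1 - x + rel_tol)) / log(x))`.
#'
#' @param cl clearance (L/h); vectorized.
#' @param v volume (L); vectorized.
#' @param reg a [regimen()].
#' @param rel_tol relative trough-change threshold, default 0.001 (0.1%).
#' @return time offset (h), a multiple of the dosing interval.
#' @export
steady_state_window <- function(cl, v, reg, rel_tol = 0.001) {
  k <- cl / v
  x <- exp(-k * reg$interval)
  m <- ceiling(log(rel_tol / (1 - x + rel_tol)) / log(x))
  m <- pmax(1, ifelse(is.finite(m), m, 1))
  (m - 1) * reg$interval
}

#' Expand a regimen into explicit dose events for one subject
#'
#' @param reg a [regimen()].
#' @param wt body weight (kg); the administered amount is
#'   `dose_per_kg * wt` rounded to 0.1 mg.
#' @param n_doses number of doses.
#' @return data frame of dose events as used by [conc_onecpt_infusion()].
#' @export
regimen_doses <- function(reg, wt, n_doses) {
  stopifnot(n_doses >= 1)
  data.frame(time = (seq_len(n_doses) - 1) * reg$interval,
             amount = round(reg$dose_per_kg * wt, 1),
             infusion_duration = reg$infusion_duration)
}
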