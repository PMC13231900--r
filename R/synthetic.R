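# Synthetic-study generator: emulates the sparse neonatal qDBS sampling
# design with known ground truth, so every pipeline stage can be tested
# without patient data.

#' Study design configuration for the synthetic generator
#'
#' Defaults emulate the study design: 72 neonates, 1-4 samples per
#' subject (median 2, about 140 samples in total), sampling windows
#' 0-0.5 / 2-3 / 4-6 h after the first dose, 30-minute infusions, and
#' maintenance dosing of 25 or 50 mg/kg every 8 or 12 h (the generator's
#' own choice, reflecting common neonatal practice; the administered
#' clinical doses were not part of the published design).
#'
#' Covariate defaults reproduce the cohort summary: PMA from a
#' left-skewed scaled Beta on \[32.7, 41.9\] weeks with median 39.7 and
#' about 19.4% preterm (GA < 37 weeks, with GA = PMA - PNA/7); weight
#' from the PMA-conditional model truncated to \[1.8, 4.2\] kg; serum
#' creatinine log-normal with median 56.7 umol/L truncated to
#' \[23.7, 88.0\]; postnatal age uniform on 1-4 days; 59.7% male.
#'
#' @param n_subjects number of neonates, default 72.
#' @param sample_count_probs probabilities of 1, 2, 3, 4 samples per
#'   subject; default `c(0.30, 0.50, 0.15, 0.05)` (median 2, mean 1.95).
#' @param windows sampling windows (h post-dose).
#' @param dose_per_kg_choices candidate maintenance doses (mg/kg).
#' @param interval_choices candidate dosing intervals (h).
#' @param infusion_duration infusion length (h), default 0.5.
#' @param pma_range,pma_beta PMA truncation range (weeks) and Beta shape
#'   parameters of the scaled distribution.
#' @param wt_model a [wt_given_pma_model()].
#' @param scr_median,scr_sdlog,scr_range serum creatinine log-normal
#'   parameters (umol/L).
#' @param pna_days support of postnatal age (days).
#' @param male_prob probability of male sex.
#' @param lloq lower limit of quantification (mg/L) used for BLQ
#'   flagging.
#' @return list of class `study_design`.
#' @export
study_design <- function(n_subjects = 72,
                         sample_count_probs = c(0.30, 0.50, 0.15, 0.05),
                         windows = design_windows(),
                         dose_per_kg_choices = c(25, 50),
                         interval_choices = c(8, 12),
                         infusion_duration = 0.5,
                         pma_range = c(32.7, 41.9),
                         pma_beta = c(2.2406, 0.9038),
                         wt_model = wt_given_pma_model(),
                         scr_median = 56.7, scr_sdlog = 0.25,
                         scr_range = c(23.7, 88.0),
                         pna_days = 1:4,
                         male_prob = 0.597,
                         lloq = 0.25) {
  stopifnot(n_subjects >= 1,
            abs(sum(sample_count_probs) - 1) < 1e-8,
            length(sample_count_probs) == 4)
  lo <- vapply(windows, `[`, numeric(1), 1)
  hi <- vapply(windows, `[`, numeric(1), 2)
  if (any(diff(lo) <= 0) || any(hi[-length(hi)] > lo[-1]))
    stop("sampling windows must be ordered and disjoint", call. = FALSE)
  structure(as.list(environment())[c(
    "n_subjects", "sample_count_probs", "windows",
    "dose_per_kg_choices", "interval_choices", "infusion_duration",
    "pma_range", "pma_beta", "wt_model", "scr_median", "scr_sdlog",
    "scr_range", "pna_days", "male_prob", "lloq")],
    class = "study_design")
}

# Truncated log-normal by rejection (vectorized redraw).
.draw_trunc_lnorm <- function(n, meanlog, sdlog, range) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  bad <- x < range[1] | x > range[2]
  while (any(bad)) {
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
    bad <- x < range[1] | x > range[2]
  }
  x
}

#' Sample baseline covariates from the study design
#'
#' @param config a [study_design()].
#' @param n number of subjects.
#' @param seed integer seed.
#' @return list of [pk_covariates()] objects, length `n`.
#' @export
sample_covariates <- function(config = study_design(), n = config$n_subjects,
                              seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  b <- stats::rbeta(n, config$pma_beta[1], config$pma_beta[2])
  pma <- config$pma_range[1] + diff(config$pma_range) * b
  pna <- sample(config$pna_days, n, replace = TRUE)
  ga <- pma - pna / 7
  wt <- .draw_wt(pma, config$wt_model)
  scr <- .draw_trunc_lnorm(n, log(config$scr_median), config$scr_sdlog,
                           config$scr_range)
  sex <- ifelse(stats::runif(n) < config$male_prob, "male", "female")
  lapply(seq_len(n), function(i)
    pk_covariates(wt = wt[i], pma = pma[i], ga = ga[i], pna = pna[i],
                  scr = scr[i], sex = sex[i]))
}

#' Generate a synthetic study with known ground truth
#'
#' Per subject: covariates are drawn from the design, a maintenance
#' regimen is assigned (dose and interval sampled from the design's
#' choices), random effects and residuals are drawn from `truth`,
#' sampling times are placed uniformly within the selected post-dose
#' windows after the first dose, and whole-blood concentrations are
#' computed from the structural model with log-normal residual error.
#' Concentrations below the LLOQ are flagged BLQ (values retained).
#'
#' @param truth a [pop_params()] object: the generating parameters.
#' @param config a [study_design()].
#' @param seed integer seed.
#' @return list with `dataset` (a `pk_dataset`) and `truth` (the
#'   parameters plus per-subject `etas` and per-observation residuals).
#' @export
generate_study <- function(truth = ceftazidime_neonatal_params(),
                           config = study_design(), seed = 1) {
  set.seed(seed)
  n <- config$n_subjects
  covs <- sample_covariates(config, n, seed = seed + 1)
  # seed+1 consumed the stream; re-seed the subject-level draws
  set.seed(seed + 2)
  eta_cl <- stats::rnorm(n, 0, sqrt(truth$omega2_cl))
  eta_v <- stats::rnorm(n, 0, sqrt(truth$omega2_v))
  counts <- sample(1:4, n, replace = TRUE,
                   prob = config$sample_count_probs)
  dpk <- sample(config$dose_per_kg_choices, n, replace = TRUE)
  tau <- sample(config$interval_choices, n, replace = TRUE)
  subjects <- vector("list", n)
  etas <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                     eta_cl = eta_cl, eta_v = eta_v)
  residuals <- vector("list", n)
  nw <- length(config$windows)
  for (i in seq_len(n)) {
    cv <- covs[[i]]
    wsel <- if (counts[i] <= nw) sort(sample.int(nw, counts[i]))
    else sort(c(seq_len(nw), sample.int(nw, counts[i] - nw)))
    times <- sort(vapply(wsel, function(w)
      stats::runif(1, max(config$windows[[w]][1], 1e-3),
                   config$windows[[w]][2]), numeric(1)))
    doses <- data.frame(time = 0,
                        amount = round(dpk[i] * cv$wt, 1),
                        infusion_duration = config$infusion_duration)
    cl <- individual_clearance(truth, cv, eta_cl[i])
    v <- individual_volume(truth, cv, eta_v[i])
    eps <- stats::rnorm(counts[i], 0, sqrt(truth$sigma2))
    conc <- conc_onecpt_infusion(times, cl, v, doses) * exp(eps)
    residuals[[i]] <- eps
    subjects[[i]] <- pk_subject(etas$subject_id[i], cv, doses,
                                data.frame(time = times, conc = conc,
                                           blq = conc < config$lloq))
  }
  list(dataset = pk_dataset(subjects, source = "synthetic", seed = seed),
       truth = list(params = truth, etas = etas, residuals = residuals,
                    regimen = data.frame(subject_id = etas$subject_id,
                                         dose_per_kg = dpk,
                                         interval = tau)))
}
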