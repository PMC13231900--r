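# Shared fixtures: small hand-built datasets and canonical parameters.

ref_params <- function() ceftazidime_neonatal_params()

# a deliberately simple two-subject dataset with known numbers
tiny_dataset <- function() {
  cov1 <- pk_covariates(wt = 3.2, pma = 39.4, ga = 39.0, pna = 2,
                        scr = 56.7, sex = "male")
  cov2 <- pk_covariates(wt = 2.5, pma = 36.0, ga = 35.8, pna = 1,
                        scr = 40.0, sex = "female")
  doses <- function(amt) data.frame(time = 0, amount = amt,
                                    infusion_duration = 0.5)
  obs <- function(t, c) data.frame(time = t, conc = c,
                                   blq = c < 0.25)
  pk_dataset(list(
    pk_subject("A", cov1, doses(80), obs(c(0.4, 2.5), c(20.1, 11.3))),
    pk_subject("B", cov2, doses(62.5), obs(c(0.3, 5.0), c(18.4, 4.2)))),
    source = "fixture")
}

# dataset drawn from the model at a configurable design scale
sim_dataset <- function(seed, n_subjects = 72, truth = ref_params(),
                        ...) {
  cfg <- study_design(n_subjects = n_subjects, ...)
  generate_study(truth = truth, config = cfg, seed = seed)
}

fast_ctl <- list(rel.tol = 1e-6, iter.max = 150, eval.max = 500)
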