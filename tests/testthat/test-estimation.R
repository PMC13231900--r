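test_that("CV% transform matches the log-normal formula and inverts exactly", {
  expect_equal(cv_percent(0), 0)
  expect_equal(cv_percent(log(2)), 100)
  expect_equal(cv_percent(0.0760), 28.1, tolerance = 1e-3)
  for (cv in c(0.5, 12, 28.1, 42.4, 150))
    expect_equal(cv_percent(cv_to_omega2(cv)), cv, tolerance = 1e-10)
  expect_error(cv_percent(-0.1), ">= 0")
})

test_that("FOCE objective reduces to the closed form at zero IIV and is additive over subjects", {
  p <- ref_params()
  gen <- sim_dataset(seed = 3, n_subjects = 8)
  ds <- handle_blq(gen$dataset)
  p0 <- pop_params(p$tvcl, p$tvv, 0, 0, p$sigma2)
  # degenerate-variance closed form: sum over observations of
  # log(2 pi s2) + (log DV - log PRED)^2 / s2
  expected <- 0
  for (s in ds$subjects) {
    pred <- conc_onecpt_infusion(s$observations$time,
                                 individual_clearance(p0, s$covariates),
                                 individual_volume(p0, s$covariates),
                                 s$doses)
    r <- log(s$observations$conc) - log(pred)
    expected <- expected +
      sum(log(2 * pi * p0$sigma2) + r^2 / p0$sigma2)
  }
  expect_equal(foce_objective(ds, p0), expected, tolerance = 1e-8)

  # duplicating a subject adds exactly its own contribution
  ofv1 <- foce_objective(ds, p)
  dup <- ds
  extra <- dup$subjects[[3]]
  extra$subject_id <- "dup"
  dup$subjects <- c(dup$subjects, list(extra))
  only3 <- pk_dataset(ds$subjects[3])
  expect_equal(foce_objective(dup, p), ofv1 + foce_objective(only3, p),
               tolerance = 1e-8)

  # invariant to subject ordering
  perm <- pk_dataset(ds$subjects[sample(seq_along(ds$subjects))])
  expect_equal(foce_objective(perm, p), ofv1, tolerance = 1e-10)
})

test_that("FOCE objective is invariant to a consistent change of time units", {
  p <- ref_params()
  gen <- sim_dataset(seed = 11, n_subjects = 10)
  ds <- handle_blq(gen$dataset)
  # rescale hours -> minutes: times and durations x60, CL in L/min
  ds_min <- ds
  for (i in seq_along(ds_min$subjects)) {
    ds_min$subjects[[i]]$doses$time <-
      ds_min$subjects[[i]]$doses$time * 60
    ds_min$subjects[[i]]$doses$infusion_duration <-
      ds_min$subjects[[i]]$doses$infusion_duration * 60
    ds_min$subjects[[i]]$observations$time <-
      ds_min$subjects[[i]]$observations$time * 60
  }
  p_min <- pop_params(p$tvcl / 60, p$tvv, p$omega2_cl, p$omega2_v,
                      p$sigma2)
  expect_equal(foce_objective(ds_min, p_min), foce_objective(ds, p),
               tolerance = 1e-9)
})

test_that("FOCE objective agrees with adaptive Gauss-Hermite quadrature on a small set", {
  skip_if_not_installed("pracma")
  p <- ref_params()
  gen <- sim_dataset(seed = 5, n_subjects = 5)
  ds <- handle_blq(gen$dataset)
  ofv <- foce_objective(ds, p)
  exact <- quadrature_ofv_oracle(ds, p)
  expect_equal(ofv, exact, tolerance = 0.01)
})

test_that("empirical Bayes estimates match a dense grid-search MAP oracle", {
  p <- ref_params()
  gen <- sim_dataset(seed = 9, n_subjects = 6)
  ds <- handle_blq(gen$dataset)
  eb <- empirical_bayes(ds, p)
  for (i in seq_along(ds$subjects)) {
    oracle <- grid_map_oracle(ds$subjects[[i]], p)
    expect_lt(max(abs(c(eb$eta_cl[i], eb$eta_v[i]) - oracle)), 1e-3)
  }
})

test_that("empirical Bayes sits at the prior mode without data and near zero for typical data", {
  p <- ref_params()
  gen <- sim_dataset(seed = 13, n_subjects = 4)
  ds <- gen$dataset
  # subject with zero observations
  ds$subjects[[2]]$observations <-
    ds$subjects[[2]]$observations[0, , drop = FALSE]
  eb <- empirical_bayes(ds, p)
  expect_equal(unlist(eb[2, c("eta_cl", "eta_v")]), c(eta_cl = 0,
                                                      eta_v = 0))
  # observations placed exactly at typical predictions, tiny sigma
  ds2 <- gen$dataset
  p_tiny <- pop_params(p$tvcl, p$tvv, p$omega2_cl, p$omega2_v, 1e-10)
  for (i in seq_along(ds2$subjects)) {
    s <- ds2$subjects[[i]]
    ds2$subjects[[i]]$observations$conc <-
      conc_onecpt_infusion(s$observations$time,
                           individual_clearance(p, s$covariates),
                           individual_volume(p, s$covariates), s$doses)
    ds2$subjects[[i]]$observations$blq <- FALSE
  }
  eb2 <- empirical_bayes(ds2, p_tiny)
  expect_lt(max(abs(c(eb2$eta_cl, eb2$eta_v))), 1e-4)
})

test_that("fit recovers generating parameters exactly from noise-free rich data", {
  truth <- pop_params(15, 60, cv_to_omega2(25), cv_to_omega2(35),
                      1e-12)
  # rich design: all etas 0, sigma ~ 0, many samples
  cfg <- study_design(n_subjects = 12,
                      sample_count_probs = c(0, 0, 0, 1))
  gen <- generate_study(truth = pop_params(15, 60, 0, 0, 1e-12),
                        config = cfg, seed = 21)
  init <- pop_params(10, 40, 0.05, 0.05, 0.01)
  fit <- fit_population(handle_blq(gen$dataset), init)
  expect_equal(fit$params$tvcl, 15, tolerance = 1e-4)
  expect_equal(fit$params$tvv, 60, tolerance = 1e-4)
  expect_true(fit$boundary)   # variances collapse on noise-free data
})

test_that("gradient of the objective vanishes at the fitted optimum", {
  p <- ref_params()
  gen <- sim_dataset(seed = 17, n_subjects = 40)
  ds <- handle_blq(gen$dataset)
  fit <- fit_population(ds, p, control = fast_ctl)
  expect_true(fit$convergence)
  par <- log(c(fit$params$tvcl, fit$params$tvv, fit$params$omega2_cl,
               fit$params$omega2_v, fit$params$sigma2))
  h <- 1e-4
  g <- vapply(1:5, function(i) {
    e <- replace(rep(0, 5), i, h)
    pp <- function(x) pop_params(exp(x[1]), exp(x[2]), exp(x[3]),
                                 exp(x[4]), exp(x[5]))
    (foce_objective(ds, pp(par + e)) -
       foce_objective(ds, pp(par - e))) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g)), 0.5)
})

test_that("shrinkage reports follow their definitions", {
  p <- ref_params()
  gen <- sim_dataset(seed = 23, n_subjects = 30)
  ds <- handle_blq(gen$dataset)
  fit <- fit_population(ds, p, control = fast_ctl)
  shr <- shrinkage(fit)
  # recompute from the definition
  expect_equal(shr[["eta_cl"]],
               100 * (1 - sd(fit$ebes$eta_cl) /
                        sqrt(fit$params$omega2_cl)),
               tolerance = 1e-8)
  gof <- gof_table(ds, fit)
  expect_equal(shr[["eps"]], 100 * (1 - sd(gof$iwres)),
               tolerance = 1e-8)
  # rich data: low eta shrinkage
  cfg_rich <- study_design(n_subjects = 25,
                           sample_count_probs = c(0, 0, 0, 1),
                           windows = list(c(0.6, 1.5), c(2, 3.5),
                                          c(4, 6), c(7, 9)))
  gen_rich <- generate_study(truth = p, config = cfg_rich, seed = 29)
  fit_rich <- fit_population(handle_blq(gen_rich$dataset), p,
                             control = fast_ctl)
  expect_lt(fit_rich$eta_shrinkage_cl, 25)
})

test_that("parameter recovery over replicate sparse studies is unbiased", {
  truth <- ref_params()
  ests <- t(vapply(1:5, function(r) {
    gen <- sim_dataset(seed = 100 + r)
    fit <- fit_population(handle_blq(gen$dataset), truth,
                          control = fast_ctl)
    c(fit$params$tvcl, fit$params$tvv)
  }, numeric(2)))
  expect_lt(abs(median(ests[, 1]) / truth$tvcl - 1), 0.10)
  expect_lt(abs(median(ests[, 2]) / truth$tvv - 1), 0.10)
})

test_that("stepwise screening returns the base model with no candidates and finds a real effect", {
  truth <- ref_params()
  gen <- sim_dataset(seed = 31, n_subjects = 40)
  ds <- handle_blq(gen$dataset)
  sel0 <- stepwise_covariate_selection(ds, truth, list(),
                                       control = fast_ctl)
  expect_length(sel0$selected, 0)
  expect_equal(sel0$fit$ofv, sel0$base_fit$ofv)

  # inject a strong SCR effect on CL (power exponent 1) and rebuild
  # concentrations so the covariate truly drives the data
  ds_eff <- ds
  scr_med <- median(vapply(ds$subjects, function(s) s$covariates$scr,
                           numeric(1)))
  set.seed(777)
  for (i in seq_along(ds_eff$subjects)) {
    s <- ds_eff$subjects[[i]]
    fac <- (s$covariates$scr / scr_med)^1.0
    cl <- individual_clearance(truth, s$covariates,
                               rnorm(1, 0, sqrt(truth$omega2_cl))) * fac
    v <- individual_volume(truth, s$covariates,
                           rnorm(1, 0, sqrt(truth$omega2_v)))
    mu <- conc_onecpt_infusion(s$observations$time, cl, v, s$doses)
    ds_eff$subjects[[i]]$observations$conc <-
      mu * exp(rnorm(length(mu), 0, sqrt(truth$sigma2)))
    ds_eff$subjects[[i]]$observations$blq <- FALSE
  }
  sel <- stepwise_covariate_selection(
    ds_eff, truth,
    list(covariate_term("cl", "scr", "power"),
         covariate_term("v", "sex", "proportional")),
    control = fast_ctl)
  labs <- vapply(sel$selected, function(x) x$label, character(1))
  expect_true("SCR on CL" %in% labs)
  expect_false("SEX on V" %in% labs)
  expect_true(all(c("step", "term", "dofv", "decision") %in%
                    names(sel$trace)))
})
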