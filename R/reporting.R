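# Configuration, full-pipeline orchestration, and publication-style
# tables and figures.

#' Run configuration for the full analysis pipeline
#'
#' Every stochastic stage carries an explicit seed so reruns are
#' byte-identical. The configuration (including defaults filled in) is
#' serialized alongside the outputs for provenance.
#'
#' @param dataset_path path to an input CSV, or `NULL` to generate a
#'   synthetic study.
#' @param synth_seed,vpc_seed,bootstrap_seed,pta_seed stage seeds.
#' @param n_vpc VPC replicates, default 1000.
#' @param n_bootstrap bootstrap replicates, default 1000.
#' @param n_pta virtual subjects per subgroup, default 10000.
#' @param init starting [pop_params()] for estimation.
#' @param conv [conversion_params()] for the PTA stage.
#' @param blq_policy BLQ handling policy, see [handle_blq()].
#' @param synth_design [study_design()] used when generating synthetic
#'   data (ignored when `dataset_path` is given).
#' @param make_plots write figure files (PNG), default TRUE.
#' @return list of class `run_config`.
#' @export
run_config <- function(dataset_path = NULL, synth_seed = 1,
                       vpc_seed = 2, bootstrap_seed = 3, pta_seed = 4,
                       n_vpc = 1000, n_bootstrap = 1000, n_pta = 10000,
                       init = ceftazidime_neonatal_params(),
                       conv = conversion_params(),
                       blq_policy = "discard",
                       synth_design = study_design(),
                       make_plots = TRUE) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields of [run_config()] may be set in a plain YAML mapping;
#' `init` and `conv` are given as nested mappings of their constructor
#' arguments.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$init)) y$init <- do.call(pop_params, y$init)
  if (!is.null(y$conv)) y$conv <- do.call(conversion_params, y$conv)
  do.call(run_config, y)
}

#' Parameter table of a fit in reporting layout
#'
#' Fixed effects with variability components re-expressed as CV%, with
#' shrinkage, and - when a bootstrap result is supplied - bootstrap
#' medians, percentile 95% CIs, and RSE%.
#'
#' @param fit a `neocef_fit`.
#' @param boot optional `neocef_boot`.
#' @return data frame, one row per reported parameter.
#' @export
parameter_table <- function(fit, boot = NULL) {
  p <- fit$params
  tab <- data.frame(
    parameter = c("CL (L/h/70 kg)", "V (L/70 kg)", "IIV CL (CV%)",
                  "IIV V (CV%)", "Residual (CV%)"),
    estimate = c(p$tvcl, p$tvv, cv_percent(p$omega2_cl),
                 cv_percent(p$omega2_v), cv_percent(p$sigma2)),
    shrinkage = c(NA, NA, fit$eta_shrinkage_cl, fit$eta_shrinkage_v,
                  fit$eps_shrinkage))
  if (!is.null(boot)) {
    s <- boot$summary
    to_cv <- function(col) c(s[[col]][1:2], cv_percent(s[[col]][3:5]))
    tab$boot_median <- to_cv("median")
    tab$boot_lower <- to_cv("lower")
    tab$boot_upper <- to_cv("upper")
    tab$rse <- s$rse
  }
  tab
}

#' VPC plot
#'
#' Observed 5/50/95% quantiles (points and solid lines) against the
#' simulated quantile medians with 95% confidence bands.
#'
#' @param x a `neocef_vpc`.
#' @return a ggplot object.
#' @export
plot_vpc <- function(x) {
  sim <- x$simulated
  obs <- x$observed
  sim$q <- factor(sim$q)
  obs$q <- factor(obs$q)
  ggplot2::ggplot(sim, ggplot2::aes(x = mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi,
                                      group = q),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = med, group = q),
                       linetype = "dashed", colour = "steelblue4") +
    ggplot2::geom_line(data = obs,
                       ggplot2::aes(y = conc, group = q),
                       colour = "black") +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = conc)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time after dose (h)",
                  y = "Concentration (mg/L)",
                  title = "Visual predictive check",
                  subtitle = sprintf(
                    "%d simulations; %.1f%% of observations in the 90%% PI",
                    x$n_sim, x$coverage)) +
    ggplot2::theme_bw()
}

#' PTA plot over the MIC grid
#'
#' One panel per dosing interval, PTA versus MIC by dose level, with
#' the 90% adequacy line.
#'
#' @param x a `neocef_pta`.
#' @param subgroup subgroup label to display (default: first).
#' @return a ggplot object.
#' @export
plot_pta <- function(x, subgroup = NULL) {
  tab <- x$table
  if (is.null(subgroup)) subgroup <- tab$subgroup[1]
  tab <- tab[tab$subgroup == subgroup, ]
  tab$dose <- factor(tab$dose_per_kg)
  tab$interval_lab <- sprintf("q%gh", tab$interval)
  ggplot2::ggplot(tab, ggplot2::aes(x = mic, y = pta,
                                    colour = dose,
                                    group = dose)) +
    ggplot2::geom_hline(yintercept = 90, linetype = "dotted") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = unique(tab$mic)) +
    ggplot2::facet_wrap(~interval_lab) +
    ggplot2::labs(x = "MIC (mg/L)", y = "PTA (%)",
                  colour = "Dose (mg/kg)",
                  title = sprintf(
                    "Probability of attaining %g%% fT>MIC (PMA %s wk)",
                    x$ft_target, subgroup)) +
    ggplot2::theme_bw()
}

#' Goodness-of-fit panel plot
#'
#' Observed versus predicted (population and individual) and CWRES
#' versus prediction and time.
#'
#' @param gof a [gof_table()] data frame.
#' @return a ggplot object.
#' @export
plot_gof <- function(gof) {
  long <- rbind(
    data.frame(x = gof$ipred, y = gof$dv, panel = "DV vs IPRED"),
    data.frame(x = gof$pred, y = gof$dv, panel = "DV vs PRED"),
    data.frame(x = gof$pred, y = gof$cwres, panel = "CWRES vs PRED"),
    data.frame(x = gof$time, y = gof$cwres, panel = "CWRES vs time"))
  ggplot2::ggplot(long, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "grey50") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-data generation (when no dataset path
#' is configured), data preparation (SCR imputation, BLQ handling),
#' population fit, goodness-of-fit table, VPC, bootstrap, and PTA
#' simulation - the PTA stage consumes the *fitted* parameters. All
#' machine-readable outputs (CSV/YAML) and optional figures are written
#' under `out_dir`, and the effective configuration is serialized for
#' provenance. A stage failure marks the bundle partial rather than
#' aborting the run.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the stage results (`dataset`, `fit`,
#'   `gof`, `vpc`, `bootstrap`, `pta`), `partial` flag and `log`.
#' @export
run_full_analysis <- function(config = run_config(), out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(partial = FALSE, log = character())
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    bundle$log <<- c(bundle$log, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      bundle$partial <<- TRUE
      note(name, paste("FAILED:", conditionMessage(e)))
      NULL
    })
  }
  cfg_out <- config
  cfg_out$init <- unclass(config$init)
  cfg_out$conv <- unclass(config$conv)[c("fu", "bp", "bp_direction")]
  cfg_out$synth_design <- lapply(unclass(config$synth_design),
                                 function(x) if (is.list(x)) lapply(x, c)
                                 else c(x))
  yaml::write_yaml(unclass(cfg_out), file.path(out_dir, "config.yaml"))

  if (is.null(config$dataset_path)) {
    gen <- stage("synth", generate_study(truth = config$init,
                                         config = config$synth_design,
                                         seed = config$synth_seed))
    bundle$dataset <- gen$dataset
    note("synth", sprintf("generated %d subjects / %d observations (seed %d)",
                          length(gen$dataset$subjects),
                          n_observations(gen$dataset), config$synth_seed))
    write_pk_dataset(gen$dataset, file.path(out_dir, "dataset.csv"))
  } else {
    bundle$dataset <- stage("read", read_pk_dataset(config$dataset_path))
    note("read", sprintf("read %s", config$dataset_path))
  }
  ds <- stage("prepare", {
    d <- impute_missing_scr(bundle$dataset)
    rep <- attr(d, "scr_imputation")
    note("prepare", sprintf("SCR imputation: %d/%d subjects (%.1f%%)",
                            rep$n_missing, rep$n_subjects,
                            rep$rate_percent))
    d <- handle_blq(d, config$blq_policy)
    note("prepare", sprintf("BLQ policy '%s': %d records affected",
                            config$blq_policy, attr(d, "n_blq")))
    d
  })

  bundle$fit <- stage("fit", fit_population(ds, config$init))
  if (!is.null(bundle$fit)) {
    note("fit", sprintf("OFV %.3f, converged %s", bundle$fit$ofv,
                        bundle$fit$convergence))
    bundle$gof <- stage("gof", gof_table(ds, bundle$fit))
    if (!is.null(bundle$gof))
      utils::write.csv(bundle$gof, file.path(out_dir, "gof.csv"),
                       row.names = FALSE)
    bundle$vpc <- stage("vpc", vpc(ds, bundle$fit$params,
                                   n_sim = config$n_vpc,
                                   seed = config$vpc_seed))
    if (!is.null(bundle$vpc)) {
      note("vpc", sprintf("coverage %.1f%%", bundle$vpc$coverage))
      utils::write.csv(bundle$vpc$simulated,
                       file.path(out_dir, "vpc_simulated.csv"),
                       row.names = FALSE)
      utils::write.csv(bundle$vpc$observed,
                       file.path(out_dir, "vpc_observed.csv"),
                       row.names = FALSE)
    }
    bundle$bootstrap <- stage("bootstrap",
                              bootstrap_fit(ds, bundle$fit$params,
                                            n_replicates = config$n_bootstrap,
                                            seed = config$bootstrap_seed))
    if (!is.null(bundle$bootstrap))
      note("bootstrap", sprintf("%.1f%% converged",
                                bundle$bootstrap$convergence_fraction))
    ptab <- parameter_table(bundle$fit, bundle$bootstrap)
    utils::write.csv(ptab, file.path(out_dir, "parameters.csv"),
                     row.names = FALSE)
    writeLines(utils::capture.output(print(ptab, digits = 4)),
               file.path(out_dir, "parameters.txt"))
    bundle$pta <- stage("pta", pta_table(bundle$fit$params,
                                         n = config$n_pta,
                                         conv = config$conv,
                                         seed = config$pta_seed))
    if (!is.null(bundle$pta))
      utils::write.csv(bundle$pta$table, file.path(out_dir, "pta.csv"),
                       row.names = FALSE)
  }
  if (isTRUE(config$make_plots)) {
    save_plot <- function(p, file)
      suppressMessages(ggplot2::ggsave(file.path(out_dir, file), p,
                                       width = 7, height = 5, dpi = 120))
    if (!is.null(bundle$vpc)) stage("plots",
                                    save_plot(plot_vpc(bundle$vpc),
                                              "vpc.png"))
    if (!is.null(bundle$gof)) stage("plots",
                                    save_plot(plot_gof(bundle$gof),
                                              "gof.png"))
    if (!is.null(bundle$pta)) stage("plots",
                                    save_plot(plot_pta(bundle$pta),
                                              "pta.png"))
  }
  writeLines(bundle$log, file.path(out_dir, "run.log"))
  invisible(bundle)
}
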