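# Independent numerical oracles used to validate the closed-form
# implementation paths. These deliberately take the slow route:
# adaptive ODE integration, Gauss-Hermite quadrature of the exact
# marginal likelihood, dense grid searches and dense profile grids.

# One-compartment infusion concentration by adaptive ODE integration
# (deSolve), integrated piecewise between dose-event discontinuities.
ode_conc_oracle <- function(times, cl, v, doses) {
  k <- cl / v
  rate_at <- function(t) {
    sum(ifelse(t >= doses$time & t < doses$time + doses$infusion_duration,
               doses$amount / doses$infusion_duration, 0))
  }
  breaks <- sort(unique(c(0, doses$time,
                          doses$time + doses$infusion_duration, times)))
  amt <- 0
  conc_out <- numeric(length(times))
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    rate <- rate_at((t0 + t1) / 2)
    sol <- deSolve::ode(y = c(A = amt),
                        times = c(t0, t1),
                        func = function(t, y, p) list(rate - k * y[1]),
                        parms = NULL, method = "lsoda",
                        rtol = 1e-12, atol = 1e-12)
    amt <- unname(sol[nrow(sol), "A"])
    hit <- which(abs(times - t1) < 1e-12)
    conc_out[hit] <- amt / v
  }
  conc_out
}

# Exact -2 log marginal likelihood by 2-D Gauss-Hermite quadrature,
# adapted per subject: nodes are centred/scaled at the conditional mode
# using the curvature of the penalized problem.
quadrature_ofv_oracle <- function(dataset, params, n_nodes = 60) {
  gh <- pracma::gaussHermite(n_nodes)
  s2 <- params$sigma2
  o1 <- params$omega2_cl; o2 <- params$omega2_v
  total <- 0
  for (s in dataset$subjects) {
    o <- s$observations
    y <- log(o$conc)
    pred <- function(e1, e2) {
      cl <- individual_clearance(params, s$covariates, e1)
      v <- individual_volume(params, s$covariates, e2)
      log(conc_onecpt_infusion(o$time, cl, v, s$doses))
    }
    neg_joint <- function(e) {
      r <- y - pred(e[1], e[2])
      sum(r^2) / (2 * s2) + e[1]^2 / (2 * o1) + e[2]^2 / (2 * o2)
    }
    mode <- stats::optim(c(0, 0), neg_joint, method = "BFGS")
    H <- stats::optimHess(mode$par, neg_joint)
    Sig <- solve(H)            # posterior covariance approximation
    L <- t(chol(Sig))
    # integrate p(y|eta) p(eta) with nodes eta = mode + sqrt(2) L z;
    # factor out the joint density at the mode for numerical range
    lp_at <- function(eta) {
      sum(stats::dnorm(y, pred(eta[1], eta[2]), sqrt(s2),
                       log = TRUE)) +
        stats::dnorm(eta[1], 0, sqrt(o1), log = TRUE) +
        stats::dnorm(eta[2], 0, sqrt(o2), log = TRUE)
    }
    lp0 <- lp_at(mode$par)
    val <- 0
    for (a in seq_len(n_nodes)) {
      for (b in seq_len(n_nodes)) {
        z <- c(gh$x[a], gh$x[b])
        eta <- mode$par + sqrt(2) * as.numeric(L %*% z)
        # weight correction for the affine substitution
        val <- val + gh$w[a] * gh$w[b] *
          exp(min(lp_at(eta) - lp0 + sum(z^2), 700))
      }
    }
    val <- val * 2 * sqrt(det(Sig))   # (sqrt 2)^2 * |L|
    total <- total - 2 * (log(val) + lp0)
  }
  total
}

# MAP of (eta_cl, eta_v) for one subject by dense grid search + local
# refinement.
grid_map_oracle <- function(subject, params, half_width = 1.5,
                            n_grid = 121) {
  o <- subject$observations
  y <- log(o$conc)
  neg_joint <- function(e1, e2) {
    cl <- individual_clearance(params, subject$covariates, e1)
    v <- individual_volume(params, subject$covariates, e2)
    r <- y - log(conc_onecpt_infusion(o$time, cl, v, subject$doses))
    sum(r^2) / params$sigma2 + e1^2 / params$omega2_cl +
      e2^2 / params$omega2_v
  }
  g <- seq(-half_width, half_width, length.out = n_grid)
  vals <- outer(g, g, Vectorize(neg_joint))
  best <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  # refine twice around the best node (final resolution ~ 1e-4)
  ctr <- c(g[best[1]], g[best[2]])
  step <- g[2] - g[1]
  for (lvl in 1:2) {
    g1 <- seq(ctr[1] - step, ctr[1] + step, length.out = 41)
    g2 <- seq(ctr[2] - step, ctr[2] + step, length.out = 41)
    vals <- outer(g1, g2, Vectorize(neg_joint))
    best <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    ctr <- c(g1[best[1]], g2[best[2]])
    step <- g1[2] - g1[1]
  }
  ctr
}

# %fT>MIC by dense-grid evaluation (0.001 h) of the finite-dose
# superposition over the steady-state interval.
ft_grid_oracle <- function(cl, v, wt, reg, mic, conv, dt = 0.001) {
  t_start <- steady_state_window(cl, v, reg)
  n_doses <- round(t_start / reg$interval) + 1
  doses <- regimen_doses(reg, wt, n_doses)
  tt <- seq(t_start, t_start + reg$interval, by = dt)
  cb <- conc_onecpt_infusion(tt, cl, v, doses)
  cu <- blood_to_unbound_plasma(cb, conv)
  100 * mean(cu > mic)
}
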