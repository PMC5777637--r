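# shared fixtures, built in code and memoized per test run

.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function(n_patients = 15, seed = 5,
                           variant = "six_state", ...) {
  key <- paste(variant, n_patients, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(n_patients = n_patients, variant = variant,
                      seed = seed, ...)
    .fixture_env[[key]] <- simulate_cohort(cfg)
  }
  .fixture_env[[key]]
}

# a hand-built 2-patient panel: deterministic, small, valid
tiny_panel <- function() {
  mk_pat <- function(pid, times, active_fun, damaged_fun) {
    do.call(rbind, lapply(seq_along(times), function(j) {
      data.frame(patient_id = pid, visit = j, time_years = times[j],
                 joint_id = 1:28, active = active_fun(j),
                 damaged = damaged_fun(j))
    }))
  }
  # patient 1: joint 1 becomes active at visit 2, joint 3 damaged from visit 3
  a1 <- function(j) as.integer(1:28 == 1 & j >= 2)
  d1 <- function(j) as.integer(1:28 == 3 & j >= 3)
  # patient 2: never active, never damaged
  a2 <- function(j) rep(0L, 28)
  d2 <- function(j) rep(0L, 28)
  obs <- rbind(mk_pat(1, c(0, 0.8, 1.5, 2.4), a1, d1),
               mk_pat(2, c(0, 1.0, 2.1), a2, d2))
  patients <- data.frame(patient_id = 1:2, sex = c(1, 0),
                         age_onset = c(35, 42), entry_duration = c(2, 5))
  panel_data(obs, patients)
}

# parameters with no covariates, used for fast fitting tests
plain_params <- function(variant = "six_state", ...) {
  defaults <- if (variant == "six_state") {
    list(
      log_lambda0 = c(act_gain = -1.2, act_loss = 0.4, dmg = -3.0),
      beta = list(act_gain = numeric(), act_loss = numeric(),
                  dmg = numeric()),
      beta_damaged = c(act_gain = -0.2, act_loss = -0.2),
      beta_active_dmg = 1.2,
      beta_stayer = c(act_gain = 1.0, act_loss = 0.2),
      alpha = -0.4, sigma2_u = 1.5, sigma2_v = 1.5, rho = 0, pi = 0.15)
  } else {
    list(
      log_mu0 = c(inactive = 0.8, active = -0.4),
      log_p0 = c(inactive = -2.5, active = -1.5),
      beta = list(soj_inactive = numeric(), soj_active = numeric(),
                  jump_inactive = numeric(), jump_active = numeric()),
      beta_stayer = c(inactive = -1.0, active = -0.2),
      alpha = c(u = -0.4, v = 0.4),
      sigma2_u = 1.5, sigma2_v = 1.5, rho = 0, pi = 0.15)
  }
  args <- utils::modifyList(defaults, list(...))
  do.call(parameter_set, c(list(variant = variant), args))
}

no_covariate_config <- function(variant = "six_state", ...) {
  preds <- jointmsm:::predictor_names(variant)
  model_config(variant,
               covariates = setNames(rep(list(character()), length(preds)),
                                     preds),
               ...)
}

# independent Runge-Kutta oracle for the Kolmogorov forward equations
ode_transition <- function(Q, t) {
  Q <- unclass(Q)
  n <- nrow(Q)
  deriv <- function(t, y, parms) list(as.numeric(matrix(y, n, n) %*% Q))
  out <- deSolve::ode(y = as.numeric(diag(n)), times = c(0, t), func = deriv,
                      parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  matrix(out[2, -1], n, n)
}

# random valid intensity sets per chain kind
random_rates <- function(kind) {
  n <- switch(kind, mover6 = 6, mover5 = 4, stayer = 2)
  stats::rexp(n, rate = stats::runif(1, 0.3, 3))
}

rates_to_generator <- function(kind, r) {
  switch(kind,
    mover6 = build_generator(
      setNames(r, c("l12", "l21", "l13", "l24", "l34", "l43")),
      state_space("six_state", "mover")),
    mover5 = build_generator(
      setNames(r, c("l12", "l21", "l13", "l23")),
      state_space("five_state", "mover")),
    stayer = build_generator(setNames(r, c("l56", "l65")),
                             state_space("six_state", "stayer")))
}

# fixed-effects (u = v = 0) mixture log-likelihood computed through the
# R-level conditional kernel: an independent reference for degenerate limits
reference_fixed_effects_loglik <- function(panel, theta, config) {
  cov <- build_covariates(panel,
                          baseline_ama_proxy = config$baseline_ama_proxy)
  obs <- data.table::as.data.table(panel$obs)
  data.table::setkey(obs, patient_id, joint_id, visit)
  cstar <- observed_mover_indicator(panel)
  six <- config$variant == "six_state"
  cols <- unique(unlist(config$covariates))
  total <- 0
  for (pid in sort(unique(obs$patient_id))) {
    o <- obs[obs$patient_id == pid]
    m <- max(o$visit)
    lm <- 0; ls <- 0
    for (j in 2:(m - 1)) {
      o1 <- o[o$visit == j]; o2 <- o[o$visit == j + 1]
      dt <- o2$time_years[1] - o1$time_years[1]
      z <- cov[cov$patient_id == pid & cov$visit == j]
      for (l in 1:28) {
        zl <- as.list(z[z$joint_id == l, cols, with = FALSE])
        r1 <- o1[o1$joint_id == l]; r2 <- o2[o2$joint_id == l]
        if (six) {
          s1 <- 1 + r1$active + 2 * r1$damaged
          s2 <- 1 + r2$active + 2 * r2$damaged
        } else {
          s1 <- if (r1$damaged == 1) 3 else 1 + r1$active
          s2 <- if (r2$damaged == 1) 3 else 1 + r2$active
        }
        pm <- conditional_interval_prob(theta, zl, s1, s2, dt, 0, 0,
                                        class = "mover")
        lm <- lm + log(pm)
        if (cstar[as.character(pid)] == 0) {
          ps <- conditional_interval_prob(theta, zl, s1, s2, dt, 0, 0,
                                          class = "stayer")
          ls <- ls + log(ps)
        }
      }
    }
    total <- total + if (cstar[as.character(pid)] == 1) {
      log(1 - theta$pi) + lm
    } else if (theta$pi == 0) {
      lm
    } else {
      m0 <- max(log(1 - theta$pi) + lm, log(theta$pi) + ls)
      m0 + log(exp(log(1 - theta$pi) + lm - m0) +
                 exp(log(theta$pi) + ls - m0))
    }
  }
  total
}
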