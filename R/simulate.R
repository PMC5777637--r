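#' Default true parameter set for the synthetic cohort generator
#'
#' Values chosen to emulate the magnitudes seen in clinic cohorts of this
#' kind: slow activation of inactive joints with fast recovery, strong
#' positive dependence of both activation and damage on the activity history
#' (AMA), a stayer subpopulation of 15% with markedly faster activation,
#' moderate observation-level heterogeneity (`sigma2_u ~ 2`) with negative
#' loading on the recovery rate (`alpha = -0.38`), and a damage baseline set
#' so that roughly a third of patients acquire damage over follow-up under
#' the reduced default covariate set.
#'
#' @param variant Model variant.
#' @param covariates Character vector of covariate names for every linear
#'   predictor (default `c("ama", "opposite_damaged", "sex")`).
#' @return A [parameter_set()].
#' @export
default_true_params <- function(variant = c("six_state", "five_state"),
                                covariates = c("ama", "opposite_damaged",
                                               "sex")) {
  variant <- match.arg(variant)
  bt <- function(vals) {
    setNames(vals[seq_along(covariates)], covariates)
  }
  if (variant == "six_state") {
    parameter_set("six_state",
      log_lambda0 = c(act_gain = -3.2, act_loss = 0.8, dmg = -6.5),
      beta = list(act_gain = bt(c(2.7, 0.17, -0.69)),
                  act_loss = bt(c(-0.5, 0.09, 0.02)),
                  dmg = bt(c(2.0, 0.83, 0.2))),
      beta_damaged = c(act_gain = -0.13, act_loss = -0.2),
      beta_active_dmg = 1.6,
      beta_stayer = c(act_gain = 2.0, act_loss = 0.22),
      alpha = -0.38, sigma2_u = 2, sigma2_v = 2, rho = 0.15, pi = 0.15)
  } else {
    parameter_set("five_state",
      log_mu0 = c(inactive = 3.0, active = -0.8),
      log_p0 = c(inactive = -4.5, active = -2.8),
      beta = list(soj_inactive = bt(c(-2.9, -0.28, 0.68)),
                  soj_active = bt(c(0.4, -0.1, 0.01)),
                  jump_inactive = bt(c(-0.25, 1.6, 1.2)),
                  jump_active = bt(c(0.84, 0.54, 0.43))),
      beta_stayer = c(inactive = -1.9, active = -0.17),
      alpha = c(u = -0.35, v = 0.44),
      sigma2_u = 2, sigma2_v = 2, rho = 0.05, pi = 0.15)
  }
}

#' Configuration of the synthetic cohort generator
#'
#' Emulates the structure of a psoriatic arthritis clinic cohort: per-patient
#' visit schedules with lognormal inter-visit gaps (mean 10 months, sd 15
#' months), 28 hand joints in the fixed anatomical layout with contralateral
#' pairing, all joints undamaged at entry, a latent stayer subpopulation, and
#' bivariate normal frailties shared by a patient's joints (drawn per
#' interval for the observation-level structure, once per patient for the
#' patient-level comparator).  Patient covariates: sex ~ Bernoulli(0.55),
#' age at arthritis onset ~ Normal(36.7, 13.3^2) years, arthritis duration at
#' entry ~ Gamma with mean 5.2 and sd 7.2 years.
#'
#' @param n_patients Cohort size.
#' @param variant Model variant to simulate under.
#' @param theta True [parameter_set()]; default [default_true_params()].
#' @param re_structure `"observation"` or `"patient"` random-effect truth.
#' @param visit_range Integer range of visits per patient (uniform draw;
#'   default 4-12).
#' @param gap_mean,gap_sd Mean and sd of inter-visit gaps in years
#'   (lognormal).
#' @param sex_prob,age_mean,age_sd,dur_mean,dur_sd Patient covariate
#'   generators.
#' @param init_active_prob Activity prevalence at clinic entry.
#' @param record_paths Keep the full continuous-time event paths in the
#'   latent record (off by default; the paths can be large).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   config.
#' @return An object of class `jm_sim_config`.
#' @export
sim_config <- function(n_patients = 200,
                       variant = c("six_state", "five_state"),
                       theta = NULL,
                       re_structure = c("observation", "patient"),
                       visit_range = c(4L, 12L),
                       gap_mean = 10 / 12, gap_sd = 1.25,
                       sex_prob = 0.55, age_mean = 36.7, age_sd = 13.3,
                       dur_mean = 5.2, dur_sd = 7.2,
                       init_active_prob = 0.1,
                       record_paths = FALSE, seed = 1L) {
  variant <- match.arg(variant)
  re_structure <- match.arg(re_structure)
  if (is.null(theta)) theta <- default_true_params(variant)
  stopifnot(inherits(theta, "jm_params"), theta$variant == variant,
            n_patients >= 1, visit_range[1] >= 3,
            gap_mean > 0, gap_sd > 0, init_active_prob >= 0,
            init_active_prob <= 1)
  structure(list(n_patients = as.integer(n_patients), variant = variant,
                 theta = theta, re_structure = re_structure,
                 visit_range = as.integer(visit_range),
                 gap_mean = gap_mean, gap_sd = gap_sd,
                 sex_prob = sex_prob, age_mean = age_mean, age_sd = age_sd,
                 dur_mean = dur_mean, dur_sd = dur_sd,
                 init_active_prob = init_active_prob,
                 record_paths = isTRUE(record_paths),
                 seed = as.integer(seed)),
            class = "jm_sim_config")
}

#' Simulate one continuous-time Markov chain interval
#'
#' Exact event-driven simulation: exponential holding times with the state's
#' total exit rate, next state drawn from the jump probabilities (exit rates
#' normalized to sum to one), repeated until the cumulative time exceeds
#' `dt`.
#'
#' @param Q Generator matrix.
#' @param dt Interval length (> 0).
#' @param state Initial state index.
#' @return List with `end_state` and `path` (data.frame of event `time`s in
#'   (0, dt) and the `state` entered; empty if no event occurred).
#' @export
simulate_ctmc_interval <- function(Q, dt, state) {
  stopifnot(dt > 0)
  Q <- unclass(Q)
  n <- nrow(Q)
  t_ev <- numeric(0)
  s_ev <- integer(0)
  cur <- state
  t_cur <- 0
  repeat {
    rate <- -Q[cur, cur]
    if (rate <= 0) break  # absorbing
    t_cur <- t_cur + rexp(1, rate)
    if (t_cur > dt) break
    jp <- Q[cur, ]
    jp[cur] <- 0
    cur <- sample.int(n, 1, prob = jp)
    t_ev <- c(t_ev, t_cur)
    s_ev <- c(s_ev, cur)
  }
  list(end_state = cur, path = data.frame(time = t_ev, state = s_ev))
}

# conditional generator rates for all 28 joints at once (vectorized in z)
sim_rates <- function(theta, variant, z, u, v) {
  bz <- function(beta, zz) {
    if (!length(beta)) return(rep(0, nrow(zz)))
    as.numeric(as.matrix(zz[, names(beta), drop = FALSE]) %*% beta)
  }
  if (variant == "six_state") {
    l12 <- exp(theta$log_lambda0[["act_gain"]] + bz(theta$beta$act_gain, z) + u)
    l21 <- exp(theta$log_lambda0[["act_loss"]] + bz(theta$beta$act_loss, z) +
                 theta$alpha * u)
    l13 <- exp(theta$log_lambda0[["dmg"]] + bz(theta$beta$dmg, z) + v)
    list(l12 = l12, l21 = l21, l13 = l13,
         l24 = l13 * exp(theta$beta_active_dmg),
         l34 = l12 * exp(theta$beta_damaged[["act_gain"]]),
         l43 = l21 * exp(theta$beta_damaged[["act_loss"]]),
         l56 = l12 * exp(theta$beta_stayer[["act_gain"]]),
         l65 = l21 * exp(theta$beta_stayer[["act_loss"]]))
  } else {
    mu1 <- exp(theta$log_mu0[["inactive"]] + bz(theta$beta$soj_inactive, z) + u)
    mu2 <- exp(theta$log_mu0[["active"]] + bz(theta$beta$soj_active, z) +
                 theta$alpha[["u"]] * u)
    o13 <- exp(theta$log_p0[["inactive"]] + bz(theta$beta$jump_inactive, z) + v)
    o23 <- exp(theta$log_p0[["active"]] + bz(theta$beta$jump_active, z) +
                 theta$alpha[["v"]] * v)
    p13 <- o13 / (1 + o13)
    p23 <- o23 / (1 + o23)
    list(l12 = (1 - p13) / mu1, l21 = (1 - p23) / mu2,
         l13 = p13 / mu1, l23 = p23 / mu2,
         l45 = 1 / (mu1 * exp(theta$beta_stayer[["inactive"]])),
         l54 = 1 / (mu2 * exp(theta$beta_stayer[["active"]])))
  }
}

#' Simulate a synthetic clinic cohort
#'
#' Generates a cohort from the data-generating process the models assume:
#' each patient is a latent stayer with probability `pi`; visit times follow
#' the configured schedule; one bivariate normal frailty pair is drawn per
#' patient-interval (observation level) or per patient; dynamic covariates
#' (AMA, attained damaged-joint count, contralateral damage) are computed
#' from the *observed* visit history and held constant over each interval,
#' exactly as the fitted model assumes; each joint then evolves as a
#' continuous-time Markov chain across the interval, and only the states at
#' visit times are recorded in the observed dataset.  All joints start
#' undamaged; activity at entry is Bernoulli.
#'
#' For the first interval (where AMA is undefined) the generator proxies AMA
#' by the activity observed at entry; the default likelihood excludes this
#' interval.
#'
#' @param config A [sim_config()].
#' @return An object of class `jm_cohort`: list with `panel` (a
#'   [panel_data()] object), `latent` (list with `classes`, `effects` and
#'   optionally `paths`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "jm_sim_config"))
  set.seed(config$seed)
  theta <- config$theta
  variant <- config$variant
  layout <- joint_layout()
  dum <- layout_dummies(layout)
  n <- config$n_patients
  # lognormal gap parameters from mean/sd
  s2 <- log(1 + (config$gap_sd / config$gap_mean)^2)
  meanlog <- log(config$gap_mean) - s2 / 2
  sdlog <- sqrt(s2)
  sd_u <- sqrt(theta$sigma2_u)
  sd_v <- sqrt(theta$sigma2_v)
  rho <- theta$rho

  obs_list <- vector("list", n)
  eff_list <- vector("list", n)
  path_list <- if (config$record_paths) vector("list", n)
  classes <- integer(n)  # 1 = mover, 0 = stayer
  sexes <- rbinom(n, 1, config$sex_prob)
  ages <- rnorm(n, config$age_mean, config$age_sd)
  durs <- rgamma(n, shape = (config$dur_mean / config$dur_sd)^2,
                 scale = config$dur_sd^2 / config$dur_mean)

  for (i in seq_len(n)) {
    vr <- config$visit_range
    m <- if (vr[1] == vr[2]) vr[1] else sample(seq(vr[1], vr[2]), 1)
    gaps <- rlnorm(m - 1, meanlog, sdlog)
    times <- c(0, cumsum(gaps))
    mover <- rbinom(1, 1, 1 - theta$pi)
    classes[i] <- mover
    act <- matrix(0L, m, 28)
    dmg <- matrix(0L, m, 28)
    act[1, ] <- rbinom(28, 1, config$init_active_prob)
    u_pat <- rnorm(1, 0, sd_u)
    v_pat <- rho * (sd_v / sd_u) * u_pat +
      rnorm(1, 0, sd_v * sqrt(1 - rho^2))
    eff <- matrix(NA_real_, m - 1, 2)
    paths_i <- if (config$record_paths) vector("list", m - 1)
    for (j in seq_len(m - 1)) {
      if (config$re_structure == "observation") {
        u <- rnorm(1, 0, sd_u)
        v <- rho * (sd_v / sd_u) * u + rnorm(1, 0, sd_v * sqrt(1 - rho^2))
      } else {
        u <- u_pat; v <- v_pat
      }
      eff[j, ] <- c(u, v)
      # covariates from the observed history at the visit opening the interval
      ama_j <- if (j == 1) as.numeric(act[1, ]) else {
        vapply(1:28, function(l) {
          tt <- times[1:j] - times[1]
          xx <- act[1:j, l]
          sum(diff(tt) * (head(xx, -1) + xx[-1]) / 2) / tt[j]
        }, 0.0)
      }
      z <- data.frame(
        ama = ama_j,
        attained_count = sum(dmg[j, ]),
        opposite_damaged = as.numeric(dmg[j, layout$contralateral]),
        sex = sexes[i], age_onset = ages[i],
        duration = durs[i] + times[j],
        jt_mcp = dum$jt_mcp, jt_pip = dum$jt_pip, jt_dip = dum$jt_dip,
        jt_thumb_mcp = dum$jt_thumb_mcp
      )
      r <- sim_rates(theta, variant, z, u, v)
      dtj <- times[j + 1] - times[j]
      ev_paths <- if (config$record_paths) vector("list", 28)
      for (l in 1:28) {
        if (mover == 1) {
          if (variant == "six_state") {
            Q <- matrix(0, 4, 4)
            Q[1, 2] <- r$l12[l]; Q[1, 3] <- r$l13[l]
            Q[2, 1] <- r$l21[l]; Q[2, 4] <- r$l24[l]
            Q[3, 4] <- r$l34[l]; Q[4, 3] <- r$l43[l]
            s0 <- 1L + act[j, l] + 2L * dmg[j, l]
          } else {
            Q <- matrix(0, 3, 3)
            Q[1, 2] <- r$l12[l]; Q[1, 3] <- r$l13[l]
            Q[2, 1] <- r$l21[l]; Q[2, 3] <- r$l23[l]
            s0 <- if (dmg[j, l] == 1L) 3L else 1L + act[j, l]
          }
        } else {
          Q <- matrix(0, 2, 2)
          if (variant == "six_state") {
            Q[1, 2] <- r$l56[l]; Q[2, 1] <- r$l65[l]
          } else {
            Q[1, 2] <- r$l45[l]; Q[2, 1] <- r$l54[l]
          }
          s0 <- 1L + act[j, l]
        }
        diag(Q) <- -rowSums(Q)
        sim <- simulate_ctmc_interval(Q, dtj, s0)
        s1 <- sim$end_state
        if (mover == 1) {
          if (variant == "six_state") {
            act[j + 1, l] <- as.integer(s1 %in% c(2L, 4L))
            dmg[j + 1, l] <- as.integer(s1 >= 3L)
          } else {
            act[j + 1, l] <- as.integer(s1 == 2L)
            dmg[j + 1, l] <- as.integer(s1 == 3L)
          }
        } else {
          act[j + 1, l] <- as.integer(s1 == 2L)
          dmg[j + 1, l] <- 0L
        }
        if (config$record_paths && nrow(sim$path)) {
          ev_paths[[l]] <- data.frame(joint_id = l,
                                      time = times[j] + sim$path$time,
                                      state = sim$path$state)
        }
      }
      if (config$record_paths) {
        keep <- !vapply(ev_paths, is.null, TRUE)
        if (any(keep)) {
          pj <- do.call(rbind, ev_paths[keep])
          pj$interval <- j
          paths_i[[j]] <- pj
        }
      }
    }
    obs_list[[i]] <- data.table(
      patient_id = i,
      visit = rep(seq_len(m), each = 28),
      time_years = rep(times, each = 28),
      joint_id = rep(1:28, m),
      active = as.integer(t(act)),
      damaged = as.integer(t(dmg))
    )
    eff_list[[i]] <- data.table(patient_id = i, interval = seq_len(m - 1),
                                u = eff[, 1], v = eff[, 2])
    if (config$record_paths) {
      keep <- !vapply(paths_i, is.null, TRUE)
      if (any(keep)) {
        pi_dt <- as.data.table(do.call(rbind, paths_i[keep]))
        pi_dt[, patient_id := i]
        path_list[[i]] <- pi_dt
      }
    }
  }
  patients <- data.table(patient_id = seq_len(n), sex = sexes,
                         age_onset = ages, entry_duration = durs)
  panel <- panel_data(rbindlist(obs_list), patients)
  latent <- list(
    classes = data.table(patient_id = seq_len(n), mover = classes),
    effects = rbindlist(eff_list)
  )
  if (config$record_paths) {
    latent$paths <- rbindlist(path_list[!vapply(path_list, is.null, TRUE)])
  }
  structure(list(panel = panel, latent = latent, config = config),
            class = "jm_cohort")
}

#' @export
print.jm_cohort <- function(x, ...) {
  cat(sprintf("<jm_cohort> %d patients (%s, %s-level REs, seed %d)\n",
              x$config$n_patients, x$config$variant,
              x$config$re_structure, x$config$seed))
  cat(sprintf("  movers: %d, stayers: %d\n",
              sum(x$latent$classes$mover == 1),
              sum(x$latent$classes$mover == 0)))
  print(x$panel)
  invisible(x)
}

#' Descriptive summary of a cohort or panel
#'
#' Reports the observed visit-to-visit transition count matrix over the four
#' activity/damage state combinations, the fraction of patients damage free
#' at their last visit, and visit-count and inter-visit gap summaries.
#'
#' @param x A `jm_cohort` or [panel_data()] object.
#' @return An object of class `jm_summary`.
#' @export
summarize_cohort <- function(x) {
  panel <- if (inherits(x, "jm_cohort")) x$panel else x
  stopifnot(inherits(panel, "jm_panel"))
  obs <- as.data.table(panel$obs)
  setkey(obs, patient_id, joint_id, visit)
  obs[, s := 1L + active + 2L * damaged]
  obs[, s_next := shift(s, -1L), by = .(patient_id, joint_id)]
  ir <- obs[!is.na(s_next)]
  labels <- c("inactive/undamaged", "active/undamaged",
              "inactive/damaged", "active/damaged")
  tm <- matrix(0L, 4, 4, dimnames = list(from = labels, to = labels))
  tab <- ir[, .N, by = .(s, s_next)]
  tm[cbind(tab$s, tab$s_next)] <- tab$N
  cstar <- observed_mover_indicator(panel)
  pv <- unique(obs[, .(patient_id, visit, time_years)])
  setkey(pv, patient_id, visit)
  gaps <- pv[, .(gap = diff(time_years)), by = patient_id]$gap
  nv <- pv[, .N, by = patient_id]$N
  structure(list(
    transition_counts = tm,
    n_transitions = sum(tm),
    damage_free_fraction = mean(cstar == 0),
    n_patients = length(cstar),
    visits = summary(nv),
    gap_years = summary(gaps)
  ), class = "jm_summary")
}

#' @export
print.jm_summary <- function(x, ...) {
  cat(sprintf("<jm_summary> %d patients, %d observed transitions\n",
              x$n_patients, x$n_transitions))
  cat("observed transition counts:\n")
  print(x$transition_counts)
  cat(sprintf("damage-free at last visit: %.1f%%\n",
              100 * x$damage_free_fraction))
  cat("visits per patient:\n"); print(x$visits)
  cat("inter-visit gaps (years):\n"); print(x$gap_years)
  invisible(x)
}

#' Write the latent record of a simulated cohort to CSV sidecar files
#'
#' @param cohort A `jm_cohort`.
#' @param stem Path stem; writes `<stem>_classes.csv`, `<stem>_effects.csv`
#'   and, if recorded, `<stem>_paths.csv`.
#' @return Character vector of paths written, invisibly.
#' @export
write_latent_csv <- function(cohort, stem) {
  stopifnot(inherits(cohort, "jm_cohort"))
  paths <- c(paste0(stem, "_classes.csv"), paste0(stem, "_effects.csv"))
  fwrite(cohort$latent$classes, paths[1])
  fwrite(cohort$latent$effects, paths[2])
  if (!is.null(cohort$latent$paths)) {
    p3 <- paste0(stem, "_paths.csv")
    fwrite(cohort$latent$paths, p3)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
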