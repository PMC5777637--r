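test_that("identical seeds give identical cohorts", {
  cfg <- sim_config(n_patients = 6, seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(as.data.frame(c1$panel$obs), as.data.frame(c2$panel$obs))
  expect_identical(c1$latent$effects, c2$latent$effects)
  c3 <- simulate_cohort(sim_config(n_patients = 6, seed = 100))
  expect_false(identical(as.data.frame(c1$panel$obs),
                         as.data.frame(c3$panel$obs)))
})

test_that("stayers never damage and near-degenerate configs behave as limits", {
  # nearly everyone a stayer: no damage anywhere, every c* = 0
  th <- plain_params(pi = 0.999)
  ch <- simulate_cohort(sim_config(n_patients = 12, theta = th, seed = 7))
  stayers <- ch$latent$classes$patient_id[ch$latent$classes$mover == 0]
  expect_gt(length(stayers), 0)
  obs <- as.data.frame(ch$panel$obs)
  expect_true(all(obs$damaged[obs$patient_id %in% stayers] == 0))
  # movers with vanishing damage intensity: no damage either
  th2 <- plain_params(pi = 0.05)
  th2$log_lambda0[["dmg"]] <- -40
  th2$beta_active_dmg <- 0
  ch2 <- simulate_cohort(sim_config(n_patients = 12, theta = th2, seed = 8))
  expect_true(all(ch2$panel$obs$damaged == 0))
  expect_true(all(observed_mover_indicator(ch2$panel) == 0))
})

test_that("event-driven interval simulation matches closed-form laws", {
  sp <- state_space("six_state", "mover")
  # all rates zero: state unchanged, empty path
  Q0 <- build_generator(c(), sp)
  s <- simulate_ctmc_interval(Q0, 5, 2)
  expect_equal(s$end_state, 2)
  expect_equal(nrow(s$path), 0)
  # holding time in state 1 is exponential with mean 1 / total exit rate
  Q <- build_generator(c(l12 = 0.9, l21 = 0.4, l13 = 0.6), sp)
  set.seed(17)
  n <- 2e4
  first_exit <- replicate(n, {
    p <- simulate_ctmc_interval(Q, 100, 1)$path
    if (nrow(p)) p$time[1] else 100
  })
  mu <- 1 / 1.5
  expect_lt(abs(mean(first_exit) - mu), 3 * mu / sqrt(n))
  # end-state distribution at dt matches the transition matrix row
  dt <- 0.8
  ends <- replicate(n, simulate_ctmc_interval(Q, dt, 1)$end_state)
  P <- transition_matrix(Q, dt)
  for (state in 1:4) {
    phat <- mean(ends == state)
    p0 <- P[1, state]
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(phat - p0), 3 * se + 1e-12)
  }
})

test_that("with no heterogeneity the observed joints are iid chains with baseline rates", {
  th <- plain_params()
  th$sigma2_u <- 1e-12; th$sigma2_v <- 1e-12
  th$pi <- 1e-9  # essentially all movers
  th$beta_damaged[] <- 0; th$beta_active_dmg <- 0
  cfg <- sim_config(n_patients = 40, theta = th, seed = 23,
                    visit_range = c(3L, 3L), init_active_prob = 0)
  ch <- simulate_cohort(cfg)
  obs <- data.table::as.data.table(ch$panel$obs)
  data.table::setkey(obs, patient_id, joint_id, visit)
  obs[, s := 1L + active + 2L * damaged]
  obs[, `:=`(s_next = data.table::shift(s, -1L),
             t_next = data.table::shift(time_years, -1L)),
      by = .(patient_id, joint_id)]
  ir <- obs[!is.na(s_next) & s == 1L]
  # pool intervals with similar length and compare with the matrix exponential
  ir[, dt := t_next - time_years]
  band <- ir[dt > 0.3 & dt < 1.0]
  rates <- conditional_intensities(th, list(), class = "mover")
  Q <- build_generator(rates, state_space("six_state", "mover"))
  expected <- vapply(band$dt, function(d) transition_matrix(Q, d)[1, 2], 0.0)
  phat <- mean(band$s_next == 2L)
  p0 <- mean(expected)
  se <- sqrt(p0 * (1 - p0) / nrow(band))
  expect_lt(abs(phat - p0), 4 * se)
})

test_that("cohort summary bookkeeping is exact", {
  ch <- fixture_cohort(10, seed = 31)
  sm <- summarize_cohort(ch)
  obs <- as.data.frame(ch$panel$obs)
  m_i <- tapply(obs$visit, obs$patient_id, max)
  expect_equal(sm$n_transitions, sum((m_i - 1) * 28))
  # damaged -> undamaged blocks are zero
  expect_true(all(sm$transition_counts[3:4, 1:2] == 0))
  expect_equal(sm$n_patients, 10)
  expect_equal(sm$damage_free_fraction,
               mean(observed_mover_indicator(ch$panel) == 0))
})

test_that("latent record aligns with the observed panel", {
  cfg <- sim_config(n_patients = 5, seed = 13, record_paths = TRUE)
  ch <- simulate_cohort(cfg)
  obs <- as.data.frame(ch$panel$obs)
  m_i <- tapply(obs$visit, obs$patient_id, max)
  expect_equal(nrow(ch$latent$effects), sum(m_i - 1))
  expect_equal(nrow(ch$latent$classes), 5)
  # recorded event paths stay inside their intervals
  if (!is.null(ch$latent$paths) && nrow(ch$latent$paths)) {
    times <- unique(obs[, c("patient_id", "visit", "time_years")])
    last <- tapply(times$time_years, times$patient_id, max)
    expect_true(all(ch$latent$paths$time <=
                      last[as.character(ch$latent$paths$patient_id)]))
  }
})
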