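test_that("conditional intensities follow the regression structure", {
  theta <- default_true_params("six_state")
  z0 <- list(ama = 0, opposite_damaged = 0, sex = 0)
  r <- conditional_intensities(theta, z0, u = 0, v = 0, class = "mover")
  expect_equal(unname(r["l12"]), exp(theta$log_lambda0[["act_gain"]]))
  expect_equal(unname(r["l21"]), exp(theta$log_lambda0[["act_loss"]]))
  expect_equal(unname(r["l13"]), exp(theta$log_lambda0[["dmg"]]))
  # proportional offsets
  expect_equal(unname(r["l24"] / r["l13"]), exp(theta$beta_active_dmg))
  expect_equal(unname(r["l34"] / r["l12"]),
               exp(theta$beta_damaged[["act_gain"]]))
  rs <- conditional_intensities(theta, z0, class = "stayer")
  expect_equal(unname(rs["l56"] / r["l12"]),
               exp(theta$beta_stayer[["act_gain"]]))
  expect_equal(unname(rs["l65"] / r["l21"]),
               exp(theta$beta_stayer[["act_loss"]]))
  # random effects enter with loading alpha on the recovery rate
  ru <- conditional_intensities(theta, z0, u = 0.7, v = -0.2, class = "mover")
  expect_equal(unname(ru["l12"] / r["l12"]), exp(0.7))
  expect_equal(unname(ru["l21"] / r["l21"]), exp(theta$alpha * 0.7))
  expect_equal(unname(ru["l13"] / r["l13"]), exp(-0.2))
  # five-state: odds inverse for the jump probability
  th5 <- default_true_params("five_state")
  r5 <- conditional_intensities(th5, z0, u = 0, v = 0.5, class = "mover")
  sj <- attr(r5, "sojourn_jump")
  o <- exp(th5$log_p0[["inactive"]]) * exp(0.5)
  expect_equal(unname(sj["p13"]), o / (1 + o))
  expect_equal(unname(sj["mu1"]), exp(th5$log_mu0[["inactive"]]))
  # bijection consistency
  expect_equal(unname(r5["l12"]), unname((1 - sj["p13"]) / sj["mu1"]))
})

test_that("structurally impossible stayer transitions have probability zero", {
  theta <- plain_params()
  z0 <- list()
  p <- conditional_interval_prob(theta, z0, 1, 3, 1, 0, 0, class = "stayer")
  expect_identical(p, 0)
  # mover with all rates ~0: same state prob 1, move prob 0
  th0 <- theta
  th0$log_lambda0[] <- -50
  p_same <- conditional_interval_prob(th0, z0, 2, 2, 1, 0, 0, class = "mover")
  p_move <- conditional_interval_prob(th0, z0, 1, 2, 1, 0, 0, class = "mover")
  expect_equal(p_same, 1, tolerance = 1e-10)
  expect_equal(p_move, 0, tolerance = 1e-10)
  # continuity at the identity: dt -> 0 gives log-prob -> 0 for same state
  p_small <- conditional_interval_prob(theta, z0, 1, 1, 1e-9, 0, 0,
                                       class = "mover")
  expect_equal(log(p_small), 0, tolerance = 1e-6)
})

test_that("one-node quadrature equals the conditional likelihood at u = v = 0", {
  theta <- plain_params()
  set.seed(3)
  z <- data.frame(row.names = 1:5)  # five joints, no covariates
  from <- c(1, 1, 2, 1, 2); to <- c(1, 2, 2, 1, 1)
  m1 <- interval_marginal_lik(theta, z, from, to, 0.9, "mover", nodes = 1)
  cond <- prod(vapply(seq_along(from), function(l) {
    conditional_interval_prob(theta, list(), from[l], to[l], 0.9, 0, 0,
                              class = "mover")
  }, 0.0))
  expect_equal(m1, cond, tolerance = 1e-12)
  # degenerate variances reproduce the same value with many nodes
  th0 <- theta; th0$sigma2_u <- 1e-14; th0$sigma2_v <- 1e-14
  m0 <- interval_marginal_lik(th0, z, from, to, 0.9, "mover", nodes = 15)
  expect_equal(m0, cond, tolerance = 1e-6)
})

test_that("quadrature marginal matches Monte-Carlo integration", {
  theta <- default_true_params("six_state")
  z <- list(ama = 0.25, opposite_damaged = 0, sex = 1)
  q <- interval_marginal_lik(theta, as.data.frame(z), 1, 2, 0.8, "mover",
                             nodes = 40)
  set.seed(77)
  n <- 2e5
  u <- rnorm(n, 0, sqrt(theta$sigma2_u))
  v <- theta$rho * sqrt(theta$sigma2_v / theta$sigma2_u) * u +
    rnorm(n, 0, sqrt(theta$sigma2_v * (1 - theta$rho^2)))
  p <- conditional_interval_prob(theta, z, 1, 2, 0.8, u, v, class = "mover")
  expect_lt(abs(mean(p) - q), 3 * sd(p) / sqrt(n))
})

test_that("increasing quadrature nodes is Cauchy convergent and single factors stabilize", {
  ch <- fixture_cohort(8, seed = 41)
  theta <- default_true_params("six_state")
  lls <- vapply(c(10, 20, 40, 80), function(nd) {
    total_loglik(ch$panel, theta, model_config("six_state", nodes = nd))
  }, 0.0)
  d <- abs(diff(lls))
  expect_true(all(diff(d) < 0))  # successive refinements shrink
  # a typical single-interval factor moves < 1e-4 in log on 15 -> 30 doubling
  z <- data.frame(ama = c(0, 0.2, 0), opposite_damaged = c(0, 0, 1),
                  sex = c(1, 1, 1))
  l15 <- log(interval_marginal_lik(theta, z, c(1, 2, 1), c(1, 1, 1), 0.7,
                                   "mover", nodes = 15))
  l30 <- log(interval_marginal_lik(theta, z, c(1, 2, 1), c(1, 1, 1), 0.7,
                                   "mover", nodes = 30))
  expect_lt(abs(l15 - l30), 1e-4)
})

test_that("mixture structure: pi = 0 collapse, c* = 1 exponent form, bounds", {
  ch <- fixture_cohort(10, seed = 31)
  mc <- model_config("six_state", nodes = 7)
  theta <- default_true_params("six_state")
  cstar <- observed_mover_indicator(ch$panel)
  th0 <- theta; th0$pi <- 0
  ll0 <- total_loglik(ch$panel, th0, mc, per_patient = TRUE)
  # with pi = 0 the stayer branch must be irrelevant
  th0b <- th0
  th0b$beta_stayer[] <- c(5, -5)
  expect_equal(total_loglik(ch$panel, th0b, mc, per_patient = TRUE), ll0)
  # c* = 1 patients contribute log(1 - pi) + log L(mover) exactly
  thp <- theta; thp$pi <- 0.3
  llp <- total_loglik(ch$panel, thp, mc, per_patient = TRUE)
  movers <- names(cstar)[cstar == 1]
  expect_equal(llp[movers], ll0[movers] + log(1 - 0.3), tolerance = 1e-12)
  # c* = 0 patients: mixture between the class log-likelihoods
  stayer_like <- names(cstar)[cstar == 0]
  expect_true(all(llp[stayer_like] >= ll0[stayer_like] + log(1 - 0.3) - 1e-10))
})

test_that("log-likelihood is invariant to joint relabeling and patient order, and additive", {
  ch <- fixture_cohort(8, seed = 41)
  mc <- model_config("six_state", nodes = 5)
  theta <- default_true_params("six_state")
  ll <- total_loglik(ch$panel, theta, mc, per_patient = TRUE)
  # relabel joints within every patient by a fixed permutation of pairs
  # (swap hands: joint k <-> k + 14 keeps types and pairing intact)
  obs2 <- as.data.frame(ch$panel$obs)
  obs2$joint_id <- ifelse(obs2$joint_id <= 14, obs2$joint_id + 14,
                          obs2$joint_id - 14)
  p2 <- panel_data(obs2, as.data.frame(ch$panel$patients))
  expect_equal(total_loglik(p2, theta, mc), sum(ll), tolerance = 1e-10)
  # patient order invariance
  obs3 <- as.data.frame(ch$panel$obs)
  obs3$patient_id <- max(obs3$patient_id) + 1 - obs3$patient_id
  pats3 <- as.data.frame(ch$panel$patients)
  pats3$patient_id <- max(pats3$patient_id) + 1 - pats3$patient_id
  p3 <- panel_data(obs3, pats3)
  expect_equal(total_loglik(p3, theta, mc), sum(ll), tolerance = 1e-10)
  # duplicating every patient doubles the log-likelihood
  obs4 <- as.data.frame(ch$panel$obs)
  obs4b <- obs4; obs4b$patient_id <- obs4b$patient_id + 1000
  pats4 <- as.data.frame(ch$panel$patients)
  pats4b <- pats4; pats4b$patient_id <- pats4b$patient_id + 1000
  p4 <- panel_data(rbind(obs4, obs4b), rbind(pats4, pats4b))
  expect_equal(total_loglik(p4, theta, mc), 2 * sum(ll), tolerance = 1e-8)
})

test_that("degenerate variances match an independent fixed-effects evaluation", {
  ch <- fixture_cohort(6, seed = 51)
  mc <- model_config("six_state", nodes = 15)
  theta <- default_true_params("six_state")
  th0 <- theta; th0$sigma2_u <- 1e-14; th0$sigma2_v <- 1e-14
  ll_quad <- total_loglik(ch$panel, th0, mc)
  ll_ref <- reference_fixed_effects_loglik(ch$panel, th0, mc)
  expect_equal(ll_quad, ll_ref, tolerance = 1e-6)
})

test_that("patient-level and observation-level structures agree on single-interval patients", {
  # three visits per patient -> exactly one usable interval each
  ch <- fixture_cohort(8, seed = 61, visit_range = c(3L, 3L))
  mc <- model_config("six_state", nodes = 9)
  theta <- default_true_params("six_state")
  ll_obs <- total_loglik(ch$panel, theta, mc)
  ll_pat <- patient_level_loglik(ch$panel, theta, mc, nodes = 9)
  expect_equal(ll_obs, ll_pat, tolerance = 1e-8)
  # with several intervals and nonzero variance they generally differ
  ch2 <- fixture_cohort(8, seed = 41)
  ll_obs2 <- total_loglik(ch2$panel, theta, mc)
  ll_pat2 <- patient_level_loglik(ch2$panel, theta, mc, nodes = 15)
  expect_gt(abs(ll_obs2 - ll_pat2), 1e-3)
})

test_that("five-state likelihood responds to its parameterization", {
  ch <- fixture_cohort(8, seed = 71, variant = "five_state")
  mc <- model_config("five_state", nodes = 7)
  theta <- default_true_params("five_state")
  ll <- total_loglik(ch$panel, theta, mc)
  expect_true(is.finite(ll))
  # perturbing the sojourn baseline changes the likelihood
  th2 <- theta; th2$log_mu0[["inactive"]] <- th2$log_mu0[["inactive"]] + 1
  expect_false(isTRUE(all.equal(total_loglik(ch$panel, th2, mc), ll)))
  # truth should beat a clearly wrong parameter set on its own data
  th3 <- theta; th3$log_mu0[] <- c(-2, 3); th3$pi <- 0.7
  expect_gt(ll, total_loglik(ch$panel, th3, mc))
})
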