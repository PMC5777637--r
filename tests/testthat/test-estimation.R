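test_that("working-scale transform is a bijection with the documented links", {
  set.seed(5)
  for (variant in c("six_state", "five_state")) {
    theta <- default_true_params(variant)
    w <- theta_to_working(theta)
    back <- working_to_theta(w, theta)
    expect_equal(theta_to_working(back), w, tolerance = 1e-12)
    expect_equal(back$sigma2_u, theta$sigma2_u, tolerance = 1e-12)
    expect_equal(back$pi, theta$pi, tolerance = 1e-12)
  }
  th <- plain_params()
  th$pi <- 0.5
  expect_equal(unname(theta_to_working(th)["logit_pi"]), 0)
  th$sigma2_u <- 1
  expect_equal(unname(theta_to_working(th)["log_sigma2_u"]), 0)
  th$pi <- 0
  expect_error(theta_to_working(th), "boundary")
})

test_that("parameter sets enforce their constraints", {
  expect_error(parameter_set("six_state", sigma2_u = -1), "positive")
  expect_error(parameter_set("six_state", rho = 1.2), "rho")
  expect_error(parameter_set("six_state", pi = 1), "pi")
  expect_error(parameter_set("six_state", nonsense = 1), "unknown")
})

fit_small <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      ch <- fixture_cohort(25, seed = 81, theta = plain_params())
      mc <- no_covariate_config(nodes = 5)
      memo <<- list(
        cohort = ch, config = mc,
        fit = fit_mover_stayer(ch$panel, mc, maxit = 300)
      )
    }
    memo
  }
})

test_that("maximum-likelihood fit converges to a stationary point", {
  fs <- fit_small()
  fit <- fs$fit
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-2)
  # reported log-likelihood equals a re-evaluation at the estimates
  expect_equal(fit$loglik,
               total_loglik(fs$cohort$panel, fit$estimates, fs$config),
               tolerance = 1e-8)
  # refitting from the optimum barely moves the likelihood
  refit <- fit_mover_stayer(fs$cohort$panel, fs$config,
                            start = fit$estimates, maxit = 100,
                            hessian = FALSE)
  expect_lt(abs(refit$loglik - fit$loglik), 1e-6)
})

test_that("standard errors and intervals respect the parameter constraints", {
  fit <- fit_small()$fit
  expect_true(all(is.finite(fit$se)))
  ci <- fit$ci
  # variance intervals positive, pi interval inside (0, 1)
  expect_true(all(ci[c("log_sigma2_u", "log_sigma2_v"), ] > 0))
  expect_true(all(ci["logit_pi", ] > 0 & ci["logit_pi", ] < 1))
  # untransformed coefficients have symmetric intervals
  bs <- "beta_stayer.act_gain"
  expect_equal(ci[bs, "upper"] - ci[bs, "estimate"],
               ci[bs, "estimate"] - ci[bs, "lower"], tolerance = 1e-8)
  # asymmetric after back-transform for the variance
  lsu <- "log_sigma2_u"
  expect_false(isTRUE(all.equal(ci[lsu, "upper"] - ci[lsu, "estimate"],
                                ci[lsu, "estimate"] - ci[lsu, "lower"])))
})

test_that("profile likelihood at the MLE of pi recovers the maximized value", {
  fs <- fit_small()
  fit <- fs$fit
  prof <- profile_pi(fs$cohort$panel, fs$config,
                     grid = fit$estimates$pi, fit = fit, maxit = 50)
  expect_equal(prof$loglik[1], fit$loglik, tolerance = 1e-4)
})

test_that("fit serializes to JSON with finite numbers", {
  fit <- fit_small()$fit
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_fit_json(fit, tmp, seed = 81)
  parsed <- jsonlite::read_json(tmp)
  expect_equal(parsed$variant, "six_state")
  expect_equal(parsed$loglik, fit$loglik, tolerance = 1e-12)
  expect_true(all(is.finite(unlist(parsed$se))))
})

test_that("fixed parameters are honored and reported", {
  fs <- fit_small()
  f <- fit_mover_stayer(fs$cohort$panel, fs$config,
                        fixed = c(logit_pi = qlogis(0.15)),
                        maxit = 100, hessian = FALSE)
  expect_equal(f$estimates$pi, 0.15, tolerance = 1e-12)
  expect_false("logit_pi" %in% f$free)
  expect_error(fit_mover_stayer(fs$cohort$panel, fs$config,
                                fixed = c(bogus = 1), maxit = 5),
               "unknown fixed")
})

test_that("five-state model fits and maps back to sojourn/jump quantities", {
  th <- plain_params("five_state")
  ch <- fixture_cohort(20, seed = 91, variant = "five_state", theta = th)
  mc <- no_covariate_config("five_state", nodes = 3)
  fit <- suppressWarnings(fit_mover_stayer(ch$panel, mc, maxit = 250,
                                           hessian = FALSE))
  expect_true(fit$converged)
  expect_equal(fit$loglik, total_loglik(ch$panel, fit$estimates, mc),
               tolerance = 1e-8)
  # baseline sojourn time of the inactive state lands near the truth
  expect_lt(abs(fit$estimates$log_mu0[["inactive"]] -
                  th$log_mu0[["inactive"]]), 1.0)
  # fitted baselines translate into valid intensities
  r <- conditional_intensities(fit$estimates, list(), class = "mover")
  expect_true(all(r > 0))
  sj <- intensities_to_sojourn_jump(r)
  expect_gt(sj[["mu1"]], 0)
  expect_true(sj[["p13"]] > 0 && sj[["p13"]] < 1)
})

test_that("crude starting values are interior and finite", {
  ch <- fixture_cohort(10, seed = 31)
  for (variant in c("six_state", "five_state")) {
    mc <- model_config(variant)
    st <- crude_start(ch$panel, mc)
    w <- theta_to_working(st)
    expect_true(all(is.finite(w)))
    expect_gt(st$pi, 0); expect_lt(st$pi, 1)
  }
})
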