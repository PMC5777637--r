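# central-difference Hessian on the working scale (default step 1e-4)
numeric_hessian <- function(fn, x, step = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xm <- x
        xp[i] <- x[i] + step; xm[i] <- x[i] - step
        H[i, i] <- (fn(xp) - 2 * fn(x) + fn(xm)) / step^2
      } else {
        xpp <- x; xpm <- x; xmp <- x; xmm <- x
        xpp[c(i, j)] <- x[c(i, j)] + step
        xmm[c(i, j)] <- x[c(i, j)] - step
        xpm[i] <- x[i] + step; xpm[j] <- x[j] - step
        xmp[i] <- x[i] - step; xmp[j] <- x[j] + step
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * step^2)
      }
    }
  }
  dimnames(H) <- list(names(x), names(x))
  H
}

numeric_gradient <- function(fn, x, step = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + step; xm[i] <- x[i] - step
    (fn(xp) - fn(xm)) / (2 * step)
  }, 0.0)
}

#' Starting values from crude transition counts
#'
#' Baseline intensities from observed transition counts divided by approximate
#' person-time at risk (ignoring clustering and interval censoring);
#' regression coefficients start at zero, variances at 0.5, correlation at 0,
#' and the stayer probability at one fifth of the observed damage-free
#' fraction.
#'
#' @param panel A [panel_data()] object.
#' @param config A [model_config()].
#' @return A [parameter_set()] suitable as `start` for [fit_mover_stayer()].
#' @export
crude_start <- function(panel, config) {
  obs <- as.data.table(panel$obs)
  setkey(obs, patient_id, joint_id, visit)
  obs[, `:=`(act_next = shift(active, -1L), dmg_next = shift(damaged, -1L),
             t_next = shift(time_years, -1L)),
      by = .(patient_id, joint_id)]
  ir <- obs[!is.na(t_next)]
  ir[, dt := t_next - time_years]
  # crude rates: events / person-time in the originating activity state
  t_inact <- sum(ir[active == 0 & damaged == 0, dt])
  t_act <- sum(ir[active == 1 & damaged == 0, dt])
  n_gain <- nrow(ir[active == 0 & act_next == 1])
  n_loss <- nrow(ir[active == 1 & act_next == 0])
  n_dmg <- nrow(ir[damaged == 0 & dmg_next == 1])
  t_undmg <- sum(ir[damaged == 0, dt])
  rate <- function(n, t) max(n, 0.5) / max(t, 1e-8)
  l_gain <- rate(n_gain, t_inact + t_act)
  l_loss <- rate(n_loss, t_act + t_inact)
  l_dmg <- rate(n_dmg, t_undmg)
  cstar <- observed_mover_indicator(panel)
  pi0 <- max(0.02, 0.2 * mean(cstar == 0))
  empty_beta <- function(cols) setNames(rep(0, length(cols)), cols)
  if (config$variant == "six_state") {
    parameter_set("six_state",
      log_lambda0 = c(act_gain = log(l_gain), act_loss = log(l_loss),
                      dmg = log(l_dmg)),
      beta = lapply(config$covariates, empty_beta),
      sigma2_u = 0.5, sigma2_v = 0.5, rho = 0, pi = pi0)
  } else {
    parameter_set("five_state",
      log_mu0 = c(inactive = log(1 / max(l_gain + l_dmg, 1e-8)),
                  active = log(1 / max(l_loss + l_dmg, 1e-8))),
      log_p0 = c(inactive = log(max(l_dmg / max(l_gain, 1e-8), 1e-4)),
                 active = log(max(l_dmg / max(l_loss, 1e-8), 1e-4))),
      beta = lapply(config$covariates, empty_beta),
      sigma2_u = 0.5, sigma2_v = 0.5, rho = 0, pi = pi0)
  }
}

#' Fit a clustered mover-stayer multistate model by maximum likelihood
#'
#' Maximizes the marginal log-likelihood [total_loglik()] on the unconstrained
#' working scale (see [theta_to_working()]) with the BFGS quasi-Newton routine
#' of [stats::optim()].  Standard errors come from inverting the numerically
#' derived (central-difference) Hessian at the maximum; 95% Wald intervals are
#' formed on the working scale and back-transformed, giving asymmetric
#' intervals for variances and the stayer proportion.
#'
#' @param panel A [panel_data()] object.
#' @param config A [model_config()].
#' @param start Optional [parameter_set()] of starting values; defaults to
#'   [crude_start()].
#' @param fixed Named numeric vector of working-scale parameters to hold
#'   fixed (e.g. `c(logit_pi = qlogis(0.1))`).
#' @param maxit Maximum BFGS iterations.
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @param hessian Compute the numerical Hessian and standard errors.
#' @param hessian_step Central-difference step on the working scale.
#' @param grad_tol Gradient max-norm above which a warning flags possible
#'   non-convergence.
#' @param trace Print optimizer progress.
#'
#' @return An object of class `jm_fit` with elements `estimates`
#'   (a [parameter_set()]), `loglik`, `working` (estimate vector), `se`,
#'   `ci` (natural-scale 95% intervals), `hessian`, `vcov`,
#'   `convergence` (0 = converged), `grad_norm`, `counts`, `config`,
#'   `n_patients`, `fixed`.
#' @export
fit_mover_stayer <- function(panel, config, start = NULL, fixed = NULL,
                             maxit = 500, reltol = 1e-8, hessian = TRUE,
                             hessian_step = 1e-4, grad_tol = 1e-3,
                             trace = 0) {
  ctx <- if (inherits(panel, "jm_lik_context")) panel else
    build_lik_context(panel, config)
  if (is.null(start)) {
    if (inherits(panel, "jm_lik_context")) {
      stop("start must be supplied when fitting from a prebuilt context")
    }
    start <- crude_start(panel, config)
  }
  stopifnot(inherits(start, "jm_params"))
  w0 <- theta_to_working(start)
  free <- setdiff(names(w0), names(fixed))
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), names(w0))
    if (length(unknown)) {
      stop("unknown fixed parameter(s): ", paste(unknown, collapse = ", "))
    }
    w0[names(fixed)] <- fixed
  }
  assemble <- function(wf) {
    w <- w0
    w[free] <- wf
    w
  }
  negll <- function(wf) {
    w <- assemble(wf)
    theta <- working_to_theta(w, start)
    ll <- tryCatch(ctx_loglik(ctx, theta), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  f0 <- negll(w0[free])
  if (f0 >= 1e10) {
    stop("log-likelihood is not finite at the starting values")
  }
  opt <- optim(w0[free], negll, method = "BFGS",
               control = list(maxit = maxit, reltol = reltol,
                              ndeps = rep(1e-5, length(free)),
                              trace = trace, REPORT = 1))
  w_hat <- assemble(opt$par)
  theta_hat <- working_to_theta(w_hat, start)
  loglik <- -negll(opt$par)
  grad <- numeric_gradient(negll, opt$par)
  grad_norm <- max(abs(grad))
  converged <- opt$convergence == 0
  if (!converged) {
    warning("optimizer did not converge (code ", opt$convergence, ")")
  } else if (grad_norm > grad_tol) {
    warning(sprintf(
      "gradient max-norm %.3g exceeds tolerance %.3g at the optimum",
      grad_norm, grad_tol))
  }
  se <- ci <- vcov <- H <- NULL
  if (hessian) {
    H <- numeric_hessian(negll, opt$par, step = hessian_step)
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vcov) || any(diag(vcov) <= 0)) {
      ev <- eigen(H, symmetric = TRUE)
      flat <- names(w_hat[free])[which.max(abs(ev$vectors[, length(free)]))]
      stop("Hessian is not positive definite at the optimum; ",
           "flattest direction is dominated by '", flat, "'")
    }
    se <- setNames(sqrt(diag(vcov)), free)
    lo <- opt$par - 1.96 * se
    hi <- opt$par + 1.96 * se
    tr <- working_transforms(free)
    back <- function(x) {
      vapply(seq_along(x), function(i) switch(tr[i],
        exp = exp(x[i]), tanh = tanh(x[i]), plogis = plogis(x[i]),
        x[i]), 0.0)
    }
    ci <- cbind(lower = back(lo), estimate = back(opt$par),
                upper = back(hi))
    rownames(ci) <- free
  }
  structure(list(
    estimates = theta_hat, loglik = loglik, working = w_hat,
    free = free, fixed = fixed, se = se, ci = ci, hessian = H, vcov = vcov,
    convergence = opt$convergence, converged = converged,
    grad_norm = grad_norm, counts = opt$counts, config = config,
    n_patients = length(ctx$pat_ids), n_parameters = length(free),
    skeleton = start
  ), class = "jm_fit")
}

#' @export
print.jm_fit <- function(x, ...) {
  cat(sprintf(
    "<jm_fit> %s model, %s-level random effects\n", x$config$variant,
    x$config$re_structure))
  cat(sprintf("  %d patients, %d free parameters\n", x$n_patients,
              x$n_parameters))
  cat(sprintf("  log-likelihood: %.4f  (converged: %s, |grad|max = %.2e)\n",
              x$loglik, x$converged, x$grad_norm))
  if (!is.null(x$ci)) {
    cat("  estimates (natural scale, 95% Wald):\n")
    tab <- cbind(x$ci[, "estimate"], x$ci[, "lower"], x$ci[, "upper"],
                 x$se)
    colnames(tab) <- c("estimate", "lower", "upper", "se(working)")
    print(round(tab, 4))
  }
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes estimates, working-scale values, standard errors, intervals,
#' log-likelihood, configuration and package version to a JSON file.
#'
#' @param fit A `jm_fit`.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  out <- list(
    package = "jointmsm",
    version = as.character(utils::packageVersion("jointmsm")),
    variant = fit$config$variant,
    re_structure = fit$config$re_structure,
    nodes = fit$config$nodes,
    loglik = fit$loglik,
    converged = fit$converged,
    grad_norm = fit$grad_norm,
    n_patients = fit$n_patients,
    working_estimates = as.list(fit$working),
    se = as.list(fit$se),
    ci = if (!is.null(fit$ci)) {
      stats::setNames(
        lapply(rownames(fit$ci), function(r) as.list(fit$ci[r, ])),
        rownames(fit$ci))
    },
    fixed = as.list(fit$fixed),
    seed = seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Profile log-likelihood for the stayer proportion
#'
#' For each grid value of `pi`, maximizes the log-likelihood over all other
#' parameters (warm-started from the supplied fit).  The full-model MLE of
#' `pi` should attain the maximum of the curve up to grid resolution.
#'
#' @param panel A [panel_data()] object.
#' @param config A [model_config()].
#' @param grid Numeric vector of `pi` values strictly inside (0, 1).
#' @param fit Optional full [fit_mover_stayer()] result used for warm starts.
#' @param maxit BFGS iteration cap per grid point.
#'
#' @return An object of class `jm_profile`: data.frame with `pi`, `loglik`,
#'   `converged`, plus attributes `argmax` and `fit_pi` (the full-model MLE
#'   if `fit` was supplied).
#' @export
profile_pi <- function(panel, config, grid, fit = NULL, maxit = 100) {
  stopifnot(all(grid > 0 & grid < 1))
  ctx <- if (inherits(panel, "jm_lik_context")) panel else
    build_lik_context(panel, config)
  start <- if (!is.null(fit)) fit$estimates else crude_start(panel, config)
  res <- lapply(grid, function(p) {
    f <- fit_mover_stayer(ctx, config, start = start,
                          fixed = c(logit_pi = qlogis(p)),
                          maxit = maxit, hessian = FALSE)
    list(loglik = f$loglik, converged = f$converged)
  })
  curve <- data.frame(pi = grid,
                      loglik = vapply(res, `[[`, 0.0, "loglik"),
                      converged = vapply(res, `[[`, TRUE, "converged"))
  structure(curve, class = c("jm_profile", "data.frame"),
            argmax = grid[which.max(curve$loglik)],
            fit_pi = if (!is.null(fit)) fit$estimates$pi,
            fit_loglik = if (!is.null(fit)) fit$loglik)
}

#' @export
print.jm_profile <- function(x, ...) {
  cat("<jm_profile> profile log-likelihood for the stayer proportion\n")
  print.data.frame(x)
  cat("argmax:", attr(x, "argmax"), "\n")
  invisible(x)
}

#' @export
plot.jm_profile <- function(x, ...) {
  graphics::plot(x$pi, x$loglik, type = "b", xlab = expression(pi),
                 ylab = "profile log-likelihood", ...)
  if (!is.null(attr(x, "fit_pi"))) {
    graphics::points(attr(x, "fit_pi"), attr(x, "fit_loglik"), pch = 4,
                     cex = 1.5)
  }
  invisible(x)
}

#' Compare observation-level and patient-level random-effect structures
#'
#' Fits the model under both random-effect structures and reports the
#' log-likelihoods and their difference.  The two models are non-nested but
#' have the same number of parameters, so the likelihoods are directly
#' comparable (equal AIC penalties).
#'
#' @param panel A [panel_data()] object.
#' @param config A [model_config()]; its `re_structure` is ignored.
#' @param nodes_observation,nodes_patient Quadrature nodes per dimension for
#'   the two structures (defaults 15 and 30).
#' @param ... Passed to [fit_mover_stayer()].
#' @return An object of class `jm_re_comparison`: list with both fits and a
#'   `table` data.frame.
#' @export
compare_random_effect_structures <- function(panel, config,
                                             nodes_observation = 15,
                                             nodes_patient = 30, ...) {
  cfg_obs <- config; cfg_obs$re_structure <- "observation"
  cfg_obs$nodes <- as.integer(nodes_observation)
  cfg_pat <- config; cfg_pat$re_structure <- "patient"
  cfg_pat$nodes <- as.integer(nodes_patient)
  fit_obs <- fit_mover_stayer(panel, cfg_obs, ...)
  fit_pat <- fit_mover_stayer(panel, cfg_pat, ...)
  stopifnot(fit_obs$n_parameters == fit_pat$n_parameters)
  tab <- data.frame(
    structure = c("observation", "patient"),
    loglik = c(fit_obs$loglik, fit_pat$loglik),
    n_parameters = c(fit_obs$n_parameters, fit_pat$n_parameters),
    converged = c(fit_obs$converged, fit_pat$converged)
  )
  structure(list(observation = fit_obs, patient = fit_pat, table = tab,
                 loglik_difference = fit_obs$loglik - fit_pat$loglik),
            class = "jm_re_comparison")
}

#' @export
print.jm_re_comparison <- function(x, ...) {
  cat("<jm_re_comparison> random-effect structure comparison\n")
  print(x$table)
  cat(sprintf("log-likelihood difference (observation - patient): %.4f\n",
              x$loglik_difference))
  invisible(x)
}
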