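# Gauss-Hermite rule standardized for N(0,1) expectations:
# nodes scaled by sqrt(2), weights normalized to sum to one.
gh_rule <- function(n) {
  if (n < 1) stop("at least one quadrature node is required")
  if (n == 1) return(list(x = 0, logw = 0, n = 1L))  # single node at the mean
  g <- pracma::gaussHermite(n)
  list(x = g$x * sqrt(2), logw = log(g$w) - 0.5 * log(pi), n = n)
}

#' Gauss-Hermite quadrature rule for standard normal expectations
#'
#' Probabilist normalization of the Gauss-Hermite rule: `E[f(Z)]` for
#' `Z ~ N(0,1)` is approximated by `sum(w * f(x))` with the returned nodes and
#' weights; the weights are positive and sum to one.
#'
#' @param n Number of nodes.
#' @return List with `x` (nodes), `w` (weights), `n`.
#' @export
quadrature_rule <- function(n) {
  g <- gh_rule(n)
  list(x = g$x, w = exp(g$logw), n = n)
}

# linear predictors (at u = v = 0) for a single covariate vector z
eta_for_z <- function(theta, z, variant = theta$variant) {
  bz <- function(beta) {
    if (!length(beta)) return(0)
    if (!all(names(beta) %in% names(z))) {
      stop("covariate(s) missing from z: ",
           paste(setdiff(names(beta), names(z)), collapse = ", "))
    }
    val <- sum(beta * unlist(z[names(beta)]))
    if (!is.finite(val)) {
      bad <- names(beta)[!is.finite(beta * unlist(z[names(beta)]))]
      stop("non-finite linear predictor; offending covariate(s): ",
           paste(bad, collapse = ", "))
    }
    val
  }
  if (variant == "six_state") {
    c(theta$log_lambda0[["act_gain"]] + bz(theta$beta$act_gain),
      theta$log_lambda0[["act_loss"]] + bz(theta$beta$act_loss),
      theta$log_lambda0[["dmg"]] + bz(theta$beta$dmg))
  } else {
    c(theta$log_mu0[["inactive"]] + bz(theta$beta$soj_inactive),
      theta$log_mu0[["active"]] + bz(theta$beta$soj_active),
      theta$log_p0[["inactive"]] + bz(theta$beta$jump_inactive),
      theta$log_p0[["active"]] + bz(theta$beta$jump_active))
  }
}

extras_for_theta <- function(theta) {
  if (theta$variant == "six_state") {
    c(theta$beta_damaged[["act_gain"]], theta$beta_damaged[["act_loss"]],
      theta$beta_active_dmg, theta$beta_stayer[["act_gain"]],
      theta$beta_stayer[["act_loss"]], theta$alpha,
      sqrt(theta$sigma2_u), sqrt(theta$sigma2_v), theta$rho, theta$pi)
  } else {
    c(theta$beta_stayer[["inactive"]], theta$beta_stayer[["active"]],
      theta$alpha[["u"]], theta$alpha[["v"]],
      sqrt(theta$sigma2_u), sqrt(theta$sigma2_v), theta$rho, theta$pi)
  }
}

#' Conditional transition intensities for one joint
#'
#' Evaluates the intensity regressions at a covariate vector `z` and random
#' effects `(u, v)`.  For the six-state model the mover intensities are
#' `l12 = lambda0_act_gain * exp(beta'z + u)`,
#' `l21 = lambda0_act_loss * exp(beta'z + alpha u)`,
#' `l13 = lambda0_dmg * exp(beta'z + v)`, with the damaged-state activity
#' rates `l34 = l12 exp(beta_damaged)`, `l43 = l21 exp(beta_damaged)`, the
#' active-state damage rate `l24 = l13 exp(beta_active)`, and the stayer
#' rates `l56 = l12 exp(beta_stayer)`, `l65 = l21 exp(beta_stayer)`.  For the
#' five-state model, mean sojourn times and jump odds are modelled
#' (`mu1 = mu0 exp(beta'z + u)`, `odds(p13) = p0 exp(beta'z + v)`, etc.) and
#' mapped through [sojourn_jump_to_intensities()].
#'
#' @param theta A [parameter_set()].
#' @param z Named list or vector of covariate values (must cover every
#'   covariate named in the regression coefficient vectors).
#' @param u,v Random-effect realizations (default 0).
#' @param class `"mover"` or `"stayer"`.
#' @param variant Model variant; defaults to the parameter set's.
#'
#' @return Named vector of intensities on the corresponding [state_space()];
#'   for the five-state mover the implied `mu`/`p` values are attached as
#'   attribute `"sojourn_jump"`.
#' @export
conditional_intensities <- function(theta, z, u = 0, v = 0,
                                    class = c("mover", "stayer"),
                                    variant = theta$variant) {
  class <- match.arg(class)
  eta <- eta_for_z(theta, z, variant)
  if (variant == "six_state") {
    l12 <- exp(eta[1] + u)
    l21 <- exp(eta[2] + theta$alpha * u)
    l13 <- exp(eta[3] + v)
    if (class == "stayer") {
      return(c(l56 = unname(l12 * exp(theta$beta_stayer[["act_gain"]])),
               l65 = unname(l21 * exp(theta$beta_stayer[["act_loss"]]))))
    }
    c(l12 = unname(l12), l21 = unname(l21), l13 = unname(l13),
      l24 = unname(l13 * exp(theta$beta_active_dmg)),
      l34 = unname(l12 * exp(theta$beta_damaged[["act_gain"]])),
      l43 = unname(l21 * exp(theta$beta_damaged[["act_loss"]])))
  } else {
    mu1 <- exp(eta[1] + u)
    mu2 <- exp(eta[2] + theta$alpha[["u"]] * u)
    if (class == "stayer") {
      mu4 <- mu1 * exp(theta$beta_stayer[["inactive"]])
      mu5 <- mu2 * exp(theta$beta_stayer[["active"]])
      out <- sojourn_jump_to_intensities(list(mu4 = mu4, mu5 = mu5))
      attr(out, "sojourn_jump") <- c(mu4 = unname(mu4), mu5 = unname(mu5))
      return(out)
    }
    o13 <- exp(eta[3] + v)
    o23 <- exp(eta[4] + theta$alpha[["v"]] * v)
    p13 <- o13 / (1 + o13)
    p23 <- o23 / (1 + o23)
    out <- sojourn_jump_to_intensities(list(mu1 = mu1, p13 = p13,
                                            mu2 = mu2, p23 = p23))
    attr(out, "sojourn_jump") <- c(mu1 = unname(mu1), mu2 = unname(mu2),
                                   p13 = unname(p13), p23 = unname(p23))
    out
  }
}

#' Conditional interval transition probability, vectorized over (u, v)
#'
#' The probability of moving from `from` to `to` over an interval of length
#' `dt`, conditional on the covariates, the latent class and the random
#' effects; evaluated for each supplied `(u, v)` pair.  This is the kernel the
#' marginal likelihood integrates, and is used for Monte-Carlo validation of
#' the quadrature.
#'
#' @inheritParams conditional_intensities
#' @param from,to States in the class's state space (six-state mover: 1-4;
#'   stayer: 1-2; five-state mover: 1-3).  Under the stayer class a damaged
#'   state is structurally unreachable and yields probability 0.
#' @param dt Interval length in years.
#' @param u,v Equal-length numeric vectors of random-effect values.
#' @return Numeric vector of probabilities.
#' @export
conditional_interval_prob <- function(theta, z, from, to, dt, u, v,
                                      class = c("mover", "stayer"),
                                      variant = theta$variant) {
  class <- match.arg(class)
  stopifnot(length(u) == length(v), dt > 0)
  base <- eta_for_z(theta, z, variant)
  extras <- extras_for_theta(theta)
  cond_prob_vec_cpp(if (variant == "six_state") 1L else 2L,
                    if (class == "mover") 1L else 0L,
                    base, extras, as.integer(from), as.integer(to),
                    dt, as.numeric(u), as.numeric(v))
}

#' Marginal likelihood factor for one observation interval
#'
#' Integrates the product of the 28 (or fewer) per-joint conditional interval
#' probabilities over the bivariate normal random effects, using the
#' factorization of the bivariate density into phi(v | u) phi(u) and nested
#' Gauss-Hermite sums.
#'
#' @param theta A [parameter_set()].
#' @param z A data.frame/list of covariate vectors, one row (element) per
#'   joint.
#' @param from,to Observed states per joint at the start and end of the
#'   interval.
#' @param dt Interval length in years.
#' @param class `"mover"` or `"stayer"`.
#' @param variant Model variant.
#' @param nodes Gauss-Hermite nodes per dimension.
#' @return The (strictly positive, unless structurally impossible) likelihood
#'   factor.
#' @export
interval_marginal_lik <- function(theta, z, from, to, dt,
                                  class = c("mover", "stayer"),
                                  variant = theta$variant, nodes = 15) {
  class <- match.arg(class)
  z <- as.data.frame(z)
  n_joint <- nrow(z)
  stopifnot(length(from) == n_joint, length(to) == n_joint)
  g <- gh_rule(nodes)
  sd_u <- sqrt(theta$sigma2_u)
  sd_v <- sqrt(theta$sigma2_v)
  rho <- theta$rho
  uu <- rep(sd_u * g$x, each = g$n)
  vv <- rho * sd_v * rep(g$x, each = g$n) +
    sd_v * sqrt(1 - rho^2) * rep(g$x, times = g$n)
  lw <- rep(g$logw, each = g$n) + rep(g$logw, times = g$n)
  logprod <- rep(0, length(uu))
  for (l in seq_len(n_joint)) {
    p <- conditional_interval_prob(theta, as.list(z[l, , drop = FALSE]),
                                   from[l], to[l], dt, uu, vv,
                                   class = class, variant = variant)
    logprod <- logprod + ifelse(p > 0, log(p), -Inf)
  }
  m <- max(lw + logprod)
  if (m == -Inf) return(0)
  exp(m) * sum(exp(lw + logprod - m))
}

# --- likelihood context -----------------------------------------------------

# Precomputes everything the C++ evaluator needs: per-interval covariate
# groups (joints sharing an identical covariate vector share one matrix
# exponential), transition count tables per group, and index pointers.
build_lik_context <- function(panel, config) {
  stopifnot(inherits(panel, "jm_panel"), inherits(config, "jm_config"))
  cov <- build_covariates(panel,
                          baseline_ama_proxy = config$baseline_ama_proxy)
  six <- config$variant == "six_state"
  obs <- as.data.table(panel$obs)
  setkey(obs, patient_id, joint_id, visit)
  obs[, s := if (six) 1L + active + 2L * damaged else
    ifelse(damaged == 1L, 3L, 1L + active)]
  obs[, `:=`(s_next = shift(s, -1L), t_next = shift(time_years, -1L)),
      by = .(patient_id, joint_id)]
  ir <- obs[!is.na(s_next),
            .(patient_id, visit, joint_id, from = s, to = s_next,
              dt = t_next - time_years)]
  ir <- merge(ir, cov, by = c("patient_id", "visit", "joint_id"))
  # drop intervals whose AMA is undefined (the first, unless proxied)
  if (!config$baseline_ama_proxy) ir <- ir[visit >= 2L]
  ir <- ir[!is.na(ama)]
  if (nrow(ir) == 0) stop("no usable observation intervals")
  ucols <- unique(unlist(config$covariates))
  missing_cols <- setdiff(ucols, names(ir))
  if (length(missing_cols)) {
    stop("covariate column(s) not available: ",
         paste(missing_cols, collapse = ", "))
  }
  setkey(ir, patient_id, visit, joint_id)
  if (length(ucols)) {
    ir[, zkey := do.call(paste, c(.SD, list(sep = "\r"))), .SDcols = ucols]
  } else {
    ir[, zkey := ""]
  }
  ir[, int_id := .GRP, by = .(patient_id, visit)]
  ir[, grp_id := .GRP, by = .(int_id, zkey)]

  ints <- ir[, .(patient_id = patient_id[1], dt = dt[1]), by = int_id]
  grps <- ir[, .(int_id = int_id[1], rep = .I[1]), by = grp_id]
  trs <- ir[, .N, by = .(grp_id, from, to)]
  setkey(trs, grp_id)

  pat_ids <- unique(ints$patient_id)  # sorted: ir is keyed by patient_id
  n_int_per_pat <- tabulate(match(ints$patient_id, pat_ids),
                            nbins = length(pat_ids))
  n_grp_per_int <- tabulate(grps$int_id, nbins = nrow(ints))
  n_tr_per_grp <- trs[, .N, by = grp_id]$N

  cstar_all <- observed_mover_indicator(panel)
  cstar <- unname(cstar_all[as.character(pat_ids)])

  X <- lapply(config$covariates, function(cols) {
    if (!length(cols)) {
      matrix(0, nrow(grps), 0)
    } else {
      as.matrix(ir[grps$rep, cols, with = FALSE])
    }
  })

  structure(list(
    config = config,
    variant_code = if (six) 1L else 2L,
    re_code = if (config$re_structure == "observation") 1L else 2L,
    pat_ids = pat_ids,
    cstar = as.integer(cstar),
    pat_ptr = as.integer(c(0, cumsum(n_int_per_pat))),
    int_dt = as.numeric(ints$dt),
    int_grp_ptr = as.integer(c(0, cumsum(n_grp_per_int))),
    grp_tr_ptr = as.integer(c(0, cumsum(n_tr_per_grp))),
    tr_from = as.integer(trs$from),
    tr_to = as.integer(trs$to),
    tr_count = as.integer(trs$N),
    X = X,
    n_rows = nrow(ir),
    n_groups = nrow(grps),
    n_intervals = nrow(ints)
  ), class = "jm_lik_context")
}

eta_matrix <- function(ctx, theta) {
  X <- ctx$X
  lin <- function(Xm, beta, base) {
    if (ncol(Xm) == 0 || !length(beta)) return(rep(base, nrow(Xm)))
    if (!all(colnames(Xm) %in% names(beta)) ||
        length(beta) != ncol(Xm)) {
      stop("regression coefficients do not match configured covariates")
    }
    base + as.numeric(Xm %*% beta[colnames(Xm)])
  }
  if (theta$variant == "six_state") {
    cbind(lin(X$act_gain, theta$beta$act_gain,
              theta$log_lambda0[["act_gain"]]),
          lin(X$act_loss, theta$beta$act_loss,
              theta$log_lambda0[["act_loss"]]),
          lin(X$dmg, theta$beta$dmg, theta$log_lambda0[["dmg"]]))
  } else {
    cbind(lin(X$soj_inactive, theta$beta$soj_inactive,
              theta$log_mu0[["inactive"]]),
          lin(X$soj_active, theta$beta$soj_active,
              theta$log_mu0[["active"]]),
          lin(X$jump_inactive, theta$beta$jump_inactive,
              theta$log_p0[["inactive"]]),
          lin(X$jump_active, theta$beta$jump_active,
              theta$log_p0[["active"]]))
  }
}

ctx_loglik <- function(ctx, theta, per_patient = FALSE,
                       nodes = ctx$config$nodes,
                       re_structure = NULL) {
  eta <- eta_matrix(ctx, theta)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  g <- gh_rule(nodes)
  re_code <- if (is.null(re_structure)) ctx$re_code else
    if (re_structure == "observation") 1L else 2L
  res <- panel_loglik_cpp(ctx$variant_code, re_code, ctx$pat_ptr, ctx$cstar,
                          ctx$int_dt, ctx$int_grp_ptr, ctx$grp_tr_ptr,
                          ctx$tr_from, ctx$tr_to, ctx$tr_count, eta,
                          extras_for_theta(theta), g$x, g$logw)
  if (per_patient) {
    setNames(res$per_patient, as.character(ctx$pat_ids))
  } else {
    res$loglik
  }
}

#' Marginal log-likelihood of a panel dataset
#'
#' The mover-stayer mixture marginal log-likelihood: per patient, the
#' conditional per-joint transition-probability products are integrated over
#' the bivariate normal random effects by Gauss-Hermite quadrature
#' (per-interval integrals for the observation-level structure; one integral
#' wrapping all intervals for the patient-level structure), and the mover and
#' stayer class likelihoods are mixed with weights `1 - pi` and `pi`.  A
#' patient with damage observed at the last visit (`c* = 1`) contributes
#' `(1 - pi) * L(mover)` only.  The first observation interval of each
#' patient is excluded because the AMA covariate is undefined at the first
#' visit (unless `baseline_ama_proxy` is set in the config).
#'
#' @param panel A [panel_data()] object (or a prebuilt likelihood context).
#' @param theta A [parameter_set()].
#' @param config A [model_config()].
#' @param per_patient Return the per-patient contributions instead of the sum.
#' @param check Error (naming the patients) if any contribution is `-Inf`.
#' @return Scalar log-likelihood, or a named per-patient vector.
#' @export
total_loglik <- function(panel, theta, config, per_patient = FALSE,
                         check = TRUE) {
  ctx <- if (inherits(panel, "jm_lik_context")) panel else
    build_lik_context(panel, config)
  ll <- ctx_loglik(ctx, theta, per_patient = TRUE)
  if (check && any(!is.finite(ll))) {
    stop("log-likelihood is -Inf for patient(s): ",
         paste(names(ll)[!is.finite(ll)], collapse = ", "),
         " (an observed transition has probability zero under theta)")
  }
  if (per_patient) ll else sum(ll)
}

#' Marginal log-likelihood under patient-level random effects
#'
#' Same mixture structure as [total_loglik()] but with a single bivariate
#' normal draw per patient shared by all intervals (the time-invariant
#' unobserved-heterogeneity comparator).  Default quadrature is 30 nodes per
#' dimension.
#'
#' @inheritParams total_loglik
#' @param nodes Nodes per dimension (default 30).
#' @export
patient_level_loglik <- function(panel, theta, config, per_patient = FALSE,
                                 nodes = 30) {
  cfg <- config
  cfg$re_structure <- "patient"
  cfg$nodes <- as.integer(nodes)
  ctx <- if (inherits(panel, "jm_lik_context")) panel else
    build_lik_context(panel, cfg)
  ll <- ctx_loglik(ctx, theta, per_patient = TRUE, nodes = nodes,
                   re_structure = "patient")
  if (per_patient) ll else sum(ll)
}
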