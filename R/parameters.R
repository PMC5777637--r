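#' Model configuration
#'
#' Collects the model variant, random-effect structure, covariate sets per
#' linear predictor, quadrature size and likelihood options.
#'
#' For the six-state model the linear predictors are `act_gain` (inactive ->
#' active intensity), `act_loss` (active -> inactive) and `dmg` (undamaged ->
#' damaged); for the five-state model they are `soj_inactive`, `soj_active`
#' (log mean sojourn times) and `jump_inactive`, `jump_active` (log odds of
#' jumping to damage).  Each element of `covariates` is a character vector of
#' column names of the [build_covariates()] table.
#'
#' @param variant `"six_state"` or `"five_state"`.
#' @param re_structure `"observation"` (independent bivariate normal random
#'   effects per patient-interval, shared across the 28 joints) or
#'   `"patient"` (one draw per patient).
#' @param covariates Named list of covariate sets; `NULL` gives the default
#'   set `c("ama", "opposite_damaged", "sex")` for every predictor.
#' @param nodes Gauss-Hermite nodes per dimension; defaults to 15 for
#'   observation-level and 30 for patient-level random effects.
#' @param baseline_ama_proxy Include the first interval, proxying AMA at the
#'   first visit by the baseline activity (default `FALSE`: the first
#'   interval is excluded because AMA is undefined there).
#'
#' @return An object of class `jm_config`.
#' @export
model_config <- function(variant = c("six_state", "five_state"),
                         re_structure = c("observation", "patient"),
                         covariates = NULL, nodes = NULL,
                         baseline_ama_proxy = FALSE) {
  variant <- match.arg(variant)
  re_structure <- match.arg(re_structure)
  preds <- predictor_names(variant)
  if (is.null(covariates)) {
    covariates <- setNames(
      rep(list(c("ama", "opposite_damaged", "sex")), length(preds)), preds)
  }
  miss <- setdiff(preds, names(covariates))
  if (length(miss)) {
    covariates[miss] <- list(character())
  }
  covariates <- covariates[preds]
  if (is.null(nodes)) {
    nodes <- if (re_structure == "observation") 15L else 30L
  }
  if (nodes < 1) stop("at least one quadrature node per dimension is required")
  structure(list(variant = variant, re_structure = re_structure,
                 covariates = covariates, nodes = as.integer(nodes),
                 baseline_ama_proxy = isTRUE(baseline_ama_proxy)),
            class = "jm_config")
}

predictor_names <- function(variant) {
  if (variant == "six_state") c("act_gain", "act_loss", "dmg")
  else c("soj_inactive", "soj_active", "jump_inactive", "jump_active")
}

#' Full parameter set
#'
#' Bundles every estimable parameter of a model variant.
#'
#' Six-state: log baseline intensities `log_lambda0` (`act_gain`, `act_loss`,
#' `dmg`); regression vectors `beta` per predictor; `beta_damaged` (effect of
#' the joint being damaged on the two activity intensities); `beta_active_dmg`
#' (effect of the joint being active on the damage intensity); `beta_stayer`
#' (stayer effects on the two activity intensities); random-effect loading
#' `alpha`; variances `sigma2_u`, `sigma2_v`; correlation `rho`; stayer
#' probability `pi`.
#'
#' Five-state: log baseline mean sojourn times `log_mu0` (`inactive`,
#' `active`); log baseline jump odds `log_p0` (`inactive`, `active`);
#' regression vectors `beta` per predictor; `beta_stayer` (stayer effects on
#' the two sojourn times); loadings `alpha = c(u = alpha1, v = alpha2)`; and
#' the same variance/correlation/mixture parameters.
#'
#' @param variant `"six_state"` or `"five_state"`.
#' @param ... Named components as described above.  Missing regression vectors
#'   default to empty; missing scalars default to 0 (variances to 1, `pi` to
#'   0.1).
#' @return An object of class `jm_params`.
#' @export
parameter_set <- function(variant = c("six_state", "five_state"), ...) {
  variant <- match.arg(variant)
  args <- list(...)
  base <- if (variant == "six_state") {
    list(
      variant = variant,
      log_lambda0 = c(act_gain = 0, act_loss = 0, dmg = 0),
      beta = list(act_gain = numeric(), act_loss = numeric(),
                  dmg = numeric()),
      beta_damaged = c(act_gain = 0, act_loss = 0),
      beta_active_dmg = 0,
      beta_stayer = c(act_gain = 0, act_loss = 0),
      alpha = 0,
      sigma2_u = 1, sigma2_v = 1, rho = 0, pi = 0.1
    )
  } else {
    list(
      variant = variant,
      log_mu0 = c(inactive = 0, active = 0),
      log_p0 = c(inactive = 0, active = 0),
      beta = list(soj_inactive = numeric(), soj_active = numeric(),
                  jump_inactive = numeric(), jump_active = numeric()),
      beta_stayer = c(inactive = 0, active = 0),
      alpha = c(u = 0, v = 0),
      sigma2_u = 1, sigma2_v = 1, rho = 0, pi = 0.1
    )
  }
  unknown <- setdiff(names(args), names(base))
  if (length(unknown)) {
    stop("unknown parameter component(s): ", paste(unknown, collapse = ", "))
  }
  theta <- modifyList(base, args)
  validate_params(theta)
  structure(theta, class = "jm_params")
}

validate_params <- function(theta) {
  if (theta$sigma2_u <= 0 || theta$sigma2_v <= 0) {
    stop("variance components must be strictly positive")
  }
  if (abs(theta$rho) >= 1) stop("|rho| must be < 1")
  if (theta$pi < 0 || theta$pi >= 1) stop("pi must lie in [0, 1)")
  invisible(theta)
}

#' @export
print.jm_params <- function(x, ...) {
  cat(sprintf("<jm_params> %s model\n", x$variant))
  v <- theta_to_working(x)
  for (nm in names(v)) cat(sprintf("  %-28s %10.4f\n", nm, v[nm]))
  invisible(x)
}

# --- working (unconstrained) scale -----------------------------------------

#' Map a parameter set to the unconstrained working scale (and back)
#'
#' Log transform for variances, atanh for the correlation, logit for the
#' stayer probability; baselines are already on the log (or log-odds) scale
#' and regression coefficients and loadings are unconstrained.  Optimization
#' and Wald intervals operate on this scale.
#'
#' @param theta A [parameter_set()].
#' @return Named numeric vector.
#' @export
theta_to_working <- function(theta) {
  validate_params(theta)
  if (theta$pi == 0) {
    stop("pi = 0 lies on the boundary of the working scale; ",
         "fit with pi fixed instead")
  }
  v <- c()
  if (theta$variant == "six_state") {
    v <- c(v, setNames(theta$log_lambda0,
                       paste0("log_lambda0.", names(theta$log_lambda0))))
    for (p in names(theta$beta)) {
      b <- theta$beta[[p]]
      if (length(b)) v <- c(v, setNames(b, paste0("beta_", p, ".", names(b))))
    }
    v <- c(v,
           beta_damaged.act_gain = unname(theta$beta_damaged["act_gain"]),
           beta_damaged.act_loss = unname(theta$beta_damaged["act_loss"]),
           beta_active_dmg = unname(theta$beta_active_dmg),
           beta_stayer.act_gain = unname(theta$beta_stayer["act_gain"]),
           beta_stayer.act_loss = unname(theta$beta_stayer["act_loss"]),
           alpha = unname(theta$alpha))
  } else {
    v <- c(v, setNames(theta$log_mu0,
                       paste0("log_mu0.", names(theta$log_mu0))),
           setNames(theta$log_p0, paste0("log_p0.", names(theta$log_p0))))
    for (p in names(theta$beta)) {
      b <- theta$beta[[p]]
      if (length(b)) v <- c(v, setNames(b, paste0("beta_", p, ".", names(b))))
    }
    v <- c(v,
           beta_stayer.inactive = unname(theta$beta_stayer["inactive"]),
           beta_stayer.active = unname(theta$beta_stayer["active"]),
           alpha1 = unname(theta$alpha["u"]),
           alpha2 = unname(theta$alpha["v"]))
  }
  c(v,
    log_sigma2_u = log(theta$sigma2_u),
    log_sigma2_v = log(theta$sigma2_v),
    atanh_rho = atanh(theta$rho),
    logit_pi = qlogis(theta$pi))
}

#' @rdname theta_to_working
#' @param working Named numeric vector as produced by [theta_to_working()].
#' @param skeleton A [parameter_set()] supplying the variant and the
#'   regression-coefficient layout.
#' @export
working_to_theta <- function(working, skeleton) {
  theta <- skeleton
  pick <- function(nm) {
    if (!nm %in% names(working)) stop("missing working parameter: ", nm)
    unname(working[[nm]])
  }
  if (skeleton$variant == "six_state") {
    theta$log_lambda0 <- c(act_gain = pick("log_lambda0.act_gain"),
                           act_loss = pick("log_lambda0.act_loss"),
                           dmg = pick("log_lambda0.dmg"))
    for (p in names(theta$beta)) {
      b <- skeleton$beta[[p]]
      if (length(b)) {
        theta$beta[[p]] <- setNames(
          vapply(paste0("beta_", p, ".", names(b)), pick, 0.0), names(b))
      }
    }
    theta$beta_damaged <- c(act_gain = pick("beta_damaged.act_gain"),
                            act_loss = pick("beta_damaged.act_loss"))
    theta$beta_active_dmg <- pick("beta_active_dmg")
    theta$beta_stayer <- c(act_gain = pick("beta_stayer.act_gain"),
                           act_loss = pick("beta_stayer.act_loss"))
    theta$alpha <- pick("alpha")
  } else {
    theta$log_mu0 <- c(inactive = pick("log_mu0.inactive"),
                       active = pick("log_mu0.active"))
    theta$log_p0 <- c(inactive = pick("log_p0.inactive"),
                      active = pick("log_p0.active"))
    for (p in names(theta$beta)) {
      b <- skeleton$beta[[p]]
      if (length(b)) {
        theta$beta[[p]] <- setNames(
          vapply(paste0("beta_", p, ".", names(b)), pick, 0.0), names(b))
      }
    }
    theta$beta_stayer <- c(inactive = pick("beta_stayer.inactive"),
                           active = pick("beta_stayer.active"))
    theta$alpha <- c(u = pick("alpha1"), v = pick("alpha2"))
  }
  theta$sigma2_u <- exp(pick("log_sigma2_u"))
  theta$sigma2_v <- exp(pick("log_sigma2_v"))
  theta$rho <- tanh(pick("atanh_rho"))
  theta$pi <- plogis(pick("logit_pi"))
  theta
}

# which working-scale parameters are transformed, for interval back-transforms
working_transforms <- function(names) {
  tr <- rep("identity", length(names))
  tr[names %in% c("log_sigma2_u", "log_sigma2_v")] <- "exp"
  tr[names == "atanh_rho"] <- "tanh"
  tr[names == "logit_pi"] <- "plogis"
  setNames(tr, names)
}
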