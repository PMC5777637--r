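#' State spaces of the conditional multistate chains
#'
#' The joint activity/damage process of a single hand joint is modelled
#' conditionally on the latent mover/stayer class.  Movers in the six-state
#' model follow a four-state chain (1 = inactive/undamaged, 2 =
#' active/undamaged, 3 = inactive/damaged, 4 = active/damaged) in which damage
#' is irreversible; stayers follow a two-state activity chain (inactive,
#' active) and can never reach a damaged state.  The five-state variant
#' collapses the two damaged states into a single absorbing state, giving a
#' three-state mover chain.
#'
#' @param variant `"six_state"` or `"five_state"`.
#' @param class `"mover"` or `"stayer"`.
#'
#' @return An object of class `jm_state_space` with elements `variant`,
#'   `class`, `states` (character labels), `n_states` and `transitions`
#'   (two-column matrix of allowed `from`/`to` state indices, with intensity
#'   names as rownames).
#' @export
#' @examples
#' state_space("six_state", "mover")
state_space <- function(variant = c("six_state", "five_state"),
                        class = c("mover", "stayer")) {
  variant <- match.arg(variant)
  class <- match.arg(class)
  if (class == "stayer") {
    states <- c("inactive", "active")
    tr <- rbind(c(1L, 2L), c(2L, 1L))
    rownames(tr) <- if (variant == "six_state") c("l56", "l65") else
      c("l45", "l54")
  } else if (variant == "six_state") {
    states <- c("inactive_undamaged", "active_undamaged",
                "inactive_damaged", "active_damaged")
    tr <- rbind(c(1L, 2L), c(2L, 1L), c(1L, 3L), c(2L, 4L),
                c(3L, 4L), c(4L, 3L))
    rownames(tr) <- c("l12", "l21", "l13", "l24", "l34", "l43")
  } else {
    states <- c("inactive", "active", "damaged")
    tr <- rbind(c(1L, 2L), c(2L, 1L), c(1L, 3L), c(2L, 3L))
    rownames(tr) <- c("l12", "l21", "l13", "l23")
  }
  colnames(tr) <- c("from", "to")
  structure(
    list(variant = variant, class = class, states = states,
         n_states = length(states), transitions = tr),
    class = "jm_state_space"
  )
}

#' @export
print.jm_state_space <- function(x, ...) {
  cat(sprintf("<jm_state_space> %s / %s: %d states\n", x$variant, x$class,
              x$n_states))
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  transitions:",
      paste(sprintf("%s(%d->%d)", rownames(x$transitions),
                    x$transitions[, 1], x$transitions[, 2]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Build a transition-intensity (generator) matrix
#'
#' Places the named nonnegative intensities on the allowed transitions of the
#' given state space and sets each diagonal entry to minus the row sum, so
#' every row of the generator sums to zero.
#'
#' @param intensities Named numeric vector of nonnegative rates (events per
#'   year).  Names must be a subset of the state space's intensity names
#'   (e.g. `l12`, `l21`, `l13`, `l24`, `l34`, `l43` for the six-state mover
#'   chain); omitted intensities are taken as zero.
#' @param space A [state_space()] object.
#'
#' @return A square matrix of class `jm_generator` with `space` attached as an
#'   attribute.
#' @export
#' @examples
#' sp <- state_space("six_state", "mover")
#' build_generator(c(l12 = 1, l13 = 0.5), sp)
build_generator <- function(intensities, space) {
  stopifnot(inherits(space, "jm_state_space"))
  if (is.null(names(intensities)) && length(intensities) > 0) {
    stop("intensities must be a named vector")
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite")
  }
  if (any(intensities < 0)) {
    bad <- names(intensities)[intensities < 0]
    stop("negative intensity for transition(s): ", paste(bad, collapse = ", "))
  }
  allowed <- rownames(space$transitions)
  unknown <- setdiff(names(intensities), allowed)
  if (length(unknown)) {
    stop("intensity named for a disallowed transition: ",
         paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  n <- space$n_states
  Q <- matrix(0, n, n, dimnames = list(space$states, space$states))
  for (nm in names(intensities)) {
    idx <- space$transitions[nm, ]
    Q[idx[1], idx[2]] <- intensities[[nm]]
  }
  diag(Q) <- -rowSums(Q)
  structure(Q, class = c("jm_generator", "matrix"), space = space)
}

#' Transition-probability matrix over an interval
#'
#' Computes `P(dt) = exp(Q * dt)` by scaling-and-squaring with a Pade
#' approximant.  Entries that are negative by no more than `1e-12` (floating
#' point noise) are clamped to zero and rows renormalized; larger violations
#' raise an error.
#'
#' @param Q A square generator matrix (rows summing to zero), e.g. from
#'   [build_generator()].
#' @param dt Interval length in years, `dt >= 0`.
#'
#' @return A stochastic matrix of the same dimension: entries in `[0, 1]`,
#'   rows summing to 1.
#' @export
#' @examples
#' sp <- state_space("six_state", "stayer")
#' Q <- build_generator(c(l56 = 1, l65 = 2), sp)
#' transition_matrix(Q, 1)
transition_matrix <- function(Q, dt) {
  Q <- unclass(Q)
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be a square matrix")
  if (any(!is.finite(Q))) stop("Q must be finite")
  if (length(dt) != 1 || !is.finite(dt)) stop("dt must be a finite scalar")
  if (dt < 0) stop("dt must be nonnegative")
  if (max(abs(rowSums(Q))) > 1e-8) {
    stop("Q rows must sum to zero (not a generator)")
  }
  P <- expm_generator_cpp(Q, dt)
  if (any(P < -1e-12)) {
    stop("matrix exponential produced entries below -1e-12; ",
         "generator may be ill-conditioned")
  }
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Map mean sojourn times and jump probabilities to intensities
#'
#' The five-state chain can equivalently be parameterized by the mean sojourn
#' times of the transient states and the jump probabilities to damage.  For a
#' time-homogeneous Markov chain the sojourn time in state r is exponential
#' with mean `1 / sum(rates out of r)` and the jump probabilities are the
#' normalized exit rates, giving the bijection
#' `l12 = (1 - p13) / mu1`, `l13 = p13 / mu1`, `l21 = (1 - p23) / mu2`,
#' `l23 = p23 / mu2`, `l45 = 1 / mu4`, `l54 = 1 / mu5`.
#'
#' @param sj Named list or vector with elements `mu1`, `mu2`, `mu4`, `mu5`
#'   (mean sojourn times in years, strictly positive) and `p13`, `p23` (jump
#'   probabilities strictly inside (0, 1)).  Any subset of the pairs may be
#'   supplied; only the corresponding intensities are returned.
#'
#' @return Named numeric vector of intensities.
#' @seealso [intensities_to_sojourn_jump()]
#' @export
#' @examples
#' sojourn_jump_to_intensities(list(mu1 = 2, p13 = 0.25))
sojourn_jump_to_intensities <- function(sj) {
  sj <- as.list(sj)
  out <- c()
  mu_check <- function(mu, nm) {
    if (!is.finite(mu) || mu <= 0) {
      stop("mean sojourn time ", nm, " must be strictly positive")
    }
  }
  p_check <- function(p, nm) {
    if (!is.finite(p) || p <= 0 || p >= 1) {
      stop("jump probability ", nm, " must lie strictly inside (0, 1)")
    }
  }
  if (!is.null(sj$mu1)) {
    mu_check(sj$mu1, "mu1")
    p_check(sj$p13, "p13")
    out <- c(out, l12 = (1 - sj$p13) / sj$mu1, l13 = sj$p13 / sj$mu1)
  }
  if (!is.null(sj$mu2)) {
    mu_check(sj$mu2, "mu2")
    p_check(sj$p23, "p23")
    out <- c(out, l21 = (1 - sj$p23) / sj$mu2, l23 = sj$p23 / sj$mu2)
  }
  if (!is.null(sj$mu4)) {
    mu_check(sj$mu4, "mu4")
    out <- c(out, l45 = 1 / sj$mu4)
  }
  if (!is.null(sj$mu5)) {
    mu_check(sj$mu5, "mu5")
    out <- c(out, l54 = 1 / sj$mu5)
  }
  if (!length(out)) stop("no sojourn/jump parameters supplied")
  out
}

#' Map intensities to mean sojourn times and jump probabilities
#'
#' Inverse of [sojourn_jump_to_intensities()]: for each modelled transient
#' state the mean sojourn time is the reciprocal total exit rate and the jump
#' probabilities are the exit rates normalized to sum to one.
#'
#' @param intensities Named numeric vector with any subset of the pairs
#'   (`l12`, `l13`), (`l21`, `l23`), `l45`, `l54`.
#'
#' @return Named numeric vector with the corresponding `mu1`, `p13`, `mu2`,
#'   `p23`, `mu4`, `mu5`.
#' @export
#' @examples
#' intensities_to_sojourn_jump(c(l12 = 0.375, l13 = 0.125))
intensities_to_sojourn_jump <- function(intensities) {
  x <- as.list(intensities)
  out <- c()
  if (!is.null(x$l12) || !is.null(x$l13)) {
    tot <- (x$l12 %||% 0) + (x$l13 %||% 0)
    if (tot <= 0) stop("zero total exit rate from state 1 (inactive)")
    out <- c(out, mu1 = 1 / tot, p13 = (x$l13 %||% 0) / tot)
  }
  if (!is.null(x$l21) || !is.null(x$l23)) {
    tot <- (x$l21 %||% 0) + (x$l23 %||% 0)
    if (tot <= 0) stop("zero total exit rate from state 2 (active)")
    out <- c(out, mu2 = 1 / tot, p23 = (x$l23 %||% 0) / tot)
  }
  if (!is.null(x$l45)) {
    if (x$l45 <= 0) stop("zero total exit rate from state 4 (stayer inactive)")
    out <- c(out, mu4 = 1 / x$l45)
  }
  if (!is.null(x$l54)) {
    if (x$l54 <= 0) stop("zero total exit rate from state 5 (stayer active)")
    out <- c(out, mu5 = 1 / x$l54)
  }
  if (!length(out)) stop("no recognized intensities supplied")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
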