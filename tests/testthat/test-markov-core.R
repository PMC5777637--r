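test_that("generator construction places intensities and zero row sums", {
  sp <- state_space("six_state", "mover")
  Q0 <- build_generator(c(), sp)
  expect_equal(unclass(Q0), matrix(0, 4, 4), ignore_attr = TRUE)

  Q <- build_generator(c(l12 = 1.0, l13 = 0.5), sp)
  expect_equal(unname(Q[1, ]), c(-1.5, 1.0, 0.5, 0))

  set.seed(42)
  for (kind in c("mover6", "mover5", "stayer")) {
    for (k in 1:20) {
      Q <- rates_to_generator(kind, random_rates(kind))
      expect_lt(max(abs(rowSums(Q))), 1e-12)
      # structural zeros: damaged -> undamaged impossible
      if (kind == "mover6") {
        expect_true(all(Q[3:4, 1:2] == 0))
      }
      if (kind == "mover5") expect_true(all(Q[3, ] == 0))
    }
  }
})

test_that("generator construction rejects invalid intensities", {
  sp <- state_space("six_state", "mover")
  expect_error(build_generator(c(l12 = -1), sp), "negative")
  expect_error(build_generator(c(l31 = 1), sp), "disallowed")
  expect_error(build_generator(c(l12 = Inf), sp), "finite")
})

test_that("transition matrix matches closed forms and limits", {
  sp2 <- state_space("six_state", "stayer")
  # P(0) = I
  Q <- build_generator(c(l56 = 0.7, l65 = 1.3), sp2)
  expect_equal(transition_matrix(Q, 0), diag(2), ignore_attr = TRUE)
  # stationary limit of the symmetric two-state chain
  Qs <- build_generator(c(l56 = 1, l65 = 1), sp2)
  expect_equal(unclass(transition_matrix(Qs, 50)),
               matrix(0.5, 2, 2), ignore_attr = TRUE, tolerance = 1e-10)
  # closed-form two-state solution, and independently a Runge-Kutta oracle
  Qa <- build_generator(c(l56 = 1, l65 = 2), sp2)
  P <- transition_matrix(Qa, 1)
  expect_equal(P[1, 1], 2 / 3 + exp(-3) / 3, tolerance = 1e-10)
  expect_equal(unclass(P), ode_transition(Qa, 1), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_error(transition_matrix(Qa, -1), "nonnegative")
  Qb <- Qa; Qb[1, 1] <- NaN
  expect_error(transition_matrix(Qb, 1), "finite")
})

test_that("transition probabilities satisfy Chapman-Kolmogorov and match the ODE oracle", {
  set.seed(7)
  for (k in 1:25) {
    kind <- sample(c("mover6", "mover5", "stayer"), 1)
    Q <- rates_to_generator(kind, random_rates(kind))
    s <- runif(1, 0, 10); t <- runif(1, 0, 10)
    Pst <- transition_matrix(Q, s + t)
    expect_lt(max(abs(rowSums(Pst) - 1)), 1e-10)
    expect_lt(max(abs(Pst - transition_matrix(Q, s) %*%
                        transition_matrix(Q, t))), 1e-8)
    expect_lt(max(abs(Pst - ode_transition(Q, s + t))), 1e-7)
  }
})

test_that("absorbing-state rows stay unit vectors", {
  set.seed(11)
  Q <- rates_to_generator("mover5", random_rates("mover5"))
  for (t in c(0.1, 1, 5, 25)) {
    P <- transition_matrix(Q, t)
    expect_equal(unname(P[3, ]), c(0, 0, 1))
  }
})

test_that("closed-form chain exponentials agree with the generic route, including near-degenerate rates", {
  set.seed(13)
  # random rates
  for (k in 1:30) {
    r <- random_rates("mover6")
    t <- runif(1, 0.05, 8)
    P1 <- jointmsm:::pmat_closed_cpp(1L, r, t)
    P2 <- transition_matrix(rates_to_generator("mover6", r), t)
    expect_lt(max(abs(P1 - P2)), 1e-9)
  }
  # degenerate corners exercised explicitly: no damaged-state activity,
  # vanishing activity rates, equal rates
  corners <- list(c(1, 2, 0.5, 0.7, 0, 0), c(0, 0, 0, 0, 0, 0),
                  c(1, 1, 1, 1, 1, 1), c(0, 2, 0.3, 0.3, 1e-12, 1e-12),
                  c(2, 0, 0.1, 0.4, 3, 0))
  for (r in corners) {
    for (t in c(0.2, 2)) {
      P1 <- jointmsm:::pmat_closed_cpp(1L, r, t)
      P2 <- transition_matrix(rates_to_generator("mover6", r), t)
      expect_lt(max(abs(P1 - P2)), 1e-9)
    }
  }
  # five-state and stayer kinds
  for (k in 1:10) {
    r5 <- random_rates("mover5"); t <- runif(1, 0.1, 5)
    expect_lt(max(abs(jointmsm:::pmat_closed_cpp(2L, r5, t) -
                        transition_matrix(rates_to_generator("mover5", r5),
                                          t))), 1e-9)
    r2 <- random_rates("stayer")
    expect_lt(max(abs(jointmsm:::pmat_closed_cpp(3L, r2, t) -
                        transition_matrix(rates_to_generator("stayer", r2),
                                          t))), 1e-9)
  }
})

test_that("sojourn/jump and intensity parameterizations are mutual inverses", {
  expect_equal(sojourn_jump_to_intensities(list(mu1 = 2, p13 = 0.25)),
               c(l12 = 0.375, l13 = 0.125))
  expect_equal(sojourn_jump_to_intensities(list(mu4 = 4)), c(l45 = 0.25))
  expect_equal(intensities_to_sojourn_jump(c(l12 = 0.375, l13 = 0.125)),
               c(mu1 = 2, p13 = 0.25))
  expect_equal(intensities_to_sojourn_jump(c(l45 = 0.25)), c(mu4 = 4))
  set.seed(19)
  for (k in 1:100) {
    sj <- list(mu1 = rexp(1) + 0.01, mu2 = rexp(1) + 0.01,
               mu4 = rexp(1) + 0.01, mu5 = rexp(1) + 0.01,
               p13 = runif(1, 0.01, 0.99), p23 = runif(1, 0.01, 0.99))
    back <- intensities_to_sojourn_jump(sojourn_jump_to_intensities(sj))
    expect_equal(back[names(back)], unlist(sj)[names(back)],
                 tolerance = 1e-12)
    # jump probabilities out of a state sum to one
    ints <- sojourn_jump_to_intensities(sj)
    expect_equal(unname(ints["l12"] + ints["l13"]) * sj$mu1, 1,
                 tolerance = 1e-12)
  }
  expect_error(sojourn_jump_to_intensities(list(mu1 = -1, p13 = 0.5)),
               "strictly positive")
  expect_error(sojourn_jump_to_intensities(list(mu1 = 1, p13 = 1)),
               "inside")
  expect_error(intensities_to_sojourn_jump(c(l12 = 0, l13 = 0)), "state 1")
})
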