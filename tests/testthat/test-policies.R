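# Planning engine: DP correctness against a pure-R solver, Whittle-index
# properties, Lagrangian relaxation bounds, allocator optimality on toys,
# and the standard-of-care baselines.

test_that("the DP matches an independent recursive solver", {
  set.seed(31)
  for (rep in 1:6) {
    p <- random_params()
    e <- sample(1:3, 1); m0 <- sample(1:3, 1); m1 <- sample(1:3, 1)
    b <- sample(c(0, 1, runif(1)), 1)
    k0 <- if (b %in% c(0, 1)) 0L else 1L
    TT <- sample(2:5, 1)
    alpha <- runif(1)
    lambda <- runif(1, -0.2, 0.5)
    st <- belief_patient_state(e, c(m0, m1), b, k0)
    vf <- finite_horizon_dp(p, st, horizon = TT, alpha = alpha, lambda = lambda)
    oracle <- r_arm_value(p, e, m0, m1, b, TT, alpha, lambda)
    expect_equal(vf$value, oracle, tolerance = 1e-10)
    expect_equal(unname(max(vf$q_values)), oracle, tolerance = 1e-10)
  }
})

test_that("value-function table satisfies its invariants", {
  p <- mk_params()
  st <- patient_state("Engaged", "A1cGe8", c("Maintenance", "Maintenance"))
  vf <- finite_horizon_dp(p, st, horizon = 6, alpha = 0.3, lambda = 0.1)
  tab <- vf$table
  expect_true(all(tab$V[tab$t == 6] == 0))
  inner <- tab[tab$t < 6, ]
  expect_equal(inner$V, pmax(inner$Q_U, inner$Q_I), tolerance = 1e-12)
})

test_that("a large action charge reduces the DP to the passive chain", {
  set.seed(33)
  for (rep in 1:3) {
    p <- random_params()
    st <- belief_patient_state("Maintenance", c("Maintenance", "Engaged"), runif(1), 1L)
    s <- list(e = 2, m0 = 2, m1 = 1)
    vf <- finite_horizon_dp(p, st, horizon = 5, alpha = 0.4, lambda = 10)
    passive <- r_arm_value(p, 2, 2, 1, st$clinical_belief, 5, 0.4, 0, forced = 1)
    expect_equal(vf$value, passive, tolerance = 1e-10)
  }
})

test_that("whittle index is zero when the actions are indistinguishable", {
  # intervention mimics self-care: same dropout rate, no chance of responding
  p <- patient_params(0, 0, 0.10, 0.10, 0.075, 0.005, 0.5, 0.3)
  st <- patient_state("Maintenance", "A1cGe8", c("Maintenance", "Maintenance"))
  expect_lt(abs(whittle_index(p, st, 0, 10)), 1e-4)
})

test_that("whittle index at the final epoch equals the one-step reward gain", {
  set.seed(35)
  for (rep in 1:5) {
    p <- random_params()
    alpha <- runif(1, 0.2, 1)
    st <- belief_patient_state("Maintenance", c("Maintenance", "Maintenance"),
                               runif(1), 1L)
    # next-month reward differs across actions only through dropout avoidance
    gain <- alpha * (p$p_U_MtoD - p$p_I_MtoD)
    idx <- whittle_index(p, st, t = 9, horizon = 10, alpha = alpha)
    expect_lt(abs(idx - gain), 2e-4)
  }
})

test_that("a dropped-out arm has zero index and acting is never advantageous", {
  p <- mk_params()
  st <- belief_patient_state("Dropout", c("Dropout", "Dropout"), 0.3, 4L)
  expect_equal(whittle_index(p, st, 0, 12), 0, tolerance = 1e-4)
  for (lam in c(0, 0.1, 1)) {
    vf <- finite_horizon_dp(p, st, horizon = 12, lambda = lam)
    expect_lte(vf$q_values["Q_I"], vf$q_values["Q_U"] + 1e-12)
  }
})

test_that("the action advantage is non-increasing in the charge", {
  set.seed(37)
  for (rep in 1:4) {
    p <- random_params()
    st <- belief_patient_state("Engaged", c("Engaged", "Maintenance"), 0, 0L)
    lams <- seq(-0.5, 1.5, by = 0.25)
    adv <- vapply(lams, function(l) {
      vf <- finite_horizon_dp(p, st, horizon = 8, alpha = 0.5, lambda = l)
      unname(vf$q_values["Q_I"] - vf$q_values["Q_U"])
    }, numeric(1))
    expect_true(all(diff(adv) <= 1e-10))
  }
})

test_that("opt policy selects by index with budget saturation", {
  p2 <- rbind(as.data.frame(unclass(mk_params())), as.data.frame(unclass(mk_params())))
  states <- data.frame(e = c(3L, 2L), m0 = c(3L, 2L), m1 = c(3L, 2L), b = c(0.4, 0))
  expect_identical(opt_policy(p2, states, 0, 12, 0.5, B = 0), integer(0))
  sel1 <- opt_policy(p2, states, 0, 12, 0.5, B = 1)
  expect_identical(sel1, 2L)  # the maintenance arm outranks the dropout
  expect_setequal(opt_policy(p2, states, 0, 12, 0.5, B = 5), 1:2)
})

test_that("unconstrained group budget makes the charge vanish", {
  p <- mk_params()
  pm <- do.call(rbind, replicate(3, as.data.frame(unclass(p)), simplify = FALSE))
  states <- data.frame(e = c(1L, 2L, 2L), m0 = c(2L, 2L, 1L), m1 = c(2L, 1L, 2L),
                       b = c(0, 0, 1))
  sol <- lagrangian_group_value(pm, states, b_g = 3, horizon = 6, alpha = 0.5)
  expect_lt(sol$lambda_star, 2e-4)
  free <- sum(vapply(1:3, function(i) {
    r_arm_value(p, states$e[i], states$m0[i], states$m1[i], states$b[i], 6, 0.5, 0)
  }, numeric(1)))
  expect_equal(sol$relaxed_value, free, tolerance = 1e-3)
})

test_that("the Lagrangian value upper-bounds the exact constrained optimum", {
  set.seed(41)
  for (rep in 1:3) {
    p1 <- random_params(); p2 <- random_params()
    states <- list(list(e = 1, m0 = 2, m1 = 2, b = 0), list(e = 2, m0 = 2, m1 = 1, b = 1))
    sdf <- data.frame(e = c(1L, 2L), m0 = c(2L, 2L), m1 = c(2L, 1L), b = c(0, 1))
    pm <- rbind(as.data.frame(unclass(p1)), as.data.frame(unclass(p2)))
    alpha <- 0.5
    exact <- brute_constrained_value(list(p1, p2), states, b_g = 1, TT = 3, alpha = alpha)
    sol <- lagrangian_group_value(pm, sdf, b_g = 1, horizon = 3, alpha = alpha)
    expect_gte(sol$relaxed_value, exact - 1e-8)
  }
})

test_that("water-filling matches exhaustive maximin search on tabulated values", {
  L <- list(c(0, 5, 6), c(0, 3, 5))  # value at budgets 0, 1, 2
  vf <- function(g, b) L[[g]][b + 1]
  alloc <- mmr_allocate(vf, n_groups = 2, B = 2)
  expect_equal(alloc$budgets, c(1L, 1L))
  expect_equal(min(alloc$group_values), 3)
  # exhaustive check over all splits of the budget
  splits <- expand.grid(b1 = 0:2, b2 = 0:2)
  splits <- splits[splits$b1 + splits$b2 <= 2, ]
  best <- max(apply(splits, 1, function(s) min(vf(1, s[1]), vf(2, s[2]))))
  expect_equal(min(alloc$group_values), best)
  # degenerate cases
  expect_equal(mmr_allocate(vf, 1, 2)$budgets, 2L)
  expect_equal(mmr_allocate(vf, 2, 0)$budgets, c(0L, 0L))
  # size caps stop allocation even with budget left over
  expect_equal(mmr_allocate(vf, 2, 4, group_sizes = c(1L, 1L))$budgets, c(1L, 1L))
})

test_that("greedy Nash-welfare matches exhaustive log-sum search on tabulated values", {
  L <- list(c(0, 5, 6), c(0, 3, 5))
  vf <- function(g, b) L[[g]][b + 1]
  alloc <- mnw_allocate(vf, n_groups = 2, B = 2)
  expect_equal(alloc$budgets, c(1L, 1L))
  eps <- 1e-6
  splits <- expand.grid(b1 = 0:2, b2 = 0:2)
  splits <- splits[splits$b1 + splits$b2 <= 2, ]
  obj <- apply(splits, 1, function(s) log(vf(1, s[1]) + eps) + log(vf(2, s[2]) + eps))
  expect_equal(log(alloc$group_values[1] + eps) + log(alloc$group_values[2] + eps),
               max(obj), tolerance = 1e-9)
  expect_equal(mnw_allocate(vf, 1, 2, group_sizes = 2L)$budgets, 2L)
})

test_that("duplicating a group's arms preserves per-capita Lagrangian values", {
  p <- mk_params()
  one <- data.frame(e = 2L, m0 = 2L, m1 = 2L, b = 0)
  two <- one[c(1, 1), ]
  pm1 <- as.data.frame(unclass(p))
  pm2 <- pm1[c(1, 1), ]
  for (b in 0:2) {
    vX <- lagrangian_group_value(pm1, one, b_g = b, horizon = 5)$relaxed_value
    vY <- lagrangian_group_value(pm2, two, b_g = 2 * b, horizon = 5)$relaxed_value
    expect_equal(vY / 2, vX, tolerance = 1e-3)
  }
})

test_that("within-group selection skips arms that do not benefit", {
  p <- mk_params()
  pm <- do.call(rbind, replicate(3, as.data.frame(unclass(p)), simplify = FALSE))
  dropouts <- data.frame(e = c(3L, 3L, 3L), m0 = 3L, m1 = 3L, b = c(0, 0.5, 1))
  expect_identical(within_group_actions(pm, dropouts, 2, 0.01, horizon = 8), integer(0))
  live <- data.frame(e = c(1L, 2L, 2L), m0 = c(2L, 2L, 2L), m1 = c(2L, 2L, 2L),
                     b = c(0, 0, 0))
  expect_identical(within_group_actions(pm, live, 0, 0.01, horizon = 8), integer(0))
  expect_setequal(within_group_actions(pm, live, 3, 0, horizon = 8, alpha = 0.5), 1:3)
  expect_error(within_group_actions(pm, live, 4, 0, horizon = 8), "exceed")
})

test_that("high-risk baselines target unhealthy non-dropout arms", {
  states <- data.frame(e = c(2L, 2L, 3L, 2L, 1L),
                       m0 = 2L, m1 = 2L,
                       b = c(0.2, 0.4, 0.1, 0.9, 0.3))
  # eligible: rows 1, 2, 5 (row 3 dropped out, row 4 believed healthy)
  expect_setequal(baseline_high_risk_random(states, 10), c(1L, 2L, 5L))
  expect_identical(baseline_high_risk_random(states, 0), integer(0))
  set.seed(5)
  a <- baseline_high_risk_random(states, 2)
  set.seed(5)
  b <- baseline_high_risk_random(states, 2)
  expect_identical(a, b)

  msi <- c(5, 2, 99, 99, 9)
  expect_identical(baseline_high_risk_round_robin(states, 2, msi), c(5L, 1L))
  expect_identical(baseline_high_risk_round_robin(states, 0, msi), integer(0))
  # never-intervened (largest months-since) outrank recently intervened
  msi2 <- c(0, 7, 0, 0, 3)
  expect_identical(baseline_high_risk_round_robin(states, 3, msi2), c(2L, 5L, 1L))
})
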