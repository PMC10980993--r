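# Patient model: engagement / clinical / memory factors, the joint kernel,
# rewards, and belief propagation.

test_that("engagement transitions follow the dropout-then-respond factorization", {
  p <- mk_params(p_I_MtoE = 0.75, p_I_MtoD = 0.03)
  expect_equal(
    engagement_transition("Maintenance", "Intervention", p),
    c(Engaged = 0.7275, Maintenance = 0.2425, Dropout = 0.03)
  )
  expect_equal(
    engagement_transition("Dropout", "Intervention", p),
    c(Engaged = 0, Maintenance = 0, Dropout = 1)
  )
  p2 <- mk_params(p_U_MtoD = 0.10)
  expect_equal(
    engagement_transition("Engaged", "SelfCare", p2),
    c(Engaged = 0, Maintenance = 0.90, Dropout = 0.10)
  )
  set.seed(11)
  for (i in 1:20) {
    pr <- random_params()
    for (e in c("Engaged", "Maintenance", "Dropout")) for (a in c("SelfCare", "Intervention")) {
      v <- engagement_transition(e, a, pr)
      expect_equal(sum(v), 1, tolerance = 1e-12)
      expect_true(all(v >= 0))
      if (a == "SelfCare") expect_identical(unname(v["Engaged"]), 0)
    }
  }
})

test_that("engagement transition distribution matches Monte-Carlo frequencies", {
  p <- mk_params(p_I_MtoE = 0.75, p_I_MtoD = 0.03)
  probs <- engagement_transition("Maintenance", "Intervention", p)
  set.seed(42)
  u <- runif(2e5)
  draws <- 1L + (u >= probs[1]) + (u >= probs[1] + probs[2])
  freq <- tabulate(draws, 3) / 2e5
  se <- sqrt(probs * (1 - probs) / 2e5)
  expect_true(all(abs(freq - probs) < 3 * se + 1e-9))
})

test_that("clinical transitions boost improvement only when engaged 3 months ago", {
  p <- mk_params(p_improve_bg = 0.075, boost = 0.5, p_relapse_bg = 0.005)
  expect_equal(clinical_transition_prob("A1cGe8", "Engaged", p), 0.1125)
  expect_equal(clinical_transition_prob("A1cGe8", "Maintenance", p), 0.075)
  expect_equal(clinical_transition_prob("A1cLt8", "Dropout", p), 0.995)
  # healthy-state retention ignores past engagement
  expect_equal(clinical_transition_prob("A1cLt8", "Engaged", p), 0.995)
  # boosted probability is capped at 1
  pb <- mk_params(p_improve_bg = 0.9, boost = 2)
  expect_equal(clinical_transition_prob("A1cGe8", "Engaged", pb), 1)
})

test_that("memory is a sliding window of past engagement", {
  expect_equal(memory_transition("Engaged", c("Maintenance", "Maintenance")),
               c("Engaged", "Maintenance"))
  expect_equal(memory_transition("Dropout", c("Dropout", "Dropout")),
               c("Dropout", "Dropout"))
  expect_equal(memory_transition("Maintenance", c("Engaged", "Dropout")),
               c("Maintenance", "Engaged"))
})

test_that("state indexing is a bijection over the 54 joint states", {
  states <- enumerate_states()
  expect_equal(nrow(states), 54L)
  idx <- state_index(states$s_E, states$s_C, states$m0, states$m1)
  expect_identical(idx, states$index)
  back <- index_state(idx)
  expect_identical(back$label, states$label)
})

test_that("the joint kernel satisfies its structural invariants", {
  set.seed(7)
  states <- enumerate_states()
  for (i in 1:8) {
    p <- if (i == 1) mk_params() else random_params()
    k <- build_transition_kernel(p)
    for (a in c("SelfCare", "Intervention")) {
      P <- k[[a]]
      expect_true(all(abs(rowSums(P) - 1) < 1e-12))
      expect_true(all(P >= 0))
      # Dropout absorbing in the engagement dimension
      from_d <- states$s_E == "Dropout"
      to_d <- states$s_E == "Dropout"
      expect_true(all(abs(rowSums(P[from_d, to_d, drop = FALSE]) - 1) < 1e-12))
    }
    # self-care never yields Engaged
    to_e <- states$s_E == "Engaged"
    expect_true(all(rowSums(k$SelfCare[, to_e, drop = FALSE]) == 0))
    # delay property: the one-step clinical marginal depends on (s_C, m1) only
    healthy_to <- states$s_C == "A1cLt8"
    for (a in c("SelfCare", "Intervention")) {
      marg <- rowSums(k[[a]][, healthy_to, drop = FALSE])
      ref <- vapply(seq_len(54), function(j) {
        clinical_transition_prob(states$s_C[j], states$m1[j], p)
      }, numeric(1))
      expect_equal(marg, ref, tolerance = 1e-12, ignore_attr = TRUE)
    }
    # engaging 3 months ago weakly increases the improvement probability
    expect_gte(clinical_transition_prob("A1cGe8", "Engaged", p),
               clinical_transition_prob("A1cGe8", "Maintenance", p))
  }
})

test_that("a factored kernel entry matches the product of its factors", {
  p <- mk_params(p_U_MtoD = 0.10, p_improve_bg = 0.075, boost = 0.5)
  k <- build_transition_kernel(p)
  i <- state_index("Maintenance", "A1cGe8", "Maintenance", "Engaged")
  j <- state_index("Maintenance", "A1cLt8", "Maintenance", "Maintenance")
  expect_equal(k$SelfCare[i, j], 0.90 * 0.1125, tolerance = 1e-12)
})

test_that("rewards combine engagement and clinical indicators by alpha", {
  s_lt <- patient_state("Maintenance", "A1cLt8", c("Maintenance", "Maintenance"))
  expect_equal(state_reward(s_lt, alpha = 0), 1)
  s_drop <- patient_state("Dropout", "A1cLt8", c("Dropout", "Dropout"))
  expect_equal(state_reward(s_drop, alpha = 1), 0)
  s_m <- patient_state("Maintenance", "A1cGe8", c("Maintenance", "Maintenance"))
  expect_equal(state_reward(s_m, alpha = 0.25), 0.25)
  b <- belief_patient_state("Maintenance", c("Maintenance", "Maintenance"), 0.4, 2L)
  expect_equal(state_reward(b, alpha = 0.5), 0.5 * 1 + 0.5 * 0.4)
})

test_that("belief propagation advances, collapses and counts months correctly", {
  p <- mk_params(p_improve_bg = 0.075, p_relapse_bg = 0.005)
  b0 <- belief_patient_state("Maintenance", c("Maintenance", "Maintenance"), 0, 0L)
  b1 <- belief_propagate(b0, "SelfCare", p, "Maintenance")
  expect_equal(b1$clinical_belief, 0.075)
  expect_equal(b1$months_unobserved, 1L)
  expect_equal(b1$s_M, c("Maintenance", "Maintenance"))

  b_obs <- belief_propagate(b1, "SelfCare", p, "Maintenance",
                            clinical_observation = "A1cLt8")
  expect_equal(b_obs$clinical_belief, 1)
  expect_equal(b_obs$months_unobserved, 0L)

  b_h <- belief_patient_state("Maintenance", c("Maintenance", "Maintenance"), 1, 0L)
  b_h1 <- belief_propagate(b_h, "SelfCare", p, "Maintenance")
  expect_equal(b_h1$clinical_belief, 0.995)

  expect_error(
    belief_propagate(b1, "SelfCare", p, "Dropout", clinical_observation = "A1cGe8"),
    "unobservable"
  )
  # the counter caps at the horizon
  b <- b0
  for (i in 1:25) b <- belief_propagate(b, "SelfCare", p, "Maintenance", horizon = 18L)
  expect_equal(b$months_unobserved, 18L)
})

test_that("observation-free belief equals the exact k-step chain marginal", {
  set.seed(21)
  for (rep in 1:5) {
    p <- random_params()
    eng_path <- c("Engaged", "Maintenance", "Maintenance", "Dropout", "Dropout",
                  "Dropout", "Dropout")
    b <- belief_patient_state("Maintenance", c("Engaged", "Maintenance"), 0, 0L)
    dist <- c(1, 0)  # (A1cGe8, A1cLt8), known unhealthy
    cur <- b
    for (k in seq_along(eng_path)) {
      m1 <- cur$s_M[2]
      pimp <- clinical_transition_prob("A1cGe8", m1, p)
      stay <- clinical_transition_prob("A1cLt8", m1, p)
      M <- rbind(c(1 - pimp, pimp), c(1 - stay, stay))
      dist <- as.numeric(dist %*% M)
      cur <- belief_propagate(cur, "SelfCare", p, eng_path[k])
      expect_equal(cur$clinical_belief, dist[2], tolerance = 1e-12)
      expect_equal(cur$months_unobserved, k)
    }
  }
})

test_that("invalid states and parameters are rejected", {
  expect_error(patient_params(0.9, 0.5, 0.03, 0.1, 0.075, 0.005, 0.5, 0.3),
               "p_I_EtoE")
  expect_error(patient_params(0.75, 0.99, 0.2, 0.1, 0.075, 0.005, 0.5, 0.3),
               "p_I_MtoD")
  expect_error(patient_params(0.75, 0.99, 0.03, 0.1, 1.5, 0.005, 0.5, 0.3),
               "\\[0, 1\\]")
  expect_error(engagement_transition("Elsewhere", "SelfCare", mk_params()),
               "unknown engagement state")
  expect_error(belief_patient_state("Engaged", c("Maintenance", "Maintenance"), 0.4, 0L),
               "months_unobserved")
})
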