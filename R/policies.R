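# Planning engine: finite-horizon DP on the belief-MDP, the Whittle-index
# policy, per-group Lagrangian value functions, the maximin (water-filling)
# and maximum-Nash-welfare budget allocators, and standard-of-care baselines.

as_param_matrix <- function(x) {
  if (inherits(x, "patient_params")) x <- as.data.frame(unclass(x)[PARAM_NAMES])
  m <- as.matrix(as.data.frame(x)[, PARAM_NAMES, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# integer/belief codes of a single state object (full or belief state)
belief_codes <- function(state) {
  if (inherits(state, "patient_state")) {
    list(e = eng_code(state$s_E), m0 = eng_code(state$s_M[1]),
         m1 = eng_code(state$s_M[2]), b = as.numeric(state$s_C == "A1cLt8"))
  } else if (inherits(state, "belief_patient_state")) {
    list(e = eng_code(state$s_E), m0 = eng_code(state$s_M[1]),
         m1 = eng_code(state$s_M[2]), b = state$clinical_belief)
  } else {
    stop("state must be a patient_state or belief_patient_state")
  }
}

# batch belief-state data.frame with columns e, m0, m1, b (integer codes)
as_belief_frame <- function(states) {
  if (inherits(states, "patient_state") || inherits(states, "belief_patient_state")) {
    s <- belief_codes(states)
    return(data.frame(e = s$e, m0 = s$m0, m1 = s$m1, b = s$b))
  }
  states <- as.data.frame(states)
  stopifnot(all(c("e", "m0", "m1", "b") %in% names(states)))
  states
}

#' Finite-horizon value function of one arm
#'
#' Solves the belief-state MDP of a single patient by backward induction
#' over the reachable belief states. Acting incurs a subtractive charge
#' `lambda` per intervention; rewards accrue on the successor state each
#' month, and the value at the horizon is identically zero.
#'
#' @param params A [patient_params()] object.
#' @param state Start state ([patient_state()] or [belief_patient_state()]).
#' @param horizon Planning horizon `H` (months).
#' @param alpha Engagement reward weight.
#' @param lambda Per-action charge (Lagrange multiplier).
#' @param t Current 0-based decision epoch; `horizon - t` epochs remain.
#' @return A `value_function`: list with the root `value`, root `q_values`
#'   (`Q_U`, `Q_I`), and a `table` of all reachable `(t, state)` pairs with
#'   their values.
#' @export
finite_horizon_dp <- function(params, state, horizon, alpha = 0, lambda = 0, t = 0L) {
  validate_patient_params(params)
  if (!is.finite(lambda)) stop("lambda must be finite")
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  TT <- as.integer(horizon) - as.integer(t)
  if (TT < 1L) stop("horizon must exceed t by at least one month")
  s <- belief_codes(state)
  tab <- cpp_arm_dp_table(as_param_matrix(params)[1, ], s$e, s$m0, s$m1, s$b,
                          TT, alpha, lambda)
  tab$t <- tab$t + as.integer(t)
  root <- tab[1, ]
  structure(
    list(value = root$V, q_values = c(Q_U = root$Q_U, Q_I = root$Q_I),
         table = tab, horizon = as.integer(horizon), alpha = alpha, lambda = lambda),
    class = "value_function"
  )
}

#' @export
print.value_function <- function(x, ...) {
  cat(sprintf("<value_function> V = %.6f (Q_U = %.6f, Q_I = %.6f), %d reachable (t, state) pairs\n",
              x$value, x$q_values[1], x$q_values[2], nrow(x$table)))
  invisible(x)
}

#' Whittle index of an arm-state
#'
#' The action charge at which intervening and self-care are equally valuable
#' under the finite-horizon DP, found by bisection on an adaptively expanded
#' bracket starting from `[-1, 2]`. If no sign change is found within the
#' expanded bracket the nearest endpoint is returned with a warning.
#'
#' @inheritParams finite_horizon_dp
#' @param tol Bisection tolerance on the charge.
#' @return The index (a scalar charge).
#' @export
whittle_index <- function(params, state, t, horizon, alpha = 0, tol = 1e-4) {
  validate_patient_params(params)
  TT <- as.integer(horizon) - as.integer(t)
  if (TT < 1L) stop("t must be smaller than horizon")
  s <- belief_codes(state)
  cpp_whittle(as_param_matrix(params)[1, ], s$e, s$m0, s$m1, s$b, TT, alpha, tol)
}

#' Whittle-index (Opt) arm selection
#'
#' Acts on the `B` arms with the largest Whittle index at the current belief
#' states; ties are broken uniformly at random using the calling RNG.
#'
#' @param params Cohort parameters: a data.frame/matrix with one row per arm
#'   and the [patient_params()] columns.
#' @param states Belief states: data.frame with integer columns `e`, `m0`,
#'   `m1` and numeric `b` (one row per arm).
#' @inheritParams finite_horizon_dp
#' @param B Per-round budget.
#' @param tol Bisection tolerance passed to the index computation.
#' @return Integer row indices of the selected arms (length `<= B`).
#' @export
opt_policy <- function(params, states, t, horizon, alpha = 0, B, tol = 1e-4) {
  states <- as_belief_frame(states)
  n <- nrow(states)
  if (B <= 0 || n == 0) return(integer(0))
  TT <- as.integer(horizon) - as.integer(t)
  idx <- cpp_whittle_batch(as_param_matrix(params),
                           as.integer(states$e), as.integer(states$m0),
                           as.integer(states$m1), as.numeric(states$b),
                           TT, alpha, tol)
  ord <- order(-idx, runif(n))
  ord[seq_len(min(B, n))]
}

#' Relaxed (Lagrangian) value of a group under a per-round budget
#'
#' Minimizes `lambda * b_g * T + sum_n V_n(lambda)` over the charge
#' `lambda >= 0` by golden-section search, where `V_n(lambda)` is each group
#' member's finite-horizon DP value at charge `lambda` and `T` the remaining
#' horizon. The minimized value upper-bounds the exact budget-constrained
#' group value.
#'
#' @inheritParams opt_policy
#' @param b_g Per-round budget available to the group.
#' @param lambda_max Upper end of the search interval.
#' @param tol Golden-section tolerance on lambda.
#' @return A `lagrange_solution`: list with `lambda_star`, `relaxed_value`
#'   and `per_arm_values`.
#' @export
lagrangian_group_value <- function(params, states, b_g, horizon, alpha = 0,
                                   t = 0L, lambda_max = 2, tol = 1e-4) {
  states <- as_belief_frame(states)
  if (b_g < 0) stop("b_g must be non-negative")
  TT <- as.integer(horizon) - as.integer(t)
  if (TT < 1L) stop("horizon must exceed t")
  pm <- as_param_matrix(params)
  e <- as.integer(states$e); m0 <- as.integer(states$m0)
  m1 <- as.integer(states$m1); b <- as.numeric(states$b)
  g <- function(lam) {
    lam * b_g * TT + sum(cpp_group_value_curve(pm, e, m0, m1, b, TT, alpha, lam))
  }
  phi <- (sqrt(5) - 1) / 2
  lo <- 0; hi <- lambda_max
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  f1 <- g(x1); f2 <- g(x2)
  while (hi - lo > tol) {
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- g(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- g(x2)
    }
  }
  lambda_star <- (lo + hi) / 2
  per_arm <- as.numeric(cpp_group_values_at(pm, e, m0, m1, b, TT, alpha, lambda_star))
  structure(
    list(lambda_star = lambda_star,
         relaxed_value = lambda_star * b_g * TT + sum(per_arm),
         per_arm_values = per_arm),
    class = "lagrange_solution"
  )
}

#' @export
print.lagrange_solution <- function(x, ...) {
  cat(sprintf("<lagrange_solution> lambda* = %.5f, L = %.5f over %d arms\n",
              x$lambda_star, x$relaxed_value, length(x$per_arm_values)))
  invisible(x)
}

#' Maximin-reward (water-filling) budget allocation
#'
#' Starting from zero, repeatedly gives one budget unit to the group whose
#' current relaxed value `L_g(s_g, b_g)` is smallest, until the total budget
#' `B` is spent; ties go to the lowest group id. Groups at their size cap
#' (when `group_sizes` is supplied) receive no further units.
#'
#' @param value_fn Function `(g, b) -> L_g(s_g, b)` returning a group's
#'   relaxed value at budget `b` (groups indexed 1..`n_groups`).
#' @param n_groups Number of groups.
#' @param B Total per-round budget.
#' @param group_sizes Optional per-group caps on the budget.
#' @return A `group_allocation`: list with integer `budgets`, the final
#'   `group_values`, and `objective = "MMR"`.
#' @export
mmr_allocate <- function(value_fn, n_groups, B, group_sizes = NULL) {
  budgets <- integer(n_groups)
  vals <- vapply(seq_len(n_groups), function(g) value_fn(g, 0L), numeric(1))
  for (i in seq_len(B)) {
    ok <- if (is.null(group_sizes)) rep(TRUE, n_groups) else budgets < group_sizes
    if (!any(ok)) break
    g <- which(ok)[which.min(vals[ok])]
    budgets[g] <- budgets[g] + 1L
    vals[g] <- value_fn(g, budgets[g])
  }
  structure(list(budgets = budgets, group_values = vals, objective = "MMR"),
            class = "group_allocation")
}

#' Maximum-Nash-welfare (equalized groups) budget allocation
#'
#' Greedily gives each budget unit to the group with the largest marginal
#' increase in the logarithm of its per-capita relaxed value, the
#' equalized-groups correction for unequal group sizes. If any per-capita
#' value is non-positive, all values are shifted by a common constant so the
#' smallest becomes `epsilon` before taking logs.
#'
#' @inheritParams mmr_allocate
#' @param group_sizes Per-group arm counts `|g|` used for the per-capita
#'   correction and as budget caps; defaults to 1 for every group.
#' @param epsilon Positive floor applied by the shift.
#' @return A `group_allocation` with `objective = "MNW"`.
#' @export
mnw_allocate <- function(value_fn, n_groups, B, group_sizes = NULL, epsilon = 1e-6) {
  sizes <- if (is.null(group_sizes)) rep(1, n_groups) else group_sizes
  budgets <- integer(n_groups)
  vcap <- function(g, b) value_fn(g, b) / sizes[g]
  cur <- vapply(seq_len(n_groups), function(g) vcap(g, 0L), numeric(1))
  nxt <- vapply(seq_len(n_groups), function(g) vcap(g, 1L), numeric(1))
  shift <- if (min(cur) <= 0) epsilon - min(cur) else 0
  for (i in seq_len(B)) {
    ok <- budgets < sizes
    if (!any(ok)) break
    gain <- log(nxt + shift) - log(cur + shift)
    if (any(!is.finite(gain[ok]))) stop("non-finite log of a group value after shifting")
    g <- which(ok)[which.max(gain[ok])]
    budgets[g] <- budgets[g] + 1L
    cur[g] <- nxt[g]
    nxt[g] <- if (budgets[g] < sizes[g]) vcap(g, budgets[g] + 1L) else NA_real_
  }
  vals <- cur * sizes
  structure(list(budgets = budgets, group_values = vals, objective = "MNW"),
            class = "group_allocation")
}

#' @export
print.group_allocation <- function(x, ...) {
  cat(sprintf("<group_allocation> %s budgets: %s\n", x$objective,
              paste(x$budgets, collapse = ", ")))
  invisible(x)
}

#' Select arms within a group under its Lagrangian charge
#'
#' Acts on the `b_g` group members with the largest action advantage
#' `Q_I - Q_U` evaluated at the group's optimal charge `lambda_star`. Arms
#' whose advantage is not positive are skipped, so part of the group budget
#' may lapse; ties are broken uniformly at random.
#'
#' @inheritParams opt_policy
#' @param b_g Budget assigned to this group.
#' @param lambda_star The group's Lagrangian charge.
#' @return Integer row indices of the selected arms (length `<= b_g`).
#' @export
within_group_actions <- function(params, states, b_g, lambda_star, t = 0L,
                                 horizon, alpha = 0) {
  states <- as_belief_frame(states)
  n <- nrow(states)
  if (b_g <= 0 || n == 0) return(integer(0))
  if (b_g > n) stop("b_g cannot exceed the group size")
  TT <- as.integer(horizon) - as.integer(t)
  adv <- cpp_group_advantages(as_param_matrix(params),
                              as.integer(states$e), as.integer(states$m0),
                              as.integer(states$m1), as.numeric(states$b),
                              TT, alpha, lambda_star)
  ord <- order(-adv, runif(n))
  sel <- ord[seq_len(min(b_g, n))]
  sel[adv[sel] > 0]
}

#' High-risk random-allocation baseline
#'
#' Interventions go to a uniform random subset of the "high risk" patients:
#' those not in Dropout whose belief of having HbA1c < 8 is below one half.
#'
#' @inheritParams opt_policy
#' @return Integer row indices of the selected arms.
#' @export
baseline_high_risk_random <- function(states, B) {
  states <- as_belief_frame(states)
  eligible <- which(states$e != 3L & states$b < 0.5)
  k <- min(B, length(eligible))
  if (k <= 0) return(integer(0))
  eligible[sample.int(length(eligible), k)]
}

#' High-risk round-robin baseline
#'
#' Among the high-risk patients (as in [baseline_high_risk_random()]),
#' prioritizes those with the longest time since their last intervention,
#' breaking ties by the smallest row index.
#'
#' @inheritParams opt_policy
#' @param months_since_intervention Per-arm months since the last
#'   intervention (months since entry for never-intervened arms).
#' @return Integer row indices of the selected arms.
#' @export
baseline_high_risk_round_robin <- function(states, B, months_since_intervention) {
  states <- as_belief_frame(states)
  eligible <- which(states$e != 3L & states$b < 0.5)
  k <- min(B, length(eligible))
  if (k <= 0) return(integer(0))
  ord <- eligible[order(-months_since_intervention[eligible], eligible)]
  ord[seq_len(k)]
}

# Lambda grid used by the in-simulation allocators: quadratic spacing
# concentrates resolution near zero, where group charges typically fall.
default_lambda_grid <- function(lambda_max = 2, n = 33L) {
  lambda_max * (seq(0, n - 1L) / (n - 1L))^2
}

# Cached per-group Lagrangian curve evaluator used by run_simulation().
# For each group the curve F_g(lambda) = sum_n V_n(lambda) is computed once
# per month on the lambda grid; L_g(b) is then the discrete Legendre
# transform min_lambda [lambda * b * T + F_g(lambda)] over the grid.
make_group_planner <- function(par_mat, states, group_of, horizon_left, alpha,
                               lambda_grid = default_lambda_grid()) {
  groups <- sort(unique(group_of))
  env <- new.env(parent = emptyenv())
  env$curves <- vector("list", length(groups))
  idx_of <- function(g) match(g, groups)
  members <- lapply(groups, function(g) which(group_of == g))
  curve <- function(g) {
    i <- idx_of(g)
    if (is.null(env$curves[[i]])) {
      m <- members[[i]]
      env$curves[[i]] <- as.numeric(cpp_group_value_curve(
        par_mat[m, , drop = FALSE],
        as.integer(states$e[m]), as.integer(states$m0[m]),
        as.integer(states$m1[m]), as.numeric(states$b[m]),
        horizon_left, alpha, lambda_grid
      ))
    }
    env$curves[[i]]
  }
  list(
    groups = groups,
    sizes = lengths(members),
    value = function(gi, b) min(lambda_grid * b * horizon_left + curve(groups[gi])),
    lambda_star = function(gi, b) {
      lambda_grid[which.min(lambda_grid * b * horizon_left + curve(groups[gi]))]
    },
    select = function(gi, b_g, lambda_star) {
      m <- members[[idx_of(groups[gi])]]
      if (b_g <= 0) return(integer(0))
      adv <- cpp_group_advantages(
        par_mat[m, , drop = FALSE],
        as.integer(states$e[m]), as.integer(states$m0[m]),
        as.integer(states$m1[m]), as.numeric(states$b[m]),
        horizon_left, alpha, lambda_star
      )
      ord <- order(-adv, runif(length(m)))
      sel <- ord[seq_len(min(b_g, length(m)))]
      m[sel[adv[sel] > 0]]
    }
  )
}
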