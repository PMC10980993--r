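# Equity metrics and the three study analyses: policy comparison at a fixed
# budget, the Pareto sweep over the reward weight, and capacity planning over
# the monthly budget.

#' Gini coefficient
#'
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, the normalized mean absolute
#' difference. Zero-mean input returns 0 by convention (an all-zero profile
#' is perfectly equal).
#'
#' @param values Non-negative values (here: per-group mean rewards).
#' @return Gini coefficient in `[0, 1]`.
#' @export
gini_coefficient <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  if (any(values < 0)) stop("Gini coefficient requires non-negative values")
  m <- mean(values)
  if (m == 0) return(0)
  n <- length(values)
  sum(abs(outer(values, values, "-"))) / (2 * n^2 * m)
}

#' Mean absolute difference
#'
#' Mean of `|x_i - x_j|` over unordered pairs.
#'
#' @param values At least two values.
#' @return Non-negative scalar.
#' @export
mean_absolute_difference <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least two values")
  d <- abs(outer(values, values, "-"))
  sum(d[upper.tri(d)]) / choose(n, 2)
}

# per-seed scalar summary used by the analysis wrappers
seed_summary <- function(config, policy, seed) {
  cfg <- config
  cfg$policy <- policy
  res <- run_simulation(cfg, seed)
  s <- month12_summary(res)
  pg <- s$per_group
  tibble::tibble(
    policy = policy, seed = seed,
    healthy_count = s$healthy_count, engaged_count = s$engaged_count,
    dropout_count = s$dropout_count,
    gini = gini_coefficient(pg$mean_final_reward),
    mad_healthy = mean_absolute_difference(pg$healthy_prop),
    mad_engaged = mean_absolute_difference(pg$engaged_prop),
    per_group = list(pg)
  )
}

se <- function(x) stats::sd(x) / sqrt(length(x))

#' Compare policies under common random numbers
#'
#' Runs every policy over the same seed set (hence identical cohorts and
#' enrollment) and summarizes twelve-month outcomes: mean and standard error
#' of the healthy / engaged / dropout counts, the Gini coefficient over the
#' six per-group mean final rewards, and the mean absolute difference of
#' per-group healthy and engagement proportions.
#'
#' @param config A [simulation_config()]; its `policy` field is ignored.
#' @param policies Character vector of policy names.
#' @param seeds Integer vector of seeds shared by all policies.
#' @return A `policy_comparison`: list with `summary` (one row per policy),
#'   `per_seed` (one row per policy x seed) and `per_group` (long format)
#'   tibbles.
#' @export
compare_policies <- function(config, policies, seeds = seq_len(config$n_seeds)) {
  if (anyDuplicated(seeds)) stop("seeds must be distinct so policies share one cohort per seed")
  per_seed <- do.call(rbind, lapply(policies, function(p) {
    do.call(rbind, lapply(seeds, function(s) seed_summary(config, p, s)))
  }))
  per_group <- do.call(rbind, lapply(seq_len(nrow(per_seed)), function(i) {
    pg <- per_seed$per_group[[i]]
    pg$policy <- per_seed$policy[i]; pg$seed <- per_seed$seed[i]
    tibble::as_tibble(pg)
  }))
  summary <- do.call(rbind, lapply(policies, function(p) {
    x <- per_seed[per_seed$policy == p, ]
    tibble::tibble(
      policy = p,
      healthy_mean = mean(x$healthy_count), healthy_se = se(x$healthy_count),
      engaged_mean = mean(x$engaged_count), engaged_se = se(x$engaged_count),
      dropout_mean = mean(x$dropout_count), dropout_se = se(x$dropout_count),
      gini_mean = mean(x$gini), gini_se = se(x$gini),
      mad_healthy_mean = mean(x$mad_healthy),
      mad_engaged_mean = mean(x$mad_engaged)
    )
  }))
  structure(list(summary = summary,
                 per_seed = per_seed[, setdiff(names(per_seed), "per_group")],
                 per_group = per_group,
                 config = config, seeds = seeds),
            class = "policy_comparison")
}

#' @export
print.policy_comparison <- function(x, ...) {
  cat(sprintf("<policy_comparison> N=%d B=%d alpha=%.2f domain=%s, %d seeds\n",
              x$config$N, x$config$B, x$config$alpha, x$config$domain, length(x$seeds)))
  print(x$summary)
  invisible(x)
}

#' Engagement / health trade-off sweep over the reward weight
#'
#' Runs the policy at each value of `alpha` (shared seeds) and reports the
#' mean twelve-month engaged and healthy counts, tracing the policy's
#' Pareto curve between the two outcomes.
#'
#' @inheritParams compare_policies
#' @param policy A single policy name.
#' @param alpha_grid Values of the engagement weight in `[0, 1]`.
#' @return Tibble with one row per `alpha`.
#' @export
pareto_sweep <- function(config, policy, alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                         seeds = seq_len(config$n_seeds)) {
  if (any(alpha_grid < 0 | alpha_grid > 1)) stop("alpha_grid must lie in [0, 1]")
  do.call(rbind, lapply(alpha_grid, function(a) {
    cfg <- config; cfg$alpha <- a
    x <- do.call(rbind, lapply(seeds, function(s) seed_summary(cfg, policy, s)))
    tibble::tibble(
      alpha = a, policy = policy,
      engaged_mean = mean(x$engaged_count), engaged_se = se(x$engaged_count),
      healthy_mean = mean(x$healthy_count), healthy_se = se(x$healthy_count),
      dropout_mean = mean(x$dropout_count), dropout_se = se(x$dropout_count)
    )
  }))
}

#' Capacity curve: outcomes as a function of the monthly budget
#'
#' @inheritParams compare_policies
#' @param policy A single policy name.
#' @param budget_grid Strictly increasing monthly budgets.
#' @return A `capacity_curve` tibble with columns `budget`, `healthy_mean`,
#'   `healthy_se`, `policy`.
#' @export
capacity_curve <- function(config, policy, budget_grid, seeds = seq_len(config$n_seeds)) {
  if (is.unsorted(budget_grid, strictly = TRUE)) stop("budget_grid must be strictly increasing")
  out <- do.call(rbind, lapply(budget_grid, function(b) {
    cfg <- config; cfg$B <- as.integer(b)
    x <- do.call(rbind, lapply(seeds, function(s) seed_summary(cfg, policy, s)))
    tibble::tibble(budget = b, policy = policy,
                   healthy_mean = mean(x$healthy_count), healthy_se = se(x$healthy_count))
  }))
  class(out) <- c("capacity_curve", class(out))
  out
}

interpolate_crossing <- function(budgets, means, target) {
  hit <- which(means >= target)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  if (i == 1L) return(budgets[1])
  budgets[i - 1] + (target - means[i - 1]) / (means[i] - means[i - 1]) *
    (budgets[i] - budgets[i - 1])
}

#' Smallest budget reaching a twelve-month healthy-count target
#'
#' Sweeps the budget grid (or reuses a supplied [capacity_curve()]) and
#' reports both the smallest grid budget whose mean healthy count reaches
#' the target and the linearly interpolated crossing between grid points.
#'
#' @inheritParams capacity_curve
#' @param target_count Target number of patients with HbA1c < 8 at month 12.
#' @param curve Optional precomputed [capacity_curve()] for this policy.
#' @return A `capacity_plan`: list with the `curve`, `budget_grid_answer`,
#'   `budget_interpolated`, `reachable`, `policy` and `target_count`.
#' @export
capacity_plan <- function(config, policy, budget_grid, target_count,
                          seeds = seq_len(config$n_seeds), curve = NULL) {
  if (is.null(curve)) curve <- capacity_curve(config, policy, budget_grid, seeds)
  hit <- which(curve$healthy_mean >= target_count)
  reachable <- length(hit) > 0
  structure(
    list(curve = curve,
         budget_grid_answer = if (reachable) curve$budget[hit[1]] else NA_real_,
         budget_interpolated = interpolate_crossing(curve$budget, curve$healthy_mean,
                                                    target_count),
         reachable = reachable, policy = policy, target_count = target_count),
    class = "capacity_plan"
  )
}

#' @export
print.capacity_plan <- function(x, ...) {
  if (x$reachable) {
    cat(sprintf("<capacity_plan> %s reaches %g healthy patients at budget %g (grid) / %.1f (interpolated)\n",
                x$policy, x$target_count, x$budget_grid_answer, x$budget_interpolated))
  } else {
    cat(sprintf("<capacity_plan> %s: target %g unreachable on the swept budgets\n",
                x$policy, x$target_count))
  }
  invisible(x)
}

#' Cost of fairness: extra budget versus the utilitarian optimum
#'
#' For each policy's capacity curve, the horizontal distance (in budget
#' units, interpolated) to the Whittle-optimal curve at the target outcome.
#'
#' @param curves Named list of [capacity_curve()] tibbles sharing one budget
#'   grid; must include `"opt"`.
#' @param target_count Target twelve-month healthy count.
#' @return Tibble with `policy` and `extra_budget` (`NA` when either curve
#'   does not reach the target).
#' @export
cost_of_fairness <- function(curves, target_count) {
  if (!"opt" %in% names(curves)) stop("curves must include the 'opt' policy")
  grids <- lapply(curves, function(cc) cc$budget)
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    stop("all curves must share the same budget grid")
  }
  ref <- interpolate_crossing(curves$opt$budget, curves$opt$healthy_mean, target_count)
  do.call(rbind, lapply(names(curves), function(p) {
    own <- interpolate_crossing(curves[[p]]$budget, curves[[p]]$healthy_mean, target_count)
    tibble::tibble(policy = p,
                   extra_budget = if (is.na(own) || is.na(ref)) NA_real_ else own - ref)
  }))
}
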