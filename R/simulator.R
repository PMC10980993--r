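# Month-by-month cohort simulation: staggered enrollment, policy queries,
# latent state transitions, observation generation and belief filtering.

#' Simulation configuration
#'
#' @param N Number of patients.
#' @param H Horizon in months. Twelve-month outcomes require the horizon to
#'   cover every patient's twelfth month after entry (entry month up to 5,
#'   so `H >= 17`).
#' @param B Monthly intervention budget.
#' @param alpha Engagement reward weight used by the planning policies.
#' @param policy One of [policy_registry()].
#' @param n_seeds Default number of seeds used by the analysis helpers.
#' @param domain `"marketscan"` (canonical groups) or `"counterexample"`.
#' @param sigma Per-patient parameter jitter standard deviation.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(N = 300L, H = 18L, B = 30L, alpha = 0,
                              policy = "no_action", n_seeds = 50L,
                              domain = c("marketscan", "counterexample"),
                              sigma = 0.05) {
  domain <- match.arg(domain)
  if (!policy %in% policy_registry()) {
    stop("unknown policy '", policy, "'; known: ", paste(policy_registry(), collapse = ", "))
  }
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (N < 6) stop("N must be at least the number of groups (6)")
  if (B < 0) stop("B must be non-negative")
  if (H < 1) stop("H must be positive")
  structure(
    list(N = as.integer(N), H = as.integer(H), B = as.integer(B), alpha = alpha,
         policy = policy, n_seeds = as.integer(n_seeds), domain = domain,
         sigma = sigma),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %s: N=%d H=%d B=%d alpha=%.2f domain=%s sigma=%g\n",
              x$policy, x$N, x$H, x$B, x$alpha, x$domain, x$sigma))
  invisible(x)
}

domain_groups <- function(domain) {
  switch(domain,
         marketscan = canonical_group_table(),
         counterexample = counterexample_group_table(),
         stop("unknown domain: ", domain))
}

#' Sample one patient month
#'
#' Draws the next latent state from the joint transition model and, with the
#' engagement-dependent observation probability (1 if the next state is
#' Engaged, `q_obs_maint` if Maintenance, 0 if Dropout), an observation of
#' the next clinical state. Uses the calling RNG.
#'
#' @param state A [patient_state()].
#' @param action `"SelfCare"` or `"Intervention"`.
#' @param params A [patient_params()] object.
#' @return List with `next_state` (a [patient_state()]) and
#'   `clinical_observation` (a clinical state name, or `NULL`).
#' @export
step_patient <- function(state, action, params) {
  if (!inherits(state, "patient_state")) stop("state must be a patient_state")
  pe <- engagement_transition(state$s_E, action, params)
  u <- runif(3)
  ne <- 1L + (u[1] >= pe[1]) + (u[1] >= pe[1] + pe[2])
  pL <- clinical_transition_prob(state$s_C, state$s_M[2], params)
  nc <- if (u[2] < pL) 2L else 1L
  nm <- memory_transition(state$s_E, state$s_M)
  q <- c(1, params$q_obs_maint, 0)[ne]
  obs <- if (u[3] < q) CLINICAL_LEVELS[nc] else NULL
  list(
    next_state = patient_state(ENGAGEMENT_LEVELS[ne], CLINICAL_LEVELS[nc], nm),
    clinical_observation = obs
  )
}

# dispatch one month's action selection; returns global patient ids
select_actions <- function(policy, par_mat, st, group_of, active_ids, msi,
                           T_left, alpha, B) {
  if (B <= 0 || length(active_ids) == 0 || policy == "no_action") return(integer(0))
  states <- data.frame(e = st$e[active_ids], m0 = st$m0[active_ids],
                       m1 = st$m1[active_ids], b = st$b[active_ids])
  pm <- par_mat[active_ids, , drop = FALSE]
  sel <- switch(
    policy,
    hr_random = baseline_high_risk_random(states, B),
    hr_round_robin = baseline_high_risk_round_robin(states, B, msi[active_ids]),
    opt = opt_policy(pm, states, t = 0L, horizon = T_left, alpha = alpha, B = B),
    mmr = ,
    mnw_eg = {
      planner <- make_group_planner(pm, states, group_of[active_ids], T_left, alpha)
      alloc <- if (policy == "mmr") {
        mmr_allocate(planner$value, length(planner$groups), B, planner$sizes)
      } else {
        mnw_allocate(planner$value, length(planner$groups), B, planner$sizes)
      }
      picked <- integer(0)
      for (gi in seq_along(planner$groups)) {
        b_g <- alloc$budgets[gi]
        if (b_g > 0) {
          lam <- planner$lambda_star(gi, b_g)
          picked <- c(picked, planner$select(gi, b_g, lam))
        }
      }
      picked
    },
    stop("unknown policy: ", policy)
  )
  active_ids[sel]
}

#' Run one simulation
#'
#' Simulates a cohort for `H` months under the configured policy. Patients
#' enter in five staggered monthly waves at state (Engaged, HbA1c >= 8,
#' memory \[Maintenance, Maintenance\]) with a collapsed clinical belief of 0.
#' Each month the policy sees the belief states of the enrolled patients and
#' selects at most `B` of them for intervention; latent states then advance
#' one month and beliefs are filtered against any new HbA1c observations.
#' All randomness is drawn from named substreams of `seed` (cohort,
#' enrollment, transitions, observations, policy tie-breaks), so two runs
#' with the same configuration and seed are identical and different policies
#' share identical cohorts.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param groups Optional `group_table` overriding the domain's canonical
#'   table (for calibration experiments with custom cohorts).
#' @return A `simulation_result`: list with the `config`, `seed`, `cohort`,
#'   state record matrices (`E`, `C`, `M0`, `M1` latent states, `B` beliefs,
#'   `K` months-unobserved; months in rows, patients in columns), the
#'   action and observation matrices, and `months_since_intervention`.
#' @export
run_simulation <- function(config, seed, groups = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  N <- config$N; H <- config$H
  if (is.null(groups)) groups <- domain_groups(config$domain)
  entry <- enrollment_schedule(N, seed = substream_seed(seed, "enrollment"))
  cohort <- sample_cohort(groups, N, config$sigma,
                          seed = substream_seed(seed, "cohort"),
                          entry_months = entry)
  par_mat <- as_param_matrix(cohort)
  streams <- make_streams(seed, c("transition", "observation", "policy"))

  st <- list(e = rep(NA_integer_, N), c = rep(NA_integer_, N),
             m0 = rep(NA_integer_, N), m1 = rep(NA_integer_, N),
             b = rep(NA_real_, N), k = rep(NA_integer_, N))
  msi <- rep(NA_integer_, N)
  E <- C <- M0 <- M1 <- K <- matrix(NA_integer_, H + 1L, N)
  Bm <- matrix(NA_real_, H + 1L, N)
  ACT <- matrix(FALSE, H, N)
  OBS <- matrix(NA_integer_, H, N)

  for (m in seq_len(H)) {
    newly <- which(entry == m)
    if (length(newly)) {
      st$e[newly] <- 1L; st$c[newly] <- 1L
      st$m0[newly] <- 2L; st$m1[newly] <- 2L
      st$b[newly] <- 0; st$k[newly] <- 0L
      msi[newly] <- 0L
      E[m, newly] <- 1L; C[m, newly] <- 1L
      M0[m, newly] <- 2L; M1[m, newly] <- 2L
      Bm[m, newly] <- 0; K[m, newly] <- 0L
    }
    ai <- which(entry <= m)
    if (!length(ai)) next
    T_left <- H - m + 1L

    sel <- with_stream(streams, "policy",
      select_actions(config$policy, par_mat, st, cohort$group_id, ai, msi,
                     T_left, config$alpha, config$B))
    if (length(sel) > config$B) stop("policy selected more arms than the budget allows")
    ACT[m, sel] <- TRUE
    act <- logical(N); act[sel] <- TRUE

    eA <- st$e[ai]; cA <- st$c[ai]; m1A <- st$m1[ai]
    dropo <- ifelse(act[ai], par_mat[ai, "p_I_MtoD"], par_mat[ai, "p_U_MtoD"])
    respond <- ifelse(eA == 1L, par_mat[ai, "p_I_EtoE"], par_mat[ai, "p_I_MtoE"])
    pE <- ifelse(eA != 3L & act[ai], (1 - dropo) * respond, 0)
    pD <- ifelse(eA == 3L, 1, dropo)
    pM <- 1 - pE - pD
    pimp <- ifelse(m1A == 1L,
                   pmin(1, (1 + par_mat[ai, "boost"]) * par_mat[ai, "p_improve_bg"]),
                   par_mat[ai, "p_improve_bg"])
    pL <- ifelse(cA == 2L, 1 - par_mat[ai, "p_relapse_bg"], pimp)

    u <- with_stream(streams, "transition", list(runif(length(ai)), runif(length(ai))))
    ne <- 1L + (u[[1]] >= pE) + (u[[1]] >= pE + pM)
    nc <- ifelse(u[[2]] < pL, 2L, 1L)

    q <- c(1, 0, 0)[ne]
    q[ne == 2L] <- par_mat[ai, "q_obs_maint"][ne == 2L]
    u3 <- with_stream(streams, "observation", runif(length(ai)))
    seen <- u3 < q
    OBS[m, ai[seen]] <- nc[seen]

    bprop <- st$b[ai] * (1 - par_mat[ai, "p_relapse_bg"]) + (1 - st$b[ai]) * pimp
    bn <- ifelse(seen, as.numeric(nc == 2L), bprop)
    kn <- ifelse(seen, 0L, pmin(st$k[ai] + 1L, H))

    st$m1[ai] <- st$m0[ai]; st$m0[ai] <- eA
    st$e[ai] <- ne; st$c[ai] <- nc
    st$b[ai] <- bn; st$k[ai] <- as.integer(kn)
    msi[ai] <- ifelse(act[ai], 0L, msi[ai] + 1L)

    E[m + 1L, ai] <- ne; C[m + 1L, ai] <- nc
    M0[m + 1L, ai] <- st$m0[ai]; M1[m + 1L, ai] <- st$m1[ai]
    Bm[m + 1L, ai] <- bn; K[m + 1L, ai] <- as.integer(kn)
  }

  structure(
    list(config = config, seed = as.integer(seed), cohort = cohort,
         E = E, C = C, M0 = M0, M1 = M1, B = Bm, K = K,
         actions = ACT, observations = OBS,
         months_since_intervention = msi),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s, N=%d, H=%d, seed=%d\n",
              x$config$policy, x$config$N, x$config$H, x$seed))
  invisible(x)
}

#' Twelve-month outcome summary
#'
#' Counts, over the true latent states, the patients with HbA1c < 8, the
#' patients still engaged (Engaged or Maintenance) and the dropouts at each
#' patient's twelfth month after entry, overall and per demographic group,
#' together with each group's mean final reward (the state reward at month
#' 12 under the configuration's `alpha`) and mean total reward over the
#' first twelve months.
#'
#' @param result A `simulation_result`.
#' @return List with `healthy_count`, `engaged_count`, `dropout_count` and a
#'   `per_group` data.frame.
#' @export
month12_summary <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  entry <- result$cohort$entry_month
  H <- result$config$H
  rows <- entry + 12L
  if (any(rows > H + 1L)) {
    stop("incomplete trajectories: horizon too short for 12-month outcomes (need H >= entry + 11)")
  }
  n <- result$config$N
  pick <- cbind(rows, seq_len(n))
  e12 <- result$E[pick]; c12 <- result$C[pick]
  alpha <- result$config$alpha
  final_reward <- alpha * (e12 != 3L) + (1 - alpha) * (c12 == 2L)
  total_reward <- numeric(n)
  for (j in seq_len(12L)) {
    pj <- cbind(entry + j, seq_len(n))
    total_reward <- total_reward +
      alpha * (result$E[pj] != 3L) + (1 - alpha) * (result$C[pj] == 2L)
  }
  g <- result$cohort$group_id
  per_group <- do.call(rbind, lapply(sort(unique(g)), function(gg) {
    i <- g == gg
    data.frame(
      group_id = gg, n = sum(i),
      healthy = sum(c12[i] == 2L), engaged = sum(e12[i] != 3L),
      dropout = sum(e12[i] == 3L),
      healthy_prop = mean(c12[i] == 2L), engaged_prop = mean(e12[i] != 3L),
      mean_final_reward = mean(final_reward[i]),
      mean_total_reward = mean(total_reward[i])
    )
  }))
  list(
    healthy_count = sum(c12 == 2L),
    engaged_count = sum(e12 != 3L),
    dropout_count = sum(e12 == 3L),
    per_group = per_group
  )
}

#' Write a simulation result to disk
#'
#' Writes a per-month long-format CSV of states, beliefs, actions and
#' observations, a per-patient twelve-month summary CSV, and a JSON metadata
#' file holding the configuration, seed and package version.
#'
#' @param result A `simulation_result`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_simulation_result <- function(result, dir, prefix = "run") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  H <- result$config$H; N <- result$config$N
  month <- rep(seq_len(H + 1L), N)
  pid <- rep(seq_len(N), each = H + 1L)
  long <- data.frame(
    month = month, patient_id = pid,
    s_E = ENGAGEMENT_LEVELS[as.vector(result$E)],
    s_C = CLINICAL_LEVELS[as.vector(result$C)],
    m0 = ENGAGEMENT_LEVELS[as.vector(result$M0)],
    m1 = ENGAGEMENT_LEVELS[as.vector(result$M1)],
    belief = as.vector(result$B),
    months_unobserved = as.vector(result$K),
    action = as.vector(rbind(result$actions, NA)),
    observation = CLINICAL_LEVELS[as.vector(rbind(result$observations, NA_integer_))],
    stringsAsFactors = FALSE
  )
  long <- long[!is.na(long$s_E), ]
  p1 <- file.path(dir, paste0(prefix, "_trajectories.csv"))
  write.csv(long, p1, row.names = FALSE)

  s <- month12_summary(result)
  entry <- result$cohort$entry_month
  pick <- cbind(entry + 12L, seq_len(N))
  m12 <- data.frame(
    patient_id = seq_len(N), group_id = result$cohort$group_id,
    entry_month = entry,
    s_E_12 = ENGAGEMENT_LEVELS[result$E[pick]],
    s_C_12 = CLINICAL_LEVELS[result$C[pick]],
    stringsAsFactors = FALSE
  )
  p2 <- file.path(dir, paste0(prefix, "_month12.csv"))
  write.csv(m12, p2, row.names = FALSE)

  meta <- list(
    config = unclass(result$config), seed = result$seed,
    package_version = as.character(utils::packageVersion("ermab")),
    healthy_count = s$healthy_count, engaged_count = s$engaged_count,
    dropout_count = s$dropout_count
  )
  p3 <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3))
}
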