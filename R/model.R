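# Patient-level Markov model: joint engagement / clinical / memory dynamics,
# the action-conditioned transition kernel, rewards, and belief-state updates
# for the intermittently observed clinical dimension.

eng_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(is.na(x)) || any(x < 1L | x > 3L)) {
      stop("engagement state code must be 1 (Engaged), 2 (Maintenance) or 3 (Dropout)")
    }
    return(x)
  }
  i <- match(x, ENGAGEMENT_LEVELS)
  if (any(is.na(i))) stop("unknown engagement state: ", paste(x[is.na(i)], collapse = ", "))
  i
}

clin_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(is.na(x)) || any(x < 1L | x > 2L)) {
      stop("clinical state code must be 1 (A1cGe8) or 2 (A1cLt8)")
    }
    return(x)
  }
  i <- match(x, CLINICAL_LEVELS)
  if (any(is.na(i))) stop("unknown clinical state: ", paste(x[is.na(i)], collapse = ", "))
  i
}

action_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(is.na(x)) || any(x < 1L | x > 2L)) stop("action code must be 1 or 2")
    return(x)
  }
  i <- match(x, ACTION_LEVELS)
  if (any(is.na(i))) stop("unknown action: ", paste(x[is.na(i)], collapse = ", "))
  i
}

#' Per-patient transition and observation parameters
#'
#' Bundles the four engagement parameters, the four clinical-progression
#' quantities (two background monthly rates plus the relative engagement boost
#' that defines the boosted improvement rate), and the probability of
#' observing the clinical state of a patient in Maintenance.
#'
#' @param p_I_MtoE Probability of responding to an intervention (moving to
#'   Engaged) from Maintenance.
#' @param p_I_EtoE Probability of responding to an intervention from Engaged.
#'   Must be at least `p_I_MtoE`.
#' @param p_I_MtoD Monthly dropout probability under an intervention. Must not
#'   exceed `p_U_MtoD`.
#' @param p_U_MtoD Monthly dropout probability under self-care.
#' @param p_improve_bg Background monthly probability of improving from
#'   HbA1c >= 8 to HbA1c < 8.
#' @param p_relapse_bg Background monthly probability of relapsing from
#'   HbA1c < 8 to HbA1c >= 8.
#' @param boost Non-negative relative multiplier on the improvement
#'   probability when the patient was Engaged three months ago; the boosted
#'   rate is `min(1, (1 + boost) * p_improve_bg)`.
#' @param q_obs_maint Probability that a patient in Maintenance produces an
#'   HbA1c measurement in a month.
#'
#' @return An object of class `patient_params`.
#' @examples
#' p <- patient_params(0.75, 0.99, 0.03, 0.10, 0.075, 0.005, 0.5, 0.3)
#' engagement_transition("Maintenance", "Intervention", p)
#' @export
patient_params <- function(p_I_MtoE, p_I_EtoE, p_I_MtoD, p_U_MtoD,
                           p_improve_bg, p_relapse_bg, boost, q_obs_maint) {
  p <- list(
    p_I_MtoE = p_I_MtoE, p_I_EtoE = p_I_EtoE,
    p_I_MtoD = p_I_MtoD, p_U_MtoD = p_U_MtoD,
    p_improve_bg = p_improve_bg, p_relapse_bg = p_relapse_bg,
    boost = boost, q_obs_maint = q_obs_maint
  )
  validate_patient_params(p)
  structure(p, class = "patient_params")
}

validate_patient_params <- function(p) {
  probs <- unlist(p[c(
    "p_I_MtoE", "p_I_EtoE", "p_I_MtoD", "p_U_MtoD",
    "p_improve_bg", "p_relapse_bg", "q_obs_maint"
  )])
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probability parameters must lie in [0, 1]")
  }
  if (!is.finite(p$boost) || p$boost < 0) stop("boost must be a non-negative number")
  if (p$p_I_EtoE < p$p_I_MtoE) {
    stop("p_I_EtoE must be >= p_I_MtoE (response is easier from Engaged)")
  }
  if (p$p_I_MtoD > p$p_U_MtoD) {
    stop("p_I_MtoD must be <= p_U_MtoD (intervention protects against dropout)")
  }
  invisible(p)
}

#' @export
print.patient_params <- function(x, ...) {
  cat("<patient_params>\n")
  for (nm in PARAM_NAMES) cat(sprintf("  %-13s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Fully observed patient state
#'
#' A patient occupies a 3-tuple: engagement state, clinical state, and a
#' 2-length memory of past engagement states (`m0` = last month, `m1` = two
#' months ago).
#'
#' @param s_E Engagement state (`"Engaged"`, `"Maintenance"`, `"Dropout"`).
#' @param s_C Clinical state (`"A1cGe8"`, `"A1cLt8"`).
#' @param s_M Length-2 character vector of engagement states, `c(m0, m1)`.
#' @return Object of class `patient_state`.
#' @export
patient_state <- function(s_E, s_C, s_M) {
  if (length(s_M) != 2L) stop("s_M must have exactly two entries")
  structure(
    list(s_E = ENGAGEMENT_LEVELS[eng_code(s_E)],
         s_C = CLINICAL_LEVELS[clin_code(s_C)],
         s_M = ENGAGEMENT_LEVELS[eng_code(s_M)]),
    class = "patient_state"
  )
}

#' @export
print.patient_state <- function(x, ...) {
  cat(sprintf("<patient_state> (%s, %s, [%s, %s])\n", x$s_E, x$s_C, x$s_M[1], x$s_M[2]))
  invisible(x)
}

#' Belief-augmented patient state
#'
#' Engagement and memory are fully observable; the clinical state is replaced
#' by the planner's belief that the patient currently has HbA1c < 8, together
#' with a counter of months since the clinical state was last observed.
#'
#' @param s_E,s_M As in [patient_state()].
#' @param clinical_belief Probability in `[0, 1]` that the clinical state is
#'   `A1cLt8`. Must be exactly 0 or 1 when `months_unobserved` is 0.
#' @param months_unobserved Non-negative integer count of months since the
#'   last HbA1c observation.
#' @return Object of class `belief_patient_state`.
#' @export
belief_patient_state <- function(s_E, s_M, clinical_belief, months_unobserved = 0L) {
  if (length(s_M) != 2L) stop("s_M must have exactly two entries")
  if (!is.finite(clinical_belief) || clinical_belief < 0 || clinical_belief > 1) {
    stop("clinical_belief must lie in [0, 1]")
  }
  months_unobserved <- as.integer(months_unobserved)
  if (is.na(months_unobserved) || months_unobserved < 0L) {
    stop("months_unobserved must be a non-negative integer")
  }
  if (months_unobserved == 0L && !(clinical_belief %in% c(0, 1))) {
    stop("clinical_belief must be 0 or 1 when months_unobserved is 0")
  }
  structure(
    list(s_E = ENGAGEMENT_LEVELS[eng_code(s_E)],
         s_M = ENGAGEMENT_LEVELS[eng_code(s_M)],
         clinical_belief = as.numeric(clinical_belief),
         months_unobserved = months_unobserved),
    class = "belief_patient_state"
  )
}

#' @export
print.belief_patient_state <- function(x, ...) {
  cat(sprintf(
    "<belief_patient_state> (%s, [%s, %s]) P(A1c<8)=%.4f, unobserved %d mo\n",
    x$s_E, x$s_M[1], x$s_M[2], x$clinical_belief, x$months_unobserved
  ))
  invisible(x)
}

#' Enumerate the 54 joint patient states
#'
#' States are ordered lexicographically by (s_E, s_C, m0, m1) with
#' Engaged < Maintenance < Dropout and A1cGe8 < A1cLt8. This ordering is the
#' indexing convention used by [build_transition_kernel()] and is fixed for
#' serialization.
#'
#' @return A data.frame with columns `index`, `s_E`, `s_C`, `m0`, `m1`,
#'   `label`.
#' @export
enumerate_states <- function() {
  grid <- expand.grid(
    m1 = 1:3, m0 = 1:3, s_C = 1:2, s_E = 1:3,
    KEEP.OUT.ATTRS = FALSE
  )[, c("s_E", "s_C", "m0", "m1")]
  data.frame(
    index = seq_len(nrow(grid)),
    s_E = ENGAGEMENT_LEVELS[grid$s_E],
    s_C = CLINICAL_LEVELS[grid$s_C],
    m0 = ENGAGEMENT_LEVELS[grid$m0],
    m1 = ENGAGEMENT_LEVELS[grid$m1],
    label = paste0(
      substr(ENGAGEMENT_LEVELS[grid$s_E], 1, 1), ".",
      c("Ge8", "Lt8")[grid$s_C], ".",
      substr(ENGAGEMENT_LEVELS[grid$m0], 1, 1),
      substr(ENGAGEMENT_LEVELS[grid$m1], 1, 1)
    ),
    stringsAsFactors = FALSE
  )
}

#' Map a patient state to its index (and back)
#'
#' @param s_E,s_C,m0,m1 State components, as names or integer codes;
#'   vectorized.
#' @return `state_index()` returns integer indices in 1..54; `index_state()`
#'   returns the corresponding rows of [enumerate_states()].
#' @export
state_index <- function(s_E, s_C, m0, m1) {
  e <- eng_code(s_E); cc <- clin_code(s_C); a <- eng_code(m0); b <- eng_code(m1)
  (e - 1L) * 18L + (cc - 1L) * 9L + (a - 1L) * 3L + (b - 1L) + 1L
}

#' @rdname state_index
#' @param index Integer indices in 1..54.
#' @export
index_state <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 1L | index > 54L)) stop("index must be in 1..54")
  enumerate_states()[index, , drop = FALSE]
}

#' One-month engagement transition distribution
#'
#' Under an intervention a patient first risks dropout (`p_I_MtoD`), then
#' responds (moving to Engaged) with probability `p_I_EtoE` from Engaged or
#' `p_I_MtoE` from Maintenance, otherwise falls to Maintenance. Under
#' self-care the patient drops out with probability `p_U_MtoD` and otherwise
#' moves to Maintenance: Engaged status requires responding to an
#' intervention, so self-care can never yield Engaged. Dropout is absorbing.
#'
#' @param s_E Current engagement state.
#' @param action `"SelfCare"` or `"Intervention"`.
#' @param params A [patient_params()] object.
#' @return Named numeric vector of probabilities over
#'   (Engaged, Maintenance, Dropout), summing to 1.
#' @export
engagement_transition <- function(s_E, action, params) {
  validate_patient_params(params)
  e <- eng_code(s_E)
  a <- action_code(action)
  out <- c(Engaged = 0, Maintenance = 0, Dropout = 0)
  if (e == 3L) {
    out["Dropout"] <- 1
  } else if (a == 2L) {
    respond <- if (e == 1L) params$p_I_EtoE else params$p_I_MtoE
    out["Dropout"] <- params$p_I_MtoD
    out["Engaged"] <- (1 - params$p_I_MtoD) * respond
    out["Maintenance"] <- (1 - params$p_I_MtoD) * (1 - respond)
  } else {
    out["Dropout"] <- params$p_U_MtoD
    out["Maintenance"] <- 1 - params$p_U_MtoD
  }
  out
}

#' One-month clinical improvement/retention probability
#'
#' Returns the probability that the next clinical state is HbA1c < 8, given
#' the current clinical state and the engagement state three months ago (the
#' last entry `m1` of the memory vector). From HbA1c >= 8 the improvement
#' probability is the background rate, multiplied by `1 + boost` (capped at
#' 1) when `m1` is Engaged. From HbA1c < 8 the patient retains the healthy
#' state with probability `1 - p_relapse_bg` regardless of past engagement.
#'
#' @param s_C Current clinical state.
#' @param m1 Engagement state three months ago.
#' @inheritParams engagement_transition
#' @return Probability that the next clinical state is `A1cLt8`.
#' @export
clinical_transition_prob <- function(s_C, m1, params) {
  validate_patient_params(params)
  cc <- clin_code(s_C)
  m <- eng_code(m1)
  if (cc == 2L) {
    1 - params$p_relapse_bg
  } else if (m == 1L) {
    min(1, (1 + params$boost) * params$p_improve_bg)
  } else {
    params$p_improve_bg
  }
}

#' Deterministic memory shift
#'
#' The memory vector is a sliding window over past engagement: the new `m0`
#' is the current engagement state and the new `m1` is the old `m0`.
#'
#' @param s_E Current engagement state.
#' @param s_M Length-2 memory vector.
#' @return The next memory vector (character, length 2).
#' @export
memory_transition <- function(s_E, s_M) {
  if (length(s_M) != 2L) stop("s_M must have exactly two entries")
  c(ENGAGEMENT_LEVELS[eng_code(s_E)], ENGAGEMENT_LEVELS[eng_code(s_M[1])])
}

#' Build the 54-state action-conditioned transition kernel
#'
#' The joint kernel is the product of the engagement, clinical and memory
#' factor transitions. The clinical factor conditions on the pre-transition
#' `m1` (the engagement state two months before the new month), which
#' together with the one-month step realizes the three-month delayed
#' intervention effect.
#'
#' @inheritParams engagement_transition
#' @return An object of class `transition_kernel`: a list with 54 x 54
#'   row-stochastic matrices `SelfCare` and `Intervention` (rows and columns
#'   in [enumerate_states()] order) and the generating `params`.
#' @export
build_transition_kernel <- function(params) {
  validate_patient_params(params)
  states <- enumerate_states()
  n <- nrow(states)
  e <- eng_code(states$s_E); cc <- clin_code(states$s_C)
  m0 <- eng_code(states$m0); m1 <- eng_code(states$m1)
  kern <- list()
  for (a in 1:2) {
    P <- matrix(0, n, n, dimnames = list(states$label, states$label))
    for (i in seq_len(n)) {
      pe <- engagement_transition(e[i], a, params)
      pL <- clinical_transition_prob(cc[i], m1[i], params)
      if (!is.finite(pL) || pL < 0 || pL > 1) {
        stop("clinical transition probability outside [0, 1]")
      }
      nm0 <- e[i]; nm1 <- m0[i]
      for (ne in 1:3) {
        if (pe[ne] == 0) next
        for (ncc in 1:2) {
          pc <- if (ncc == 2L) pL else 1 - pL
          if (pc == 0) next
          j <- (ne - 1L) * 18L + (ncc - 1L) * 9L + (nm0 - 1L) * 3L + (nm1 - 1L) + 1L
          P[i, j] <- P[i, j] + pe[ne] * pc
        }
      }
    }
    kern[[ACTION_LEVELS[a]]] <- P
  }
  structure(c(kern, list(params = params)), class = "transition_kernel")
}

#' @export
print.transition_kernel <- function(x, ...) {
  cat("<transition_kernel> 54 states x {SelfCare, Intervention}\n")
  invisible(x)
}

#' State reward
#'
#' The reward of a state is `alpha * r_E + (1 - alpha) * r_C`, where
#' `r_E = 1` unless the patient has dropped out, and `r_C = 1` if
#' HbA1c < 8 (for belief states, `r_C` is the clinical belief).
#'
#' @param state A [patient_state()] or [belief_patient_state()].
#' @param alpha Engagement weight in `[0, 1]`.
#' @return A reward in `[0, 1]`.
#' @export
state_reward <- function(state, alpha) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  r_E <- as.numeric(state$s_E != "Dropout")
  r_C <- if (inherits(state, "belief_patient_state")) {
    state$clinical_belief
  } else {
    as.numeric(state$s_C == "A1cLt8")
  }
  alpha * r_E + (1 - alpha) * r_C
}

#' Advance a belief state by one observed month
#'
#' Propagates the clinical belief one month forward through
#' [clinical_transition_prob()] (using the pre-transition `m1`), shifts the
#' memory window, and installs the realized next engagement state. If an
#' HbA1c observation is supplied the belief collapses to 0 or 1 and the
#' unobserved-month counter resets; otherwise the counter increments (capped
#' at `horizon`).
#'
#' @param belief A [belief_patient_state()].
#' @param action The action taken this month (`"SelfCare"` or
#'   `"Intervention"`); the engagement realization already reflects it, so
#'   the argument is validated but does not alter the update.
#' @param params A [patient_params()] object.
#' @param observed_engagement The realized next engagement state.
#' @param clinical_observation Optional observed next clinical state; only
#'   permitted when the next engagement state is not Dropout.
#' @param horizon Cap for `months_unobserved`.
#' @return The next [belief_patient_state()].
#' @export
belief_propagate <- function(belief, action, params, observed_engagement,
                             clinical_observation = NULL, horizon = 18L) {
  if (!inherits(belief, "belief_patient_state")) stop("belief must be a belief_patient_state")
  validate_patient_params(params)
  action_code(action)
  ne <- eng_code(observed_engagement)
  if (!is.null(clinical_observation) && ne == 3L) {
    stop("clinical state is unobservable for a patient in Dropout")
  }
  m1 <- eng_code(belief$s_M[2])
  p_imp <- if (m1 == 1L) min(1, (1 + params$boost) * params$p_improve_bg) else params$p_improve_bg
  b <- belief$clinical_belief
  b_next <- b * (1 - params$p_relapse_bg) + (1 - b) * p_imp
  new_m <- memory_transition(belief$s_E, belief$s_M)
  if (!is.null(clinical_observation)) {
    b_next <- as.numeric(clin_code(clinical_observation) == 2L)
    k <- 0L
  } else {
    k <- min(belief$months_unobserved + 1L, as.integer(horizon))
  }
  belief_patient_state(ENGAGEMENT_LEVELS[ne], new_m, b_next, k)
}
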