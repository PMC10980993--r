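# Independent oracles used across the suite: a pure-R recursive belief-MDP
# solver, a brute-force budget-constrained planner for tiny instances, and
# fixture constructors. These deliberately share no code with the package's
# C++ planning core.

mk_params <- function(p_I_MtoE = 0.75, p_I_EtoE = 0.99, p_I_MtoD = 0.03,
                      p_U_MtoD = 0.10, p_improve_bg = 0.075, p_relapse_bg = 0.005,
                      boost = 0.5, q_obs_maint = 0.3) {
  patient_params(p_I_MtoE, p_I_EtoE, p_I_MtoD, p_U_MtoD,
                 p_improve_bg, p_relapse_bg, boost, q_obs_maint)
}

random_params <- function() {
  mtoe <- runif(1, 0.1, 0.9)
  mtod <- runif(1, 0, 0.3)
  mk_params(
    p_I_MtoE = mtoe, p_I_EtoE = runif(1, mtoe, 1),
    p_I_MtoD = mtod, p_U_MtoD = runif(1, mtod, 0.5),
    p_improve_bg = runif(1, 0, 0.3), p_relapse_bg = runif(1, 0, 0.2),
    boost = runif(1, 0, 2), q_obs_maint = runif(1, 0, 1)
  )
}

# a cohort in which every group shares identical parameters (used to compare
# the simulator against single-chain closed forms)
uniform_group_table <- function(p_U_MtoD = 0.10, p_improve_bg = 0.075,
                                p_relapse_bg = 0.005, boost = 0) {
  tab <- canonical_group_table()
  tab$p_I_MtoE <- 0.75
  tab$p_U_MtoD <- p_U_MtoD
  tab$p_I_MtoD <- min(0.03, p_U_MtoD)
  tab$p_improve_bg <- p_improve_bg
  tab$p_relapse_bg <- p_relapse_bg
  tab$boost <- boost
  tab
}

# Pure-R finite-horizon solver over the belief MDP. `forced` pins the policy
# to one action (1 = self-care) for passive-value oracles.
r_arm_value <- function(params, e, m0, m1, b, TT, alpha, lambda, forced = NULL) {
  memo <- new.env(parent = emptyenv())
  pimp_of <- function(m1) {
    if (m1 == 1) min(1, (1 + params$boost) * params$p_improve_bg) else params$p_improve_bg
  }
  eng <- function(e, a) {
    if (e == 3) return(c(0, 0, 1))
    if (a == 2) {
      r <- if (e == 1) params$p_I_EtoE else params$p_I_MtoE
      d <- params$p_I_MtoD
      c((1 - d) * r, (1 - d) * (1 - r), d)
    } else {
      c(0, 1 - params$p_U_MtoD, params$p_U_MtoD)
    }
  }
  rec <- function(e, m0, m1, b, d) {
    if (d == 0) return(0)
    key <- paste(e, m0, m1, sprintf("%.12f", b), d)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    bp <- b * (1 - params$p_relapse_bg) + (1 - b) * pimp_of(m1)
    qv <- c(NA_real_, NA_real_)
    for (a in 1:2) {
      v <- if (a == 2) -lambda else 0
      pe <- eng(e, a)
      for (ne in 1:3) {
        if (pe[ne] == 0) next
        q <- c(1, params$q_obs_maint, 0)[ne]
        kids <- list()
        if (q > 0) {
          kids <- c(kids, list(list(p = pe[ne] * q * bp, b = 1),
                               list(p = pe[ne] * q * (1 - bp), b = 0)))
        }
        if (q < 1) kids <- c(kids, list(list(p = pe[ne] * (1 - q), b = bp)))
        for (kid in kids) {
          if (kid$p == 0) next
          r <- alpha * (ne != 3) + (1 - alpha) * kid$b
          v <- v + kid$p * (r + rec(ne, e, m0, kid$b, d - 1))
        }
      }
      qv[a] <- v
    }
    out <- if (is.null(forced)) max(qv) else qv[forced]
    memo[[key]] <- out
    out
  }
  rec(e, m0, m1, b, TT)
}

# Exact optimum over all history-dependent policies for a tiny group of arms
# under a hard per-round budget. Exponential; keep arms <= 2 and TT <= 4.
brute_constrained_value <- function(plist, states, b_g, TT, alpha) {
  n <- length(plist)
  memo <- new.env(parent = emptyenv())
  arm_children <- function(p, st, a) {
    if (st$e == 3) {
      pe <- c(0, 0, 1)
    } else if (a == 2) {
      r <- if (st$e == 1) p$p_I_EtoE else p$p_I_MtoE
      d <- p$p_I_MtoD
      pe <- c((1 - d) * r, (1 - d) * (1 - r), d)
    } else {
      pe <- c(0, 1 - p$p_U_MtoD, p$p_U_MtoD)
    }
    pimp <- if (st$m1 == 1) min(1, (1 + p$boost) * p$p_improve_bg) else p$p_improve_bg
    bp <- st$b * (1 - p$p_relapse_bg) + (1 - st$b) * pimp
    out <- list()
    for (ne in 1:3) {
      if (pe[ne] == 0) next
      q <- c(1, p$q_obs_maint, 0)[ne]
      add <- function(pr, bb) {
        if (pr > 0) out[[length(out) + 1]] <<- list(
          p = pr, st = list(e = ne, m0 = st$e, m1 = st$m0, b = bb),
          r = alpha * (ne != 3) + (1 - alpha) * bb)
      }
      if (q > 0) { add(pe[ne] * q * bp, 1); add(pe[ne] * q * (1 - bp), 0) }
      if (q < 1) add(pe[ne] * (1 - q), bp)
    }
    out
  }
  subsets <- Filter(function(s) length(s) <= b_g,
                    unlist(lapply(0:n, function(k) combn(n, k, simplify = FALSE)),
                           recursive = FALSE))
  rec <- function(sts, d) {
    if (d == 0) return(0)
    key <- paste(vapply(sts, function(s) paste(s$e, s$m0, s$m1, sprintf("%.12f", s$b)),
                        ""), d, collapse = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    for (S in subsets) {
      kids <- lapply(seq_len(n), function(i) {
        arm_children(plist[[i]], sts[[i]], if (i %in% S) 2 else 1)
      })
      expand <- function(i, pr, acc_r, acc_st) {
        if (pr == 0) return(0)
        if (i > n) return(pr * (acc_r + rec(acc_st, d - 1)))
        tot <- 0
        for (k in kids[[i]]) {
          tot <- tot + expand(i + 1, pr * k$p, acc_r + k$r, c(acc_st, list(k$st)))
        }
        tot
      }
      best <- max(best, expand(1, 1, 0, list()))
    }
    memo[[key]] <- best
    best
  }
  rec(states, TT)
}
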