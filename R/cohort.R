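# Cohort generation: the six demographic groups with their published summary
# statistics, the counterexample variant with an "unmovable" group, per-patient
# parameter jitter, and the staggered enrollment schedule.

GROUP_SIZES <- c(0.175, 0.15, 0.2, 0.15, 0.125, 0.2)

#' Canonical six-group parameter table
#'
#' Six demographic groups (age bands 30-44 / 45-54 / 55-64 crossed with
#' man / woman) with mean transition parameters taken from published
#' claims-derived statistics: background monthly improvement and relapse
#' rates of 7.5% and 0.5% with about one percentage point of spread across
#' groups, monthly self-care dropout near 10% with about four points of
#' spread, an engagement boost of 25% / 50% / 75% by age band, response
#' probabilities of 99% (from Engaged) and mean 75% (from Maintenance, with
#' the same group offsets as dropout), a 3% dropout rate under intervention,
#' and a 30% monthly chance of observing the HbA1c of a Maintenance patient.
#' Group offsets are symmetric and evenly spaced so that group means average
#' to the published values.
#'
#' @return A `group_table` data.frame with one row per group: `group_id`
#'   (0-5), `label`, `relative_size`, and the [patient_params()] fields.
#' @export
canonical_group_table <- function() {
  ages <- rep(c("30-44", "45-54", "55-64"), each = 2)
  genders <- rep(c("man", "woman"), 3)
  off_clin <- seq(-0.005, 0.005, length.out = 6)
  off_drop <- seq(-0.02, 0.02, length.out = 6)
  tab <- data.frame(
    group_id = 0:5,
    label = paste(ages, genders, sep = "/"),
    relative_size = GROUP_SIZES,
    p_I_MtoE = 0.75 + off_drop,
    p_I_EtoE = 0.99,
    p_I_MtoD = 0.03,
    p_U_MtoD = 0.10 + off_drop,
    p_improve_bg = 0.075 + off_clin,
    p_relapse_bg = 0.005,
    boost = rep(c(0.25, 0.50, 0.75), each = 2),
    q_obs_maint = 0.30,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("group_table", "data.frame")
  validate_group_table(tab)
  tab
}

#' Counterexample parameter table with one unmovable group
#'
#' Identical to [canonical_group_table()] except that interventions are made
#' barely effective for group 0: its engagement boost drops to 0.01 and its
#' response probabilities from Engaged and Maintenance both drop to 0.02, so
#' intervening changes its clinical trajectory by a negligible amount. This
#' domain exercises the known failure mode of maximin allocation, which can
#' sink the whole budget into a group whose outcomes cannot be moved.
#'
#' @return A `group_table` data.frame, as [canonical_group_table()].
#' @export
counterexample_group_table <- function() {
  tab <- canonical_group_table()
  tab$boost[1] <- 0.01
  tab$p_I_MtoE[1] <- 0.02
  tab$p_I_EtoE[1] <- 0.02
  validate_group_table(tab)
  tab
}

validate_group_table <- function(tab) {
  stopifnot(is.data.frame(tab), nrow(tab) >= 1)
  if (!isTRUE(all.equal(sum(tab$relative_size), 1))) stop("relative sizes must sum to 1")
  for (i in seq_len(nrow(tab))) group_params(tab, i - 1L)
  invisible(tab)
}

#' Extract one group's mean parameters
#'
#' @param groups A `group_table` data.frame.
#' @param group_id Group identifier (0-based, matching the table).
#' @return A [patient_params()] object.
#' @export
group_params <- function(groups, group_id) {
  row <- groups[groups$group_id == group_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown group_id: ", group_id)
  patient_params(
    row$p_I_MtoE, row$p_I_EtoE, row$p_I_MtoD, row$p_U_MtoD,
    row$p_improve_bg, row$p_relapse_bg, row$boost, row$q_obs_maint
  )
}

largest_remainder <- function(weights, total) {
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)  # ties resolve to lowest index
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Sample a cohort of patients with jittered parameters
#'
#' Group counts follow the relative sizes via largest-remainder rounding.
#' Each probability parameter is drawn independently from a normal
#' distribution centred on the group mean with standard deviation `sigma`,
#' then clipped to `[0, 1]`; the boost multiplier is kept at the group value.
#' After clipping, the response and dropout orderings are restored pairwise
#' (`p_I_EtoE >= p_I_MtoE`, `p_I_MtoD <= p_U_MtoD`) so every sampled patient
#' is a valid parameter set.
#'
#' @param groups A `group_table` data.frame.
#' @param N Number of patients (at least the number of groups).
#' @param sigma Jitter standard deviation (0.05 in the study conditions).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param entry_months Optional integer vector of entry months (length `N`).
#'   By default a staggered [enrollment_schedule()] derived from `seed`.
#' @return A `cohort` data.frame with columns `patient_id`, `group_id`,
#'   `entry_month` and the parameter columns; the seed is kept as an
#'   attribute.
#' @export
sample_cohort <- function(groups, N, sigma = 0.05, seed = 1L, entry_months = NULL) {
  if (N < nrow(groups)) stop("N must be at least the number of groups")
  if (sigma < 0) stop("sigma must be non-negative")
  counts <- largest_remainder(groups$relative_size, N)
  gid <- rep(groups$group_id, counts)
  jittered <- c("p_I_MtoE", "p_I_EtoE", "p_I_MtoD", "p_U_MtoD",
                "p_improve_bg", "p_relapse_bg", "q_obs_maint")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  cols <- list()
  for (nm in jittered) {
    mu <- rep(groups[[nm]], counts)
    cols[[nm]] <- pmin(1, pmax(0, rnorm(N, mean = mu, sd = sigma)))
  }
  cols$boost <- rep(groups$boost, counts)
  # restore the parameter orderings that define a valid patient
  cols$p_I_EtoE <- pmax(cols$p_I_EtoE, cols$p_I_MtoE)
  cols$p_I_MtoD <- pmin(cols$p_I_MtoD, cols$p_U_MtoD)
  if (is.null(entry_months)) {
    entry_months <- enrollment_schedule(N, seed = as.integer(seed) + 1L)
  }
  stopifnot(length(entry_months) == N)
  out <- data.frame(
    patient_id = seq_len(N), group_id = gid, entry_month = as.integer(entry_months),
    cols[PARAM_NAMES], stringsAsFactors = FALSE
  )
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("cohort", "data.frame")
  out
}

#' Staggered enrollment schedule
#'
#' Randomly partitions `N` patients into five equal waves entering in months
#' 1 through 5 (largest-remainder wave sizes when `N` is not divisible by 5).
#'
#' @param N Number of patients.
#' @param seed Integer seed.
#' @return Integer vector of entry months in `{1, ..., 5}`, length `N`.
#' @export
enrollment_schedule <- function(N, seed = 1L) {
  sizes <- largest_remainder(rep(1, 5), N)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  months <- rep(1:5, sizes)
  sample(months, N, replace = FALSE)
}

#' Write / read a cohort as CSV
#'
#' Numeric columns are serialized with 17 significant digits so that a
#' write/read round-trip reproduces the cohort exactly.
#'
#' @param cohort A `cohort` data.frame.
#' @param path File path.
#' @return `read_cohort()` returns the `cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  for (nm in c(PARAM_NAMES)) out[[nm]] <- as.numeric(out[[nm]])
  out$patient_id <- as.integer(out$patient_id)
  out$group_id <- as.integer(out$group_id)
  out$entry_month <- as.integer(out$entry_month)
  class(out) <- c("cohort", "data.frame")
  out
}
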