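# Experiment orchestration: named presets reproducing the study's result
# suites, a validating config reader, and a resumable runner with a manifest.

#' Named experiment presets
#'
#' Presets expand to a full experiment specification: a list of simulation
#' configurations, the policies to compare, and the seed set.
#'
#' * `"fig4"` — policy comparison at budget `B = N/10` for cohorts of 150,
#'   300 and 600 patients.
#' * `"fig5"` — per-group outcome comparison at `N = 300`, `B = 30`.
#' * `"pareto"` — reward-weight sweep at `N = 300`, `B = 30`,
#'   `alpha` in 0, 0.25, 0.5, 0.75, 1.
#' * `"capacity"` — budget sweep over 0, 15, 30, 45, 60, 75, 100, 150 at
#'   `N = 300`.
#'
#' @param name Preset name.
#' @param domain Simulation domain passed to every configuration.
#' @param n_seeds Number of seeds (default 50, the study conditions).
#' @return An `experiment_spec` list with fields `name`, `configs`,
#'   `policies`, `seeds`.
#' @export
experiment_preset <- function(name = c("fig4", "fig5", "pareto", "capacity"),
                              domain = "marketscan", n_seeds = 50L) {
  name <- match.arg(name)
  all_pol <- policy_registry()
  spec <- switch(
    name,
    fig4 = list(
      configs = lapply(c(150L, 300L, 600L), function(n) {
        simulation_config(N = n, B = n %/% 10L, alpha = 0, domain = domain)
      }),
      policies = all_pol
    ),
    fig5 = list(
      configs = list(simulation_config(N = 300L, B = 30L, alpha = 0, domain = domain)),
      policies = all_pol
    ),
    pareto = list(
      configs = lapply(c(0, 0.25, 0.5, 0.75, 1), function(a) {
        simulation_config(N = 300L, B = 30L, alpha = a, domain = domain)
      }),
      policies = setdiff(all_pol, "no_action")
    ),
    capacity = list(
      configs = lapply(c(0L, 15L, 30L, 45L, 60L, 75L, 100L, 150L), function(b) {
        simulation_config(N = 300L, B = b, alpha = 0, domain = domain)
      }),
      policies = setdiff(all_pol, "no_action")
    )
  )
  structure(c(list(name = name, seeds = seq_len(n_seeds)), spec),
            class = "experiment_spec")
}

#' Read an experiment specification from a YAML file
#'
#' The file either names a preset (`preset: fig4`, with optional `domain`
#' and `n_seeds`) or spells out `configs` (a list of simulation-config
#' fields), `policies` and `seeds`.
#'
#' @param path YAML file path.
#' @return An `experiment_spec`.
#' @export
read_experiment_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$preset)) {
    return(experiment_preset(raw$preset,
                             domain = raw$domain %||% "marketscan",
                             n_seeds = raw$n_seeds %||% 50L))
  }
  configs <- lapply(raw$configs, function(cc) {
    # YAML 1.1 resolves a bare `N` key to boolean FALSE; map it back
    names(cc)[names(cc) %in% c("FALSE", "n")] <- "N"
    do.call(simulation_config, cc)
  })
  structure(list(name = raw$name %||% "custom", configs = configs,
                 policies = raw$policies, seeds = raw$seeds %||% seq_len(raw$n_seeds %||% 50L)),
            class = "experiment_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an experiment specification
#'
#' Checks field ranges and policy names and emits divisibility warnings
#' without running any simulation.
#'
#' @param spec An `experiment_spec`, or a path to a YAML spec file.
#' @return A data.frame of problems (columns `level`, `where`, `message`);
#'   zero rows when the spec is clean.
#' @export
validate_config <- function(spec) {
  if (is.character(spec)) spec <- read_experiment_spec(spec)
  problems <- list()
  note <- function(level, where, message) {
    problems[[length(problems) + 1L]] <<- data.frame(
      level = level, where = where, message = message, stringsAsFactors = FALSE)
  }
  if (!length(spec$configs)) note("error", "configs", "no configurations")
  for (i in seq_along(spec$configs)) {
    cfg <- spec$configs[[i]]
    where <- sprintf("configs[%d]", i)
    if (!is.finite(cfg$alpha) || cfg$alpha < 0 || cfg$alpha > 1) {
      note("error", where, "alpha outside [0,1]")
    }
    if (cfg$H < 17L) {
      note("warning", where,
           sprintf("H = %d cannot cover 12-month outcomes for the last enrollment wave (needs H >= 17)", cfg$H))
    }
    if (cfg$N %% 5L != 0L) note("warning", where, "N not divisible by the 5 enrollment waves")
    if (cfg$N %% 6L != 0L) note("warning", where, "N not divisible by the 6 groups; counts use largest remainder")
    if (cfg$B > cfg$N) note("warning", where, "budget exceeds cohort size")
  }
  bad <- setdiff(spec$policies, policy_registry())
  if (length(bad)) {
    note("error", "policies", paste0("unknown policy: ", paste(bad, collapse = ", "),
                                     " (known: ", paste(policy_registry(), collapse = ", "), ")"))
  }
  if (anyDuplicated(spec$seeds)) note("error", "seeds", "duplicate seeds")
  if (length(problems)) do.call(rbind, problems) else
    data.frame(level = character(0), where = character(0), message = character(0))
}

cell_id <- function(cfg, policy, seed) {
  sprintf("%s_N%d_H%d_B%d_a%g_s%g_%s_seed%d",
          cfg$domain, cfg$N, cfg$H, cfg$B, cfg$alpha, cfg$sigma, policy, seed)
}

#' Run an experiment suite
#'
#' Executes every (configuration x policy x seed) cell, appending one
#' twelve-month summary row per cell to `results.csv` in the output
#' directory. Completed cells are recorded in `manifest.csv` and skipped on
#' rerun, so an interrupted experiment resumes where it stopped. A
#' `metadata.json` captures the expanded specification and package version.
#'
#' @param spec An `experiment_spec` (see [experiment_preset()]), or a path
#'   to a YAML spec file.
#' @param out_dir Output directory.
#' @param quiet Suppress per-cell progress messages.
#' @return Tibble of all result rows (including previously completed ones).
#' @export
run_experiment <- function(spec, out_dir, quiet = FALSE) {
  if (is.character(spec)) spec <- read_experiment_spec(spec)
  probs <- validate_config(spec)
  if (any(probs$level == "error")) {
    stop("invalid experiment spec:\n", paste(probs$message[probs$level == "error"], collapse = "\n"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  results_path <- file.path(out_dir, "results.csv")
  done <- if (file.exists(manifest_path)) read.csv(manifest_path)$cell else character(0)

  jsonlite::write_json(
    list(name = spec$name, policies = spec$policies, seeds = spec$seeds,
         configs = lapply(spec$configs, unclass),
         package_version = as.character(utils::packageVersion("ermab"))),
    file.path(out_dir, "metadata.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  for (cfg in spec$configs) {
    for (policy in spec$policies) {
      for (seed in spec$seeds) {
        id <- cell_id(cfg, policy, seed)
        if (id %in% done) next
        t0 <- Sys.time()
        row <- seed_summary(cfg, policy, seed)
        elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
        out <- data.frame(
          cell = id, domain = cfg$domain, N = cfg$N, H = cfg$H, B = cfg$B,
          alpha = cfg$alpha, sigma = cfg$sigma, policy = policy, seed = seed,
          healthy_count = row$healthy_count, engaged_count = row$engaged_count,
          dropout_count = row$dropout_count, gini = row$gini,
          mad_healthy = row$mad_healthy, mad_engaged = row$mad_engaged,
          stringsAsFactors = FALSE
        )
        write.table(out, results_path, sep = ",", row.names = FALSE,
                    col.names = !file.exists(results_path), append = file.exists(results_path))
        write.table(data.frame(cell = id), manifest_path, sep = ",", row.names = FALSE,
                    col.names = !file.exists(manifest_path), append = file.exists(manifest_path))
        done <- c(done, id)
        if (!quiet) message(sprintf("[%s] %.1fs", id, elapsed))
      }
    }
  }
  tibble::as_tibble(read.csv(results_path, stringsAsFactors = FALSE))
}
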