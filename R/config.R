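# Configuration handling. All tunables live in one packaged YAML file;
# parse_config() merges (defaults <- file <- overrides), rejects unknown
# keys, and validates every invariant before anything runs.

default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "kapsim",
              mustWork = TRUE)
}

#' Parse and validate a run configuration
#'
#' Builds the full run configuration by layering, in increasing
#' precedence: packaged defaults, an optional user YAML/JSON file, and an
#' optional list of explicit overrides. Unknown keys are rejected by name;
#' the merged result is validated against all type invariants (rates
#' non-negative, `z > 0`, the national threshold positive, process/decision
#' consistency, eligibility parameters in `[0, 100]`).
#'
#' The process presets bind the decision model: process I uses maximum-score
#' selection (`sdm0`) on a static list, process II the shared
#' decision-making model (`sdm1`) on a static list, and process III `sdm1`
#' with the dynamic waiting list.
#'
#' @param path optional path to a YAML or JSON config file.
#' @param overrides optional named list, merged last (highest precedence);
#'   nested values use nested lists, e.g.
#'   `list(dynamics = list(lambda_in = 1))`.
#' @return a validated `kap_config` list.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  cfg <- yaml::read_yaml(default_config_path())
  if (!is.null(path)) {
    kap_assert(file.exists(path), "config file not found: %s", path,
               class = "kap_io_error")
    user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                             simplifyVector = TRUE)
            else yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, "config")
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides, "overrides")
  validate_config(cfg)
}

# Recursive merge; unknown keys in `new` are errors. The k_in/k_out
# schedules and coefficient table are replaced wholesale, not merged.
merge_config <- function(base, new, where) {
  if (is.null(new)) return(base)
  kap_assert(is.list(new) && (length(new) == 0 || !is.null(names(new))),
             "%s: expected a named mapping", where,
             class = "kap_validation_error")
  for (key in names(new)) {
    kap_assert(key %in% names(base), "%s: unknown key '%s'", where, key,
               class = "kap_validation_error")
    replace_whole <- key %in% c("k_in", "k_out", "coefficients")
    if (is.list(base[[key]]) && !is.null(names(base[[key]])) &&
        !replace_whole) {
      base[[key]] <- merge_config(base[[key]], new[[key]],
                                  paste0(where, "$", key))
    } else {
      base[[key]] <- new[[key]]
    }
  }
  base
}

#' @rdname parse_config
#' @param cfg a configuration list to validate.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, field, constraint) {
    kap_assert(isTRUE(ok), "config field '%s' violates: %s", field,
               constraint, class = "kap_validation_error")
  }
  chk(cfg$process %in% c("I", "II", "III"), "process", "one of I, II, III")
  # process binds the decision model and dynamics
  cfg$decision_model <- if (cfg$process == "I") "sdm0" else "sdm1"
  cfg$dynamics$enabled <- cfg$process == "III"
  chk(cfg$donor_sample_size >= 1, "donor_sample_size", ">= 1")
  chk(cfg$dynamics$n0 >= 0, "dynamics$n0", ">= 0")
  chk(cfg$dynamics$lambda_in >= 0, "dynamics$lambda_in", ">= 0")
  chk(cfg$dynamics$lambda_out >= 0, "dynamics$lambda_out", ">= 0")
  chk(cfg$dynamics$reentry_prob >= 0 && cfg$dynamics$reentry_prob <= 1,
      "dynamics$reentry_prob", "in [0, 1]")
  for (sched in c("k_in", "k_out")) {
    for (seg in cfg$dynamics[[sched]]) {
      chk(!is.null(seg$year) && !is.null(seg$multiplier) &&
            seg$multiplier >= 0,
          paste0("dynamics$", sched), "entries need year and multiplier >= 0")
    }
  }
  chk(cfg$scoring$national_threshold > 0, "scoring$national_threshold", "> 0")
  chk(cfg$scoring$level_base > 0, "scoring$level_base", "> 0")
  chk(cfg$eligibility$mode %in% c("default", "corisk", "irisk"),
      "eligibility$mode", "one of default, corisk, irisk")
  if (cfg$eligibility$mode == "corisk") {
    chk(cfg$eligibility$c >= 0 && cfg$eligibility$c <= 100,
        "eligibility$c", "in [0, 100]")
  }
  if (cfg$eligibility$mode == "irisk") {
    chk(cfg$eligibility$s >= 0 && cfg$eligibility$s <= 100,
        "eligibility$s", "in [0, 100]")
  }
  chk(cfg$acceptance$z > 0, "acceptance$z", "> 0")
  chk(cfg$acceptance$alpha2_scale %in% c("percentile", "raw"),
      "acceptance$alpha2_scale", "percentile or raw")
  chk(cfg$waiting_time_from %in% c("listing", "dialysis"),
      "waiting_time_from", "listing or dialysis")
  chk(cfg$replications >= 1, "replications", ">= 1")
  chk(cfg$workers >= 1, "workers", ">= 1")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed",
      "a single integer")
  needed <- c("age", "sex_m", "lung_disease", "smoking", "diabetes",
              "cardiovascular_disease", "cancer", "pra", "blood_group_o",
              "state_metro", "years_on_dialysis")
  miss <- setdiff(needed, names(cfg$exit_scorer$coefficients))
  kap_assert(length(miss) == 0,
             "config field 'exit_scorer$coefficients' missing: %s",
             paste(miss, collapse = ", "), class = "kap_config_error")
  structure(cfg, class = "kap_config")
}

# Piecewise-constant yearly multiplier lookup; 1 outside any segment.
rate_multiplier <- function(schedule, day) {
  if (length(schedule) == 0) return(1)
  yr <- as.integer(format(as.Date(day), "%Y"))
  for (seg in schedule) {
    if (yr == as.integer(seg$year)) return(as.numeric(seg$multiplier))
  }
  1
}
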