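#' Read a stratified rate table from delimited text
#'
#' Comma-delimited with a header, UTF-8, `.` decimal; one row per
#' (sex, year, age group).  Columns `sex`, `year`, `age_lo`, `age_hi`
#' (empty for an open-ended top group), `value`, and optional `population`.
#' Parse or validation failures report the offending data row.
#'
#' @param path File to read.
#' @param quantity Which quantity the table holds (see [rate_table()]).
#' @return A validated rate table.
#' @export
read_rate_table <- function(path, quantity) {
  if (!file.exists(path)) stop_domain(sprintf("File not found: %s", path))
  raw <- tryCatch(
    # parse problems surface through readr::problems() below, not warnings
    suppressWarnings(
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(
                        sex = readr::col_character(),
                        .default = readr::col_double()
                      ))
    ),
    error = function(e) {
      stop_domain(sprintf("Cannot parse %s: %s", path, conditionMessage(e)))
    }
  )
  if (nrow(raw) == 0) stop_domain(sprintf("%s is empty.", path))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop_domain(sprintf("Parse error in %s, row %d: expected %s, got %s.",
                        path, probs$row[1], probs$expected[1],
                        probs$actual[1]))
  }
  rate_table(raw, quantity)
}

#' Write a rate table to delimited text
#'
#' Inverse of [read_rate_table()] up to column order and float formatting.
#'
#' @param table A rate table.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(table, path) {
  cols <- intersect(c("sex", "year", "age_lo", "age_hi", "value",
                      "population"), names(table))
  readr::write_csv(tibble::as_tibble(table)[cols], path)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the four rate tables and the population table in the same
#' delimited format [read_rate_table()] reads, plus the ground-truth answer
#' key (`answers.json`, never read by the analysis pipeline).
#'
#' @param dataset A `synthetic_claims` object from [simulate_claims()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "synthetic_claims")) {
    stop_domain("`dataset` must come from simulate_claims().")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("prevalence", "incidence", "mortality", "rate_ratio")) {
    write_rate_table(dataset[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  readr::write_csv(dataset$population, file.path(dir, "population.csv"))
  scn <- dataset$truth$scenario
  answers <- list(
    se = scn$se,
    fpr_profile = lapply(scn$fpr_profile, as.list),
    incidence = scn$incidence,
    mortality = scn$mortality,
    rate_ratio = scn$rate_ratio,
    incidence_drift = scn$incidence_drift,
    noise = scn$noise,
    seed = scn$seed
  )
  jsonlite::write_json(answers, file.path(dir, "answers.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the arguments of [analysis_config()]; the table entries are
#' file paths resolved relative to the YAML file's directory.
#'
#' @param path YAML file.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("Config not found: %s", path))
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.character(p) && !file.exists(p)) file.path(base, p) else p
  }
  for (nm in c("prevalence", "incidence", "mortality", "rate_ratio",
               "population")) {
    if (is.null(y[[nm]])) stop_domain(sprintf("Config key `%s` is required.", nm))
    y[[nm]] <- resolve(y[[nm]])
    if (is.character(y[[nm]]) && !file.exists(y[[nm]])) {
      stop_domain(sprintf("Config `%s` points to a missing file: %s",
                          nm, y[[nm]]))
    }
  }
  for (nm in c("se_range", "grid_ages", "count_ages")) {
    if (!is.null(y[[nm]])) y[[nm]] <- as.numeric(unlist(y[[nm]]))
  }
  do.call(analysis_config, y)
}

#' Write the Monte-Carlo FPR matrix to delimited text
#'
#' Long format: one row per (sex, age, scenario) with the assumed
#' sensitivity, the estimated specificity/FPR, and the clipping flag.
#'
#' @param fpr The `fpr` tibble of an [run_full_analysis()] result.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_fpr_matrix <- function(fpr, path) {
  readr::write_csv(fpr, path)
  invisible(path)
}

#' Write the count summary as JSON
#'
#' One object per group (men/women/total) with median and 95% bounds in
#' thousands.
#'
#' @param summary The `summary` tibble of an [run_full_analysis()] result.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_fp_summary <- function(summary, path) {
  out <- lapply(seq_len(nrow(summary)), function(k) {
    list(group = summary$group[k], median = summary$median[k],
         ci_low = summary$ci_low[k], ci_high = summary$ci_high[k],
         unit = summary$unit[k])
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the run manifest
#'
#' Written atomically (temp file + rename) at the end of a run; every
#' warning raised during the run appears in it.
#'
#' @param analysis An `fpr_analysis`.
#' @param path Destination JSON file.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(analysis, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(analysis$manifest, tmp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

# ---- command-line interface -------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: fpclaims <command> [--flag value ...]",
    "",
    "commands:",
    "  simulate      write a synthetic claims dataset  (--out DIR [--seed N] [--noise none|binomial])",
    "  fit           fit the four rate surfaces        (--config FILE --out DIR)",
    "  estimate-fpr  Monte-Carlo FPR matrix            (--config FILE --out DIR [--n N] [--seed N])",
    "  counts        count summary JSON                (--config FILE --out DIR [--n N] [--seed N])",
    "  run-all       full pipeline + manifest          (--config FILE --out DIR [--n N] [--seed N])",
    sep = "\n"
  )
}

parse_cli_flags <- function(args) {
  flags <- list()
  k <- 1
  while (k <= length(args)) {
    if (!startsWith(args[k], "--")) {
      stop_domain(sprintf("Unexpected argument `%s` (flags are --name value).",
                          args[k]))
    }
    if (k == length(args)) stop_domain(sprintf("Flag %s needs a value.", args[k]))
    flags[[substring(args[k], 3)]] <- args[k + 1]
    k <- k + 2
  }
  flags
}

cli_load_config <- function(flags) {
  if (is.null(flags$config)) stop_domain("--config FILE is required.")
  config <- read_analysis_config(flags$config)
  if (!is.null(flags$n)) config$n_scenarios <- as.integer(flags$n)
  if (!is.null(flags$seed)) config$seed <- as.integer(flags$seed)
  config
}

#' Command-line entry point
#'
#' Dispatcher behind the `inst/cli/fpclaims` script.  Commands: `simulate`,
#' `fit`, `estimate-fpr`, `counts`, `run-all`.  Flags are `--name value`
#' pairs; `--config` names a YAML file (see [read_analysis_config()]) whose
#' values `--n` and `--seed` override.  Configuration problems are reported
#' before any computation starts.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly: 0 on success, 1 on error.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  command <- args[1]
  status <- tryCatch({
    flags <- parse_cli_flags(args[-1])
    out <- flags$out
    if (is.null(out)) stop_domain("--out is required.")
    switch(command,
      "simulate" = {
        scn <- default_scenario(
          seed = as.integer(flags$seed %||% 1L),
          noise = flags$noise %||% "none"
        )
        write_synthetic_dataset(simulate_claims(scn), out)
        message("wrote synthetic dataset to ", out)
      },
      "fit" = {
        config <- cli_load_config(flags)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        fits <- list(
          prevalence = fit_prevalence(config$prevalence,
                                      config$prevalence_df,
                                      config$open_group_offset,
                                      config$weighted),
          incidence = fit_incidence(config$incidence, config$incidence_df,
                                    config$open_group_offset,
                                    config$weighted),
          mortality = fit_mortality(config$mortality,
                                    open_group_offset = config$open_group_offset,
                                    weighted = config$weighted),
          rate_ratio = fit_rate_ratio(config$rate_ratio,
                                      config$rate_ratio_df,
                                      config$open_group_offset,
                                      config$weighted)
        )
        report <- lapply(fits, function(f) {
          list(model = f$basis, transform = f$transform,
               age_range = f$age_range,
               coefficients = as.list(coef(f$fit)))
        })
        jsonlite::write_json(report, file.path(out, "coefficients.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        message("wrote coefficient report to ", out)
      },
      "estimate-fpr" = {
        config <- cli_load_config(flags)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        analysis <- run_full_analysis(config)
        write_fpr_matrix(analysis$fpr, file.path(out, "fpr_matrix.csv"))
        message("wrote FPR matrix to ", out)
      },
      "counts" = {
        config <- cli_load_config(flags)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        analysis <- run_full_analysis(config)
        write_fp_summary(analysis$summary, file.path(out, "summary.json"))
        message("wrote count summary to ", out)
      },
      "run-all" = {
        config <- cli_load_config(flags)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        analysis <- run_full_analysis(config)
        write_fpr_matrix(analysis$fpr, file.path(out, "fpr_matrix.csv"))
        write_fp_summary(analysis$summary, file.path(out, "summary.json"))
        readr::write_csv(analysis$totals, file.path(out, "totals.csv"))
        write_run_manifest(analysis, file.path(out, "manifest.json"))
        message("wrote full results to ", out)
      },
      {
        cat(cli_usage(), "\n")
        stop_domain(sprintf("Unknown command `%s`.", command))
      }
    )
    0L
  }, error = function(e) {
    message(sprintf("fpclaims %s: error: %s", command, conditionMessage(e)))
    1L
  })
  invisible(status)
}
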