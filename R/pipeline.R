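#' Assemble a run configuration
#'
#' Bundles everything one study run needs: the generative model, the
#' genotype presets, the dose ladder, the stimulation times, the replicate
#' count, analysis options and the master seed. The same object drives
#' [run_robustness()], [run_capacity()] and [run_all()].
#'
#' @param synthetic a [synthetic_config()] (its `seed` is overridden by
#'   `seed` below so one master seed governs the whole run).
#' @param presets genotype preset names (see [genotype_presets()]).
#' @param doses dose ladder (ng/ml).
#' @param times subset of `c("early", "late")`.
#' @param n_replicates replicates per condition.
#' @param mi_options list: `min_events`, `floor`, `tol`.
#' @param cc_options list: `method` ("ba"/"classifier"), `grid_size`,
#'   `min_n`.
#' @param seed master seed recorded in every artifact.
#' @param output optional output directory for CSV/JSON reports (created
#'   if missing); `NULL` keeps everything in memory.
#' @return object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       presets = c("wt", "dEx3", "dEx3_SHP2"),
                       doses = DEFAULT_DOSES,
                       times = c("early", "late"),
                       n_replicates = 3L,
                       mi_options = list(),
                       cc_options = list(),
                       seed = 1L,
                       output = NULL) {
  synthetic$seed <- seed
  synthetic <- validate_synthetic_config(synthetic)
  known <- names(genotype_presets())
  bad <- setdiff(presets, known)
  if (length(bad)) {
    stop(
      "unknown preset(s): ", paste(bad, collapse = ", "),
      " (available: ", paste(known, collapse = ", "), ")",
      call. = FALSE
    )
  }
  mi_defaults <- list(min_events = 500L, floor = 1, tol = 1e-4)
  cc_defaults <- list(method = "ba", grid_size = 512L, min_n = 100L)
  mi_options <- utils::modifyList(mi_defaults, mi_options)
  cc_options <- utils::modifyList(cc_defaults, cc_options)
  structure(
    list(
      synthetic = synthetic, presets = presets, doses = as.numeric(doses),
      times = times, n_replicates = n_replicates,
      mi_options = mi_options, cc_options = cc_options,
      seed = seed, output = output
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML schema mirrors the [run_config()] arguments; `synthetic` keys
#' mirror [synthetic_config()] field names exactly.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, y$synthetic %||% list())
  run_config(
    synthetic = syn,
    presets = y$presets %||% c("wt", "dEx3", "dEx3_SHP2"),
    doses = unlist(y$doses %||% DEFAULT_DOSES),
    times = unlist(y$times %||% c("early", "late")),
    n_replicates = y$n_replicates %||% 3L,
    mi_options = y$mi_options %||% list(),
    cc_options = y$cc_options %||% list(),
    seed = y$seed %||% 1L,
    output = y$output
  )
}

ensure_output <- function(config) {
  if (is.null(config$output)) {
    return(NULL)
  }
  if (!dir.exists(config$output)) {
    dir.create(config$output, recursive = TRUE)
  }
  config$output
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

simulate_study <- function(config) {
  pipeline_log(
    "simulate", "%d preset(s) x %d dose(s) x %d time(s) x %d replicate(s)",
    length(config$presets), length(config$doses), length(config$times),
    config$n_replicates
  )
  generate_study(
    config$synthetic, config$presets, config$doses,
    config$times, config$n_replicates
  )
}

#' Robustness (mutual information) analysis of a study
#'
#' Simulates the configured study (or takes one), computes MI per
#' condition-replicate, screens the standardised MI values for normality,
#' runs the N-way ANOVA over genotype and dose (per stimulation time), and
#' the pairwise 1-way ANOVA + unbiased Cohen's d post-hoc scheme between
#' genotypes at each dose. Low MI is read as high robustness of STAT3
#' phosphorylation to the cell's STAT3 content.
#'
#' @param config a [run_config()].
#' @param study optional pre-generated study (list of event tables); by
#'   default the study is simulated from `config`.
#' @return list of class `robustness_report`: `mi` (per-condition table
#'   with robustness labels), `normality`, `anova` (per time), `posthoc`
#'   (pairwise genotype comparisons per time x dose), `seed`. If
#'   `config$output` is set, writes `mi_results.csv` and
#'   `robustness_report.json` there.
#' @export
run_robustness <- function(config, study = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(study)) study <- simulate_study(config)
  opts <- config$mi_options
  pipeline_log("mi", "estimating MI for %d condition(s)", length(study))
  mi <- mi_per_condition(study,
    min_events = opts$min_events,
    floor = opts$floor, tol = opts$tol
  )
  mi <- label_robustness(mi)

  norm <- tryCatch(
    {
      z <- center_scale(
        mi$mi_bits,
        interaction(mi$genotype, mi$dose_ng_ml, mi$time_min)
      )
      ks_normality(z)
    },
    error = function(e) list(statistic = NA_real_, p.value = NA_real_)
  )

  anova_by_time <- lapply(split(mi, mi$time_min), function(d) {
    if (length(unique(d$genotype)) < 2L || length(unique(d$dose_ng_ml)) < 2L) {
      return(NULL)
    }
    anova_nway(d$mi_bits, d[, c("genotype", "dose_ng_ml")])
  })
  anova_by_time <- anova_by_time[!vapply(anova_by_time, is.null, logical(1))]

  posthoc <- do.call(rbind, lapply(
    split(mi, interaction(mi$time_min, mi$dose_ng_ml, drop = TRUE)),
    function(d) {
      if (length(unique(d$genotype)) < 2L) {
        return(NULL)
      }
      cmp <- pairwise_comparisons(d$mi_bits, d$genotype)
      cbind(time_min = d$time_min[1L], dose_ng_ml = d$dose_ng_ml[1L], cmp)
    }
  ))
  rownames(posthoc) <- NULL

  report <- structure(
    list(
      mi = mi, normality = norm, anova = anova_by_time,
      posthoc = posthoc, seed = config$seed
    ),
    class = "robustness_report"
  )
  out <- ensure_output(config)
  if (!is.null(out)) {
    utils::write.csv(mi, file.path(out, "mi_results.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(
        seed = config$seed, normality = norm, anova = anova_by_time,
        posthoc = posthoc,
        interpretation = "low MI between STAT3 expression and pSTAT3 = high robustness"
      ),
      file.path(out, "robustness_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    pipeline_log("mi", "wrote %s", file.path(out, "mi_results.csv"))
  }
  report
}

#' Channel-capacity analysis of a study
#'
#' Capacity per (genotype, time, replicate) by the configured method,
#' followed by the N-way ANOVA over genotype and time and the pairwise
#' p-then-d scheme between genotypes (per time) and between times (per
#' genotype).
#'
#' @param config a [run_config()].
#' @param study optional pre-generated study.
#' @return list of class `capacity_report`: `cc` (per-replicate table,
#'   including `n_states = 2^cc_bits`), `anova`, `posthoc_genotype`,
#'   `posthoc_time`, `seed`. If `config$output` is set, writes
#'   `cc_results.csv` and `capacity_report.json`.
#' @export
run_capacity <- function(config, study = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(study)) study <- simulate_study(config)
  opts <- config$cc_options
  pipeline_log("capacity", "method = %s", opts$method)
  cc <- cc_per_condition(study,
    time = NULL, method = opts$method,
    grid_size = opts$grid_size, min_n = opts$min_n
  )

  anova_tab <- if (length(unique(cc$genotype)) >= 2L &&
    length(unique(cc$time_min)) >= 2L) {
    anova_nway(cc$cc_bits, cc[, c("genotype", "time_min")])
  } else {
    NULL
  }

  posthoc_genotype <- do.call(rbind, lapply(split(cc, cc$time_min), function(d) {
    if (length(unique(d$genotype)) < 2L) {
      return(NULL)
    }
    cbind(time_min = d$time_min[1L], pairwise_comparisons(d$cc_bits, d$genotype))
  }))
  rownames(posthoc_genotype) <- NULL

  posthoc_time <- do.call(rbind, lapply(split(cc, cc$genotype), function(d) {
    if (length(unique(d$time_min)) < 2L) {
      return(NULL)
    }
    cbind(genotype = d$genotype[1L], pairwise_comparisons(d$cc_bits, d$time_min))
  }))
  rownames(posthoc_time) <- NULL

  report <- structure(
    list(
      cc = cc, anova = anova_tab, posthoc_genotype = posthoc_genotype,
      posthoc_time = posthoc_time, seed = config$seed
    ),
    class = "capacity_report"
  )
  out <- ensure_output(config)
  if (!is.null(out)) {
    utils::write.csv(cc, file.path(out, "cc_results.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(
        seed = config$seed, anova = anova_tab,
        posthoc_genotype = posthoc_genotype, posthoc_time = posthoc_time
      ),
      file.path(out, "capacity_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    pipeline_log("capacity", "wrote %s", file.path(out, "cc_results.csv"))
  }
  report
}

#' Run the full pipeline: simulate, robustness, capacity, manifest
#'
#' Executes every stage under one master seed; rerunning with the same
#' configuration reproduces all numeric outputs bit-identically. When
#' `config$output` is set, per-condition CSVs, both reports and a JSON
#' manifest (seed, parameters, file hashes) are written there.
#'
#' @param config a [run_config()].
#' @return list of class `siginfo_run`: `robustness`, `capacity`,
#'   `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  study <- simulate_study(config)
  out <- ensure_output(config)
  files <- character(0)
  if (!is.null(out)) {
    sim_dir <- file.path(out, "simulated")
    if (!dir.exists(sim_dir)) dir.create(sim_dir, recursive = TRUE)
    for (key in names(study)) {
      f <- file.path(sim_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", key), ".csv"))
      write_event_table(study[[key]], f)
      files <- c(files, f)
    }
  }
  robustness <- run_robustness(config, study = study)
  capacity <- run_capacity(config, study = study)

  manifest <- list(
    package = "siginfo",
    version = as.character(utils::packageVersion("siginfo")),
    seed = config$seed,
    synthetic = unclass(config$synthetic),
    presets = config$presets,
    doses = config$doses,
    times = config$times,
    n_replicates = config$n_replicates,
    mi_options = config$mi_options,
    cc_options = config$cc_options,
    n_conditions = length(study)
  )
  if (!is.null(out)) {
    files <- c(
      files,
      file.path(out, c(
        "mi_results.csv", "robustness_report.json",
        "cc_results.csv", "capacity_report.json"
      ))
    )
    files <- files[file.exists(files)]
    manifest$file_md5 <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    pipeline_log("manifest", "wrote %s", file.path(out, "manifest.json"))
  }
  structure(
    list(robustness = robustness, capacity = capacity, manifest = manifest),
    class = "siginfo_run"
  )
}
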