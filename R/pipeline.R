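## End-to-end orchestration: inputs (read or synthesized), measurement,
## diagnosis, cohort tables, group comparison, report files and run log.

#' Pipeline configuration
#'
#' Collects the inputs and options of [run_pipeline()].  When a path is
#' `NULL` the corresponding input is synthesized from `synth_config` /
#' `roster_spec` under `seed`, so the full pipeline runs with no
#' external data.
#'
#' @param out_dir Output directory (created if missing).
#' @param landmarks_path,features_path,groups_path Optional input CSVs
#'   (formats as in [read_landmarks()], [read_condyle_features()],
#'   [read_groups()]).
#' @param alpha Significance level in (0, 1) used for routing and letter
#'   displays.
#' @param rotation_deg X-axis rotation in degrees.
#' @param seed Integer seed governing all synthesis.
#' @param synth_config Synthetic cohort configuration
#'   ([synthetic_config()]).
#' @param roster_spec Condylar roster specification
#'   ([tmjoa_roster_spec()]).
#' @return A list of class `tmj_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            landmarks_path = NULL,
                            features_path = NULL,
                            groups_path = NULL,
                            alpha = 0.05,
                            rotation_deg = 7,
                            seed = 1L,
                            synth_config = synthetic_config(
                              rotation_deg = rotation_deg),
                            roster_spec = tmjoa_roster_spec()) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  for (p in c(landmarks_path, features_path, groups_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, landmarks_path = landmarks_path,
                 features_path = features_path, groups_path = groups_path,
                 alpha = alpha, rotation_deg = rotation_deg,
                 seed = as.integer(seed), synth_config = synth_config,
                 roster_spec = roster_spec),
            class = "tmj_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys: `out_dir`, `landmarks`, `features`, `groups`,
#' `alpha`, `rotation_deg`, `seed`.  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `tmj_pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("out_dir", "landmarks", "features", "groups", "alpha",
             "rotation_deg", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(y$out_dir)) stop("configuration must set out_dir", call. = FALSE)
  pipeline_config(out_dir = y$out_dir,
                  landmarks_path = y$landmarks,
                  features_path = y$features,
                  groups_path = y$groups,
                  alpha = y$alpha %||% 0.05,
                  rotation_deg = y$rotation_deg %||% 7,
                  seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Measurement of all landmark sets, condylar classification with
#' worst-side patient aggregation, cohort tabulation, and the
#' three-group comparison of every cephalometric variable; writes
#' `landmarks.csv` (when synthesized), `measurements.csv`,
#' `diagnoses.csv`, `patient_table.csv`, `feature_table.csv`,
#' `comparison.csv` (formatted report), `comparison_tests.csv` (raw
#' statistics) and `run_log.txt` into the output directory.  Reruns
#' with the same configuration and seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results
#'   (`measurements`, `diagnoses`, `cohort_summary`, `comparison`) and
#'   the written `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tmj_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log <- c(sprintf("cephtmj %s", as.character(utils::packageVersion("cephtmj"))),
           sprintf("seed: %d", config$seed),
           sprintf("alpha: %g", config$alpha),
           sprintf("rotation: %g deg inferior to SN", config$rotation_deg))

  # --- landmarks and group labels -----------------------------------
  if (is.null(config$landmarks_path)) {
    cohort <- generate_cohort(config$synth_config, seed = config$seed)
    landmarks <- cohort$landmarks
    groups <- cohort$groups
    log <- c(log, sprintf("landmarks: synthesized (%d subjects, %d redraws)",
                          nrow(groups), attr(cohort, "rejected")))
    paths$landmarks <- file.path(config$out_dir, "landmarks.csv")
    write_landmarks(landmarks, paths$landmarks)
  } else {
    landmarks <- read_landmarks(config$landmarks_path)
    if (is.null(config$groups_path)) {
      stop("groups_path is required when landmarks are read from file",
           call. = FALSE)
    }
    groups <- read_groups(config$groups_path)
    log <- c(log, sprintf("landmarks: %s", config$landmarks_path))
  }

  measurements <- ceph_measure(landmarks, rotation_deg = config$rotation_deg)
  missing_grp <- setdiff(measurements$subject_id, groups$subject_id)
  if (length(missing_grp)) {
    stop("missing group label for subject(s): ",
         paste(head(missing_grp, 5), collapse = ", "), call. = FALSE)
  }
  measurements <- dplyr::inner_join(groups, measurements, by = "subject_id")
  paths$measurements <- file.path(config$out_dir, "measurements.csv")
  write_measurements(measurements, paths$measurements)

  # --- condylar classification --------------------------------------
  if (is.null(config$features_path)) {
    features <- generate_condylar_roster(config$roster_spec,
                                         seed = config$seed)
    log <- c(log, sprintf("condylar features: synthesized (%d condyles)",
                          nrow(features)))
  } else {
    features <- read_condyle_features(config$features_path)
    log <- c(log, sprintf("condylar features: %s", config$features_path))
  }
  diagnoses <- aggregate_patients(classify_condyles(features))
  paths$diagnoses <- file.path(config$out_dir, "diagnoses.csv")
  readr::write_csv(diagnoses, paths$diagnoses)

  summary <- summarize_cohort(diagnoses, features)
  paths$patient_table <- file.path(config$out_dir, "patient_table.csv")
  readr::write_csv(summary$patients, paths$patient_table)
  feat <- summary$features
  feat$pct <- round(feat$pct, 1)  # report rounding: 1 decimal
  paths$feature_table <- file.path(config$out_dir, "feature_table.csv")
  readr::write_csv(feat, paths$feature_table)

  # --- group comparison ---------------------------------------------
  comparison <- compare_groups(measurements, group,
                               variables = CEPH_VARIABLES,
                               alpha = config$alpha)
  for (i in seq_len(nrow(comparison$tests))) {
    log <- c(log, sprintf("post-hoc route %s: %s (Levene p = %.4f)",
                          comparison$tests$variable[i],
                          comparison$tests$method[i],
                          comparison$tests$homogeneity_p[i]))
  }
  paths$comparison <- file.path(config$out_dir, "comparison.csv")
  readr::write_csv(comparison_report(comparison), paths$comparison)
  paths$comparison_tests <- file.path(config$out_dir, "comparison_tests.csv")
  readr::write_csv(glance(comparison), paths$comparison_tests)

  paths$log <- file.path(config$out_dir, "run_log.txt")
  writeLines(log, paths$log)
  invisible(list(measurements = measurements, diagnoses = diagnoses,
                 cohort_summary = summary, comparison = comparison,
                 paths = paths))
}
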