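## Rule-based condylar osseous diagnosis and patient-level aggregation.
##
## A condyle is osteoarthrotic when it shows frank degeneration
## (subcortical cyst, surface erosion, osteophyte, generalized sclerosis)
## or a short condyle; it is indeterminate for osteoarthrosis when it
## shows only remodeling signs (subcortical sclerosis, articular surface
## flattening, condylar hypoplasia); otherwise it is normal.  Mixed-tier
## records take the more severe tier.

validate_feature_tbl <- function(features) {
  need <- c("subject_id", "side", TMJ_FEATURES)
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    stop("feature table is missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(features$side %in% c("left", "right"))) {
    stop("side must be 'left' or 'right'", call. = FALSE)
  }
  dup <- duplicated(features[, c("subject_id", "side")])
  if (any(dup)) {
    d <- features[dup, ]
    stop(sprintf("duplicate condyle record: subject %s, %s side",
                 d$subject_id[1], d$side[1]), call. = FALSE)
  }
  for (f in TMJ_FEATURES) {
    v <- features[[f]]
    if (!all(v %in% c(0, 1, TRUE, FALSE))) {
      stop(sprintf("feature column '%s' must be 0/1 or logical", f),
           call. = FALSE)
    }
  }
  invisible(features)
}

classify_one <- function(flags) {
  flags <- as.logical(flags[TMJ_FEATURES])
  names(flags) <- TMJ_FEATURES
  oa <- TMJ_OA_TIER[flags[TMJ_OA_TIER]]
  ind <- TMJ_IND_TIER[flags[TMJ_IND_TIER]]
  if (length(oa)) {
    list(category = "osteoarthrosis", triggering = oa)
  } else if (length(ind)) {
    list(category = "indeterminate", triggering = ind)
  } else {
    list(category = "normal", triggering = character(0))
  }
}

#' Classify condylar osseous status
#'
#' Applies the three-tier osseous diagnosis to each per-condyle feature
#' record.  Any osteoarthrosis-tier flag (subcortical cyst, erosion,
#' osteophyte, generalized sclerosis, short condyle) yields
#' `osteoarthrosis`; otherwise any remodeling flag (subcortical
#' sclerosis, surface flattening, hypoplasia) yields `indeterminate`;
#' otherwise `normal`.
#'
#' @param features A data frame with columns `subject_id`, `side`
#'   ("left"/"right") and one 0/1 (or logical) column per feature flag:
#'   `r paste0("`", TMJ_FEATURES, "`", collapse = ", ")`.
#' @return The input tibble with added columns `category` (ordered
#'   factor normal < indeterminate < osteoarthrosis) and
#'   `triggering_features` (list-column of the true flags in the winning
#'   tier).
#' @export
classify_condyles <- function(features) {
  validate_feature_tbl(features)
  res <- purrr::map(seq_len(nrow(features)), function(i) {
    classify_one(unlist(features[i, TMJ_FEATURES]))
  })
  out <- tibble::as_tibble(features)
  out$category <- tmj_category_factor(purrr::map_chr(res, "category"))
  out$triggering_features <- purrr::map(res, "triggering")
  out
}

#' Aggregate condylar diagnoses to the patient level
#'
#' The patient-level diagnosis is the more severe of the two condylar
#' diagnoses (worst-side rule).  Laterality refers to the patient
#' category: `bilateral` when both condyles carry it, `unilateral`
#' otherwise.
#'
#' @param diagnoses Output of [classify_condyles()] (or any data frame
#'   with `subject_id`, `side`, `category`); every subject must have
#'   exactly one left and one right record.
#' @return A tibble with columns `subject_id`, `left_category`,
#'   `right_category`, `patient_category` and `laterality`.
#' @export
aggregate_patients <- function(diagnoses) {
  need <- c("subject_id", "side", "category")
  if (!all(need %in% names(diagnoses))) {
    stop("diagnoses must have columns subject_id, side, category",
         call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(diagnoses), dplyr::all_of(need)),
    names_from = "side", values_from = "category")
  for (s in c("left", "right")) {
    if (!s %in% names(wide) || anyNA(wide[[s]])) {
      bad <- if (!s %in% names(wide)) wide$subject_id else
        wide$subject_id[is.na(wide[[s]])]
      stop(sprintf("missing %s-condyle diagnosis for subject(s) %s", s,
                   paste(head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  left <- tmj_category_factor(wide$left)
  right <- tmj_category_factor(wide$right)
  patient <- tmj_category_factor(
    TMJ_CATEGORIES[pmax(as.integer(left), as.integer(right))])
  tibble::tibble(
    subject_id = wide$subject_id,
    left_category = left,
    right_category = right,
    patient_category = patient,
    laterality = ifelse(left == right, "bilateral", "unilateral"))
}

#' Tabulate a diagnosed cohort
#'
#' Produces the two cohort tables of the analysis: (a) patient counts by
#' diagnostic category and laterality, and (b) per-feature record
#' prevalences, where every true flag on every condyle contributes one
#' record and every flagless condyle contributes one "normal" record.
#'
#' @param patients Output of [aggregate_patients()].
#' @param features Per-condyle feature table (as for
#'   [classify_condyles()]).
#' @return A list of class `tmj_cohort_summary` with tibbles `patients`
#'   (category, unilateral, bilateral, total) and `features` (feature,
#'   n, pct), plus `n_patients` and `n_records`.
#' @export
summarize_cohort <- function(patients, features) {
  validate_feature_tbl(features)
  cat <- tmj_category_factor(patients$patient_category)
  lat <- factor(patients$laterality, levels = c("unilateral", "bilateral"))
  tab <- table(category = cat, laterality = lat)
  pat <- tibble::tibble(
    category = rownames(tab),
    unilateral = as.integer(tab[, "unilateral"]),
    bilateral = as.integer(tab[, "bilateral"]))
  pat$total <- pat$unilateral + pat$bilateral

  flag_mat <- sapply(TMJ_FEATURES, function(f) as.logical(features[[f]]))
  flag_mat <- matrix(flag_mat, ncol = length(TMJ_FEATURES),
                     dimnames = list(NULL, TMJ_FEATURES))
  n_normal <- sum(rowSums(flag_mat) == 0)
  counts <- c(normal = n_normal, colSums(flag_mat))
  # report order: normal, hypoplasia, flattening, sclerosis, cyst,
  # erosion, osteophyte, generalized sclerosis, short condyle
  order <- c("normal", "hypoplasia", "surface_flattening",
             "subcortical_sclerosis", "subcortical_cyst", "erosion",
             "osteophyte", "generalized_sclerosis", "short_condyle")
  counts <- counts[order]
  feat <- tibble::tibble(
    feature = names(counts),
    n = as.integer(counts),
    pct = 100 * as.integer(counts) / sum(counts))
  structure(list(patients = pat, features = feat,
                 n_patients = nrow(patients), n_records = sum(counts)),
            class = "tmj_cohort_summary")
}

#' @export
print.tmj_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (%d condylar feature records)\n\n",
              x$n_patients, x$n_records))
  cat("Patients by diagnostic category and laterality:\n")
  print(x$patients)
  cat("\nCondylar osseous feature prevalence:\n")
  feat <- x$features
  feat$pct <- round(feat$pct, 1)
  print(feat)
  invisible(x)
}
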