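## Method-error analysis for repeated digitizations.

#' Dahlberg method error
#'
#' Random (digitizing) error for paired repeated measurements:
#' `sqrt(sum(d^2) / (2 n))` with `d = first - second`.  Same units as
#' the measurement.
#'
#' @param first,second Numeric vectors of repeated measurements, paired
#'   by subject and in the same order.
#' @return The Dahlberg error (non-negative scalar).
#' @examples
#' dahlberg_error(c(1, 2, 3, 4), c(0, 3, 2, 5))  # sqrt(4/8)
#' @export
dahlberg_error <- function(first, second) {
  if (length(first) == 0L || length(first) != length(second)) {
    stop("first and second must be non-empty vectors of equal length",
         call. = FALSE)
  }
  d <- first - second
  if (anyNA(d)) stop("repeated measurements must not contain NA", call. = FALSE)
  sqrt(sum(d^2) / (2 * length(d)))
}

paired_t_stat <- function(first, second) {
  d <- first - second
  n <- length(d)
  if (n < 2L) stop("paired t test needs at least 2 pairs", call. = FALSE)
  if (sd(d) < 1e-12) {
    # zero-variance conventions: identical repeats show no systematic
    # error (p = 1); a constant nonzero shift is detected with certainty
    if (abs(mean(d)) < 1e-12) {
      return(list(statistic = 0, p_value = 1, df = n - 1))
    }
    return(list(statistic = sign(mean(d)) * Inf, p_value = 0, df = n - 1))
  }
  tt <- t.test(first, second, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Reliability report for repeated digitizations
#'
#' For each variable present in both tables, computes the Dahlberg
#' random error and a two-sided paired t test for systematic error
#' between the first and second digitization.
#'
#' @param first,second Data frames of repeated measurements with the
#'   same subjects in the same order (a `subject_id` column, if present,
#'   is used to check the pairing); remaining numeric columns are the
#'   variables.
#' @param variables Optional character vector restricting which columns
#'   are analyzed.
#' @return A tibble with columns `variable`, `n`, `dahlberg`,
#'   `t_statistic`, `df`, `p_value`.
#' @export
reliability_report <- function(first, second, variables = NULL) {
  first <- tibble::as_tibble(first)
  second <- tibble::as_tibble(second)
  if (nrow(first) != nrow(second)) {
    stop("first and second must have the same number of subjects",
         call. = FALSE)
  }
  if ("subject_id" %in% names(first) && "subject_id" %in% names(second) &&
      !identical(as.character(first$subject_id),
                 as.character(second$subject_id))) {
    stop("subject_id mismatch between the two digitizations", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- intersect(names(first), names(second))
    variables <- variables[vapply(first[variables], is.numeric, logical(1))]
    variables <- setdiff(variables, "subject_id")
  }
  if (!length(variables)) stop("no shared numeric variables", call. = FALSE)
  rows <- purrr::map(variables, function(v) {
    tt <- paired_t_stat(first[[v]], second[[v]])
    tibble::tibble(variable = v, n = nrow(first),
                   dahlberg = dahlberg_error(first[[v]], second[[v]]),
                   t_statistic = tt$statistic, df = tt$df,
                   p_value = tt$p_value)
  })
  dplyr::bind_rows(rows)
}
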