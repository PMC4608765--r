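## Three-group comparison of cephalometric variables with
## homogeneity-routed post-hoc tests and compact letter displays.

#' Compare cephalometric variables across diagnostic groups
#'
#' For each variable: one-way ANOVA; mean-centered Levene test of
#' variance homogeneity; pairwise post-hoc comparisons routed to Fisher
#' LSD when the Levene p-value exceeds `alpha` and to Dunnett T3
#' otherwise; and a compact letter display in which groups sharing a
#' letter are not significantly different pairwise (p > alpha).
#'
#' @param data A data frame holding the grouping column and the
#'   measurement columns (e.g. the output of [ceph_measure()] joined to
#'   group labels).
#' @param group The grouping column (tidy-eval, unquoted).
#' @param variables Character vector of variable columns to analyze;
#'   defaults to all numeric columns except the group.
#' @param alpha Significance level used both for routing and for the
#'   letter display (default 0.05).
#' @return An object of class `tmj_comparison`: a list with
#'   \describe{
#'     \item{summary}{tibble, one row per variable x group: n, mean, sd,
#'       letters.}
#'     \item{tests}{tibble, one row per variable: F, df, p, Levene p,
#'       post-hoc method.}
#'     \item{pairwise}{tibble, one row per variable x group pair:
#'       p-value and method.}
#'     \item{alpha, groups}{the level and group ordering used.}
#'   }
#'   `tidy()`, `glance()`, `autoplot()` and `comparison_report()`
#'   methods are available.
#' @examples
#' set.seed(1)
#' coh <- generate_cohort(synthetic_config(), seed = 1)
#' cmp <- compare_groups(coh$measurements, group)
#' glance(cmp)
#' @export
compare_groups <- function(data, group, variables = NULL, alpha = 0.05) {
  data <- tibble::as_tibble(data)
  gcol <- rlang::as_name(rlang::ensym(group))
  if (!gcol %in% names(data)) {
    stop(sprintf("grouping column '%s' not found", gcol), call. = FALSE)
  }
  g <- factor(data[[gcol]])
  if (all(levels(g) %in% TMJ_CATEGORIES)) {
    g <- factor(as.character(g), levels = intersect(TMJ_CATEGORIES, levels(g)))
  }
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
    variables <- setdiff(variables, gcol)
  }
  if (!length(variables)) stop("no variables to compare", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)

  summaries <- list(); tests <- list(); pairs <- list()
  for (v in variables) {
    x <- data[[v]]
    an <- one_way_anova(x, g)
    hom <- variance_homogeneity(x, g)
    method <- if (hom > alpha) "LSD" else "DunnettT3"
    pmat <- if (method == "LSD") lsd_pairwise(x, g) else
      dunnett_t3_pairwise(x, g)
    letters <- compact_letters(pmat, alpha)
    s <- group_stats(x, g)
    summaries[[v]] <- tibble::tibble(
      variable = v, group = s$levels, n = s$n, mean = s$mean,
      sd = sqrt(s$var), letters = unname(letters[s$levels]))
    tests[[v]] <- tibble::tibble(
      variable = v, statistic = an$statistic, df1 = an$df[1],
      df2 = an$df[2], p_value = an$p_value, homogeneity_p = hom,
      method = method)
    idx <- which(upper.tri(pmat), arr.ind = TRUE)
    pairs[[v]] <- tibble::tibble(
      variable = v,
      group1 = rownames(pmat)[idx[, 1]],
      group2 = colnames(pmat)[idx[, 2]],
      p_value = pmat[idx], method = method)
  }
  structure(list(summary = dplyr::bind_rows(summaries),
                 tests = dplyr::bind_rows(tests),
                 pairwise = dplyr::bind_rows(pairs),
                 alpha = alpha, groups = levels(g)),
            class = "tmj_comparison")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy pairwise comparisons
#'
#' One row per variable and group pair with the post-hoc p-value.
#'
#' @param x A `tmj_comparison` object.
#' @param ... Unused.
#' @export
tidy.tmj_comparison <- function(x, ...) x$pairwise

#' Per-variable test summaries
#'
#' One row per variable: ANOVA F and p, Levene homogeneity p, and the
#' post-hoc method routed to.
#'
#' @param x A `tmj_comparison` object.
#' @param ... Unused.
#' @export
glance.tmj_comparison <- function(x, ...) x$tests

#' @export
print.tmj_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %d variable(s) across %d groups (alpha = %g)\n\n",
              nrow(x$tests), length(x$groups), x$alpha))
  print(comparison_report(x))
  invisible(x)
}

#' Format a comparison as a publication-style table
#'
#' One row per variable; per-group columns show "mean+/-sd letters"
#' (groups sharing a letter are not significantly different at the
#' comparison's alpha), followed by the ANOVA F, p and the post-hoc
#' method used.
#'
#' @param x A `tmj_comparison` object.
#' @param digits Decimals for means/SDs and F (default 2).
#' @return A tibble of formatted strings.
#' @export
comparison_report <- function(x, digits = 2) {
  stopifnot(inherits(x, "tmj_comparison"))
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  wide <- x$summary
  wide$cell <- paste0(fmt(wide$mean), "±", fmt(wide$sd),
                      ifelse(wide$letters == "", "", paste0(" ", wide$letters)))
  wide <- tidyr::pivot_wider(wide[, c("variable", "group", "cell")],
                             names_from = "group", values_from = "cell")
  out <- dplyr::left_join(wide, x$tests, by = "variable")
  out$F <- fmt(out$statistic)
  out$p <- formatC(out$p_value, format = "g", digits = 3)
  dplyr::select(out, "variable", dplyr::all_of(x$groups), "F", "p", "method")
}

#' Plot group means with letter groupings
#'
#' Point-and-error-bar (mean +/- SD) panel per variable, annotated with
#' the compact letter display.
#'
#' @param object A `tmj_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.tmj_comparison <- function(object, ...) {
  s <- object$summary
  s$group <- factor(s$group, levels = object$groups)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean + .data$sd,
                                    label = .data$letters),
                       vjust = -0.6, size = 3) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± SD",
                  caption = sprintf(
                    "groups sharing a letter: pairwise p > %g", object$alpha)) +
    ggplot2::theme_bw()
}

#' @export
ggplot2::autoplot
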