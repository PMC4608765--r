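## One-way ANOVA, variance-homogeneity routing and pairwise post-hoc
## machinery (Fisher LSD under homogeneity, Dunnett T3 otherwise).

group_stats <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- tapply(x, g, length)
  if (any(n < 2L)) stop("every group needs n >= 2", call. = FALSE)
  if (!all(is.finite(x))) stop("values must be finite", call. = FALSE)
  list(g = g, levels = levels(g), n = as.numeric(n),
       mean = as.numeric(tapply(x, g, mean)),
       var = as.numeric(tapply(x, g, stats::var)),
       N = length(x), k = nlevels(g))
}

#' One-way analysis of variance
#'
#' Classical between/within F test with (k - 1, N - k) degrees of
#' freedom.  When every observation is identical the statistic is
#' defined as F = 0 with p = 1.
#'
#' @param x Numeric response vector.
#' @param g Group labels (coerced to factor).
#' @return A list with `statistic`, `p_value`, `df` (length 2),
#'   `ms_within`, and per-group `means` and `ns`.
#' @export
one_way_anova <- function(x, g) {
  s <- group_stats(x, g)
  ssw <- sum((s$n - 1) * s$var)
  grand <- mean(x)
  ssb <- sum(s$n * (s$mean - grand)^2)
  df <- c(s$k - 1, s$N - s$k)
  out <- list(df = df, ms_within = ssw / df[2],
              means = setNames(s$mean, s$levels),
              ns = setNames(s$n, s$levels))
  if (ssw < 1e-12 * max(1, abs(grand))^2) {
    if (ssb < 1e-12 * max(1, abs(grand))^2) {
      out$statistic <- 0; out$p_value <- 1
    } else {
      out$statistic <- Inf; out$p_value <- 0
    }
    return(out)
  }
  ft <- oneway.test(x ~ s$g, var.equal = TRUE)
  out$statistic <- unname(ft$statistic)
  out$p_value <- ft$p.value
  out
}

#' Variance homogeneity (mean-centered Levene test)
#'
#' Levene's test with mean centering: a one-way ANOVA on the absolute
#' deviations from the group means.  This is the routing criterion
#' between the LSD and Dunnett T3 post-hoc procedures.
#'
#' @inheritParams one_way_anova
#' @return The Levene p-value.
#' @export
variance_homogeneity <- function(x, g) {
  s <- group_stats(x, g)
  dev <- abs(x - ave(x, s$g))
  one_way_anova(dev, s$g)$p_value
}

#' Fisher LSD pairwise comparisons
#'
#' Unadjusted pairwise t tests using the pooled ANOVA mean square error
#' with N - k degrees of freedom.
#'
#' @inheritParams one_way_anova
#' @return A symmetric matrix of two-sided p-values with group names on
#'   both dimensions (diagonal NA).
#' @export
lsd_pairwise <- function(x, g) {
  s <- group_stats(x, g)
  an <- one_way_anova(x, g)
  mse <- an$ms_within
  df <- an$df[2]
  p <- matrix(NA_real_, s$k, s$k, dimnames = list(s$levels, s$levels))
  for (i in seq_len(s$k - 1)) {
    for (j in (i + 1):s$k) {
      se <- sqrt(mse * (1 / s$n[i] + 1 / s$n[j]))
      if (se < 1e-12) {
        pij <- if (abs(s$mean[i] - s$mean[j]) < 1e-12) 1 else 0
      } else {
        tij <- (s$mean[i] - s$mean[j]) / se
        pij <- 2 * pt(abs(tij), df, lower.tail = FALSE)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  p
}

#' Studentized maximum modulus distribution
#'
#' CDF of the studentized maximum modulus: the maximum of `m`
#' independent |N(0,1)| variables studentized by a common chi with `df`
#' degrees of freedom.  Used for Dunnett T3 adjusted p-values (with the
#' independent-contrast approximation and each pair's own
#' Welch-Satterthwaite df).  Computed by numerical integration over the
#' chi-square mixing density.
#'
#' @param q Quantile(s), non-negative.
#' @param m Number of contrasts.
#' @param df Degrees of freedom (recycled against `q`).
#' @return `P(SMM <= q)`, vectorized over `q` and `df`.
#' @export
psmm <- function(q, m, df) {
  mapply(function(qi, di) {
    if (!is.finite(qi)) return(if (qi > 0) 1 else 0)
    if (qi <= 0) return(0)
    integrate(function(u) (2 * pnorm(qi * sqrt(u / di)) - 1)^m * dchisq(u, di),
              lower = 0, upper = Inf, rel.tol = 1e-9)$value
  }, q, df)
}

#' Dunnett T3 pairwise comparisons
#'
#' Welch-type pairwise statistics (unpooled variances, Welch-
#' Satterthwaite degrees of freedom) referred to the studentized maximum
#' modulus distribution with m = k(k-1)/2 contrasts; appropriate when
#' group variances are unequal.
#'
#' @inheritParams one_way_anova
#' @return A symmetric matrix of adjusted two-sided p-values (diagonal
#'   NA).
#' @export
dunnett_t3_pairwise <- function(x, g) {
  s <- group_stats(x, g)
  m <- s$k * (s$k - 1) / 2
  p <- matrix(NA_real_, s$k, s$k, dimnames = list(s$levels, s$levels))
  for (i in seq_len(s$k - 1)) {
    for (j in (i + 1):s$k) {
      vi <- s$var[i] / s$n[i]
      vj <- s$var[j] / s$n[j]
      if (vi + vj < 1e-14) {
        pij <- if (abs(s$mean[i] - s$mean[j]) < 1e-12) 1 else 0
      } else {
        tij <- abs(s$mean[i] - s$mean[j]) / sqrt(vi + vj)
        df <- (vi + vj)^2 /
          (vi^2 / (s$n[i] - 1) + vj^2 / (s$n[j] - 1))
        pij <- 1 - psmm(tij, m, df)
      }
      p[i, j] <- p[j, i] <- min(1, max(0, pij))
    }
  }
  p
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: groups sharing a letter are not
#' significantly different pairwise at level `alpha`; every
#' non-significant pair shares at least one letter.  Deterministic:
#' pairs are processed in label order and letters assigned by first
#' group membership.
#'
#' @param pmat Symmetric matrix of pairwise p-values with group names.
#' @param alpha Significance level.
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  groups <- rownames(pmat)
  k <- length(groups)
  cols <- list(seq_len(k))  # start: one column holding all groups
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (is.na(pmat[i, j]) || pmat[i, j] > alpha) next
      new_cols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  cols <- cols[lengths(cols) > 0]
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  letters_out <- rep("", k)
  for (ci in seq_along(cols)) {
    letters_out[cols[[ci]]] <- paste0(letters_out[cols[[ci]]], letters[ci])
  }
  setNames(letters_out, groups)
}
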