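# ANOVA, Levene routing, LSD, Dunnett T3 / SMM, compact letters.

test_that("one-way ANOVA matches a from-scratch sum-of-squares oracle", {
  x <- c(1, 2, 3, 2, 3, 4, 10, 11, 12)
  g <- rep(c("a", "b", "c"), each = 3)
  an <- one_way_anova(x, g)
  # brute-force SS computation
  grand <- mean(x)
  ssb <- sum(tapply(x, g, length) * (tapply(x, g, mean) - grand)^2)
  ssw <- sum((x - ave(x, g))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(an$statistic, f_hand, tolerance = 1e-10)
  expect_equal(an$p_value, pf(f_hand, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(an$df, c(2, 6))
})

test_that("identical groups give F = 0, p = 1; separated groups reject", {
  x <- rep(5, 9); g <- rep(1:3, each = 3)
  an <- one_way_anova(x, g)
  expect_equal(an$statistic, 0)
  expect_equal(an$p_value, 1)
  set.seed(3)
  x2 <- c(rnorm(10, 0), rnorm(10, 10), rnorm(10, 20))
  expect_lt(one_way_anova(x2, rep(1:3, each = 10))$p_value, 1e-10)
})

test_that("for two groups ANOVA F equals the squared pooled t", {
  set.seed(14)
  x <- c(rnorm(8, 0, 1), rnorm(12, 1, 1))
  g <- rep(c("a", "b"), c(8, 12))
  an <- one_way_anova(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(an$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("mean-centered Levene test agrees with car and detects heteroscedasticity", {
  skip_if_not_installed("car")
  set.seed(15)
  x <- c(rnorm(20, 0, 1), rnorm(25, 0, 2), rnorm(30, 0, 1.5))
  g <- factor(rep(1:3, c(20, 25, 30)))
  p_mine <- variance_homogeneity(x, g)
  p_car <- car::leveneTest(x, g, center = mean)[1, "Pr(>F)"]
  expect_equal(p_mine, p_car, tolerance = 1e-10)
  # strong variance inequality is detected
  set.seed(16)
  hits <- 0L
  for (i in 1:20) {
    y <- c(rnorm(200, 0, 1), rnorm(200, 0, 3))
    if (variance_homogeneity(y, rep(1:2, each = 200)) < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  # group order permutation leaves the p-value unchanged
  perm <- sample(length(x))
  expect_equal(variance_homogeneity(x[perm], g[perm]), p_mine,
               tolerance = 1e-12)
})

test_that("LSD uses the pooled MSE and reduces to the pooled t at k = 2", {
  set.seed(17)
  x <- c(rnorm(9, 0), rnorm(11, 0.8))
  g <- rep(c("a", "b"), c(9, 11))
  p <- lsd_pairwise(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(p["a", "b"], tt$p.value, tolerance = 1e-12)
  # identical groups: all pairwise p = 1
  p1 <- lsd_pairwise(rep(2, 12), rep(1:3, each = 4))
  expect_true(all(p1[upper.tri(p1)] == 1))
  # widely separated means: all pairwise p tiny
  set.seed(18)
  x3 <- c(rnorm(10, 0, 1), rnorm(10, 10, 1), rnorm(10, 20, 1))
  p3 <- lsd_pairwise(x3, rep(1:3, each = 10))
  expect_true(all(p3[upper.tri(p3)] < 1e-6))
  expect_equal(p3, t(p3))
})

test_that("SMM distribution matches a Monte-Carlo oracle", {
  set.seed(19)
  m <- 3; df <- 24; R <- 1e5
  z <- matrix(abs(rnorm(R * m)), R)
  denom <- sqrt(rchisq(R, df) / df)
  mx <- apply(z, 1, max) / denom
  for (q in c(1.5, 2.2, 3)) {
    expect_equal(psmm(q, m, df), mean(mx <= q), tolerance = 0.01)
  }
  expect_equal(psmm(0, 3, 10), 0)
  # m = 1 reduces to the two-sided t probability
  expect_equal(psmm(2, 1, 15), 1 - 2 * pt(2, 15, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("Dunnett T3 is conservative relative to unadjusted Welch and handles ties", {
  set.seed(20)
  x <- c(rnorm(10, 0, 1), rnorm(15, 0.5, 3), rnorm(20, 1, 0.5))
  g <- rep(c("a", "b", "c"), c(10, 15, 20))
  p3 <- dunnett_t3_pairwise(x, g)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    w <- t.test(x[g == pair[1]], x[g == pair[2]])$p.value
    expect_gte(p3[pair[1], pair[2]], w - 1e-12)
  }
  expect_true(all(p3[upper.tri(p3)] >= 0 & p3[upper.tri(p3)] <= 1))
  pid <- dunnett_t3_pairwise(rep(4, 12), rep(1:3, each = 4))
  expect_true(all(pid[upper.tri(pid)] == 1))
})

test_that("compact letters are consistent with the pairwise matrix on random instances", {
  check_cld <- function(pmat, letters_vec, alpha) {
    k <- nrow(pmat)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        shared <- length(intersect(strsplit(letters_vec[i], "")[[1]],
                                   strsplit(letters_vec[j], "")[[1]])) > 0
        if (pmat[i, j] <= alpha) expect_false(shared) else expect_true(shared)
      }
    }
  }
  set.seed(21)
  for (rep in 1:400) {
    k <- sample(2:5, 1)
    pmat <- matrix(0, k, k, dimnames = list(letters[1:k], letters[1:k]))
    pv <- runif(k * (k - 1) / 2)
    pmat[upper.tri(pmat)] <- pv
    pmat <- pmat + t(pmat)
    diag(pmat) <- NA
    check_cld(pmat, compact_letters(pmat, alpha = 0.5), 0.5)
  }
  # all-distinct and all-shared extremes
  pm <- matrix(0.001, 3, 3, dimnames = list(1:3, 1:3)); diag(pm) <- NA
  expect_equal(unname(compact_letters(pm)), c("a", "b", "c"))
  pm2 <- matrix(0.9, 3, 3, dimnames = list(1:3, 1:3)); diag(pm2) <- NA
  expect_equal(unname(compact_letters(pm2)), c("a", "a", "a"))
})
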