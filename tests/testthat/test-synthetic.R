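# Synthetic generator: measurement sampling, inverse geometry, rosters.

test_that("round trip measure(construct(theta)) recovers theta to 1e-9", {
  # the published normal-group means as the anchor point
  theta <- tibble::tibble(SNA = 82.40, SNB = 73.94, MP_SN = 39.11,
                          A_to_Y = 61.69, Pg_to_Y = 48.60, N_Me = 122.25,
                          S_Go = 78.01)
  m <- ceph_measure(construct_landmarks(theta))
  expect_equal(as.numeric(m[free_vars]), as.numeric(theta), tolerance = 1e-9)
  expect_equal(m$ANB, m$SNA - m$SNB, tolerance = 1e-12)
  expect_equal(m$ratio, 100 * m$S_Go / m$N_Me, tolerance = 1e-12)

  set.seed(23)
  worst <- 0
  for (i in 1:300) {
    th <- random_theta()
    mt <- ceph_measure(construct_landmarks(th))
    worst <- max(worst, max(abs(as.numeric(mt[free_vars]) - as.numeric(th))))
  }
  expect_lt(worst, 1e-9)
})

test_that("round trip also holds for a user-fixed S-N distance, with infeasibility flagged", {
  th <- tibble::tibble(SNA = 78, SNB = 72, MP_SN = 40, A_to_Y = 58,
                       Pg_to_Y = 46, N_Me = 118, S_Go = 74)
  nu <- list(sn_mm = 66)
  m <- ceph_measure(construct_landmarks(th, nuisance = nu))
  expect_equal(as.numeric(m[free_vars]), as.numeric(th), tolerance = 1e-9)
  # with d fixed at 66 the A-line is posterior of nasion's Y-parallel,
  # so SNA beyond the 83-degree ceiling has no solution
  th_bad <- dplyr::mutate(th, SNA = 85)
  expect_error(construct_landmarks(th_bad, nuisance = nu), "infeasible")
  # a mandibular plane parallel to the X-axis cannot intersect the
  # posterior-height horizontal
  expect_error(construct_landmarks(dplyr::mutate(th, MP_SN = 7)),
               "infeasible")
})

test_that("nuisance parameters do not move any reported measurement", {
  th <- random_theta_fixed <- tibble::tibble(
    SNA = 81, SNB = 73, MP_SN = 44, A_to_Y = 60, Pg_to_Y = 45,
    N_Me = 121, S_Go = 73)
  base <- ceph_measure(construct_landmarks(th))
  for (nu in list(list(nb_mm = 80), list(me_x_mm = 52),
                  list(pg_rise_mm = 12), list(sn_mm = 70))) {
    m <- ceph_measure(construct_landmarks(th, nuisance = nu))
    expect_equal(as.numeric(m[measurement_cols]),
                 as.numeric(base[measurement_cols]), tolerance = 1e-9)
  }
})

test_that("sampling is deterministic under seed and degenerate at SD = 0", {
  cfg <- synthetic_config()
  a <- sample_measurements(cfg, "osteoarthrosis", n = 50, seed = 99)
  b <- sample_measurements(cfg, "osteoarthrosis", n = 50, seed = 99)
  expect_identical(a, b)
  p0 <- tmjoa_group_params()
  p0$sd <- 0
  expect_error(synthetic_config(params = p0), "SD")
  # near-zero SDs collapse every draw onto the mean vector
  p0$sd <- 1e-9
  cfg0 <- synthetic_config(params = p0)
  d <- sample_measurements(cfg0, "normal", n = 5, seed = 1)
  mu <- setNames(p0$mean[p0$group == "normal"],
                 p0$variable[p0$group == "normal"])
  for (v in free_vars) expect_equal(d[[v]], rep(unname(mu[v]), 5),
                                    tolerance = 1e-6)
})

test_that("sampled marginals match the configured distributions (KS, fixed seed)", {
  cfg <- synthetic_config()
  d <- sample_measurements(cfg, "osteoarthrosis", n = 5000, seed = 2024)
  pars <- tmjoa_group_params()
  pars <- pars[pars$group == "osteoarthrosis", ]
  for (v in free_vars) {
    mu <- pars$mean[pars$variable == v]
    sg <- pars$sd[pars$variable == v]
    expect_gt(ks.test(d[[v]], "pnorm", mu, sg)$p.value, 0.01)
  }
  # derived identities hold on every draw
  expect_equal(d$ANB, d$SNA - d$SNB, tolerance = 1e-12)
  expect_equal(d$ratio, 100 * d$S_Go / d$N_Me, tolerance = 1e-12)
})

test_that("direct ratio mode samples the ratio and derives S_Go", {
  cfg <- synthetic_config(ratio_mode = "direct")
  d <- sample_measurements(cfg, "osteoarthrosis", n = 5000, seed = 31)
  expect_gt(ks.test(d$ratio, "pnorm", 57.13, 4.48)$p.value, 0.01)
  expect_equal(d$S_Go, d$ratio * d$N_Me / 100, tolerance = 1e-12)
})

test_that("generate_cohort produces the configured sizes with valid geometry", {
  coh <- generate_cohort(synthetic_config(), seed = 55)
  expect_equal(nrow(coh$groups), 75)
  expect_equal(unname(table(coh$groups$group)[c("normal", "indeterminate",
                                                "osteoarthrosis")]),
               c(17L, 19L, 39L), ignore_attr = TRUE)
  # every landmark set re-measures to the recorded measurement table
  m2 <- ceph_measure(coh$landmarks)
  merged <- dplyr::inner_join(m2, coh$measurements, by = "subject_id",
                              suffix = c("", ".drawn"))
  for (v in free_vars) {
    expect_equal(merged[[v]], merged[[paste0(v, ".drawn")]],
                 tolerance = 1e-9)
  }
  # determinism
  coh2 <- generate_cohort(synthetic_config(), seed = 55)
  expect_identical(coh$measurements, coh2$measurements)
  expect_identical(coh$landmarks, coh2$landmarks)
  # group-wise MP_SN means near their configured values (CLT bound)
  mps <- dplyr::summarise(dplyr::group_by(coh$measurements, group),
                          m = mean(MP_SN))
  pars <- tmjoa_group_params()
  for (gr in mps$group) {
    mu <- pars$mean[pars$group == gr & pars$variable == "MP_SN"]
    sg <- pars$sd[pars$group == gr & pars$variable == "MP_SN"]
    n <- sum(coh$groups$group == gr)
    expect_lt(abs(mps$m[mps$group == gr] - mu), 4 * sg / sqrt(n))
  }
})

test_that("config validation rejects empty groups and bad correlations", {
  expect_error(synthetic_config(group_sizes = c(a = 17, b = 19, c = 0)),
               "n >= 2")
  expect_error(synthetic_config(correlation = diag(3)), "correlation")
  bad <- diag(7); bad[1, 2] <- 0.5  # asymmetric
  expect_error(synthetic_config(correlation = bad), "correlation")
})

test_that("roster generator reproduces the reference patient table and tallies", {
  f <- generate_condylar_roster(seed = 123)
  pat <- aggregate_patients(classify_condyles(f))
  s <- summarize_cohort(pat, f)
  expect_equal(s$patients$total, c(17L, 21L, 45L))
  expect_equal(s$patients$bilateral, c(17L, 19L, 39L))
  expect_equal(s$patients$unilateral, c(0L, 2L, 6L))
  expect_equal(s$n_records, 183L)
  got <- setNames(s$features$n, s$features$feature)
  expect_equal(got[["normal"]], 39L)
  expect_equal(got[["short_condyle"]], 34L)
  expect_equal(got[["subcortical_cyst"]], 0L)
  expect_equal(got[["erosion"]], 26L)
})

test_that("rosters classify back to random consistent specifications", {
  set.seed(202)
  cats <- c("normal", "indeterminate", "osteoarthrosis")
  for (rep in 1:25) {
    pats <- expand.grid(left = cats, right = cats,
                        stringsAsFactors = FALSE)
    pats$n <- rpois(nrow(pats), 4)
    pats <- pats[pats$n > 0, ]
    sp <- roster_spec(pats)
    f <- generate_condylar_roster(sp, seed = rep)
    diag <- aggregate_patients(classify_condyles(f))
    canon <- function(l, r) sort(paste(pmin(as.character(l), as.character(r)),
                                       pmax(as.character(l), as.character(r))))
    expect_equal(canon(diag$left_category, diag$right_category),
                 canon(pats$left[rep(seq_len(nrow(pats)), pats$n)],
                       pats$right[rep(seq_len(nrow(pats)), pats$n)]))
  }
  # all-normal spec: no flags anywhere
  f0 <- generate_condylar_roster(
    roster_spec(tibble::tibble(left = "normal", right = "normal", n = 5)),
    seed = 1)
  expect_true(all(as.matrix(f0[cephtmj:::TMJ_FEATURES]) == 0))
  # inconsistent tallies are rejected
  expect_error(generate_condylar_roster(roster_spec(
    tibble::tibble(left = "osteoarthrosis", right = "osteoarthrosis", n = 2),
    feature_tallies = c(erosion = 1L))), "inconsistent")
})
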