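# Condylar osseous classification, worst-side aggregation, cohort tables.

all_flags <- cephtmj:::TMJ_FEATURES
oa_tier <- cephtmj:::TMJ_OA_TIER
ind_tier <- cephtmj:::TMJ_IND_TIER

test_that("hand cases classify as expected", {
  f <- dplyr::bind_rows(
    feature_row("p1", "left", "erosion"),
    feature_row("p1", "right", c("subcortical_sclerosis",
                                 "surface_flattening")),
    feature_row("p2", "left"),
    feature_row("p2", "right", c("surface_flattening", "osteophyte")))
  d <- classify_condyles(f)
  expect_equal(as.character(d$category),
               c("osteoarthrosis", "indeterminate", "normal",
                 "osteoarthrosis"))
  expect_equal(d$triggering_features[[1]], "erosion")
  expect_setequal(d$triggering_features[[2]],
                  c("subcortical_sclerosis", "surface_flattening"))
  expect_equal(d$triggering_features[[4]], "osteophyte")  # winning tier only
})

test_that("all 256 flag combinations match a brute-force restatement of the rules", {
  grid <- expand.grid(rep(list(0:1), length(all_flags)))
  names(grid) <- all_flags
  grid$subject_id <- sprintf("c%03d", seq_len(nrow(grid)))
  grid$side <- "left"
  got <- classify_condyles(grid)
  # independent restatement: per-flag severity lookup, take the maximum
  severity <- ifelse(all_flags %in% oa_tier, 3L, 2L)
  want <- apply(as.matrix(grid[all_flags]), 1, function(fl) {
    s <- c(1L, severity[fl == 1])
    c("normal", "indeterminate", "osteoarthrosis")[max(s)]
  })
  expect_equal(as.character(got$category), unname(want))
  # monotonicity: adding an OA-tier flag never lowers the category
  for (f in oa_tier) {
    with_f <- grid
    with_f[[f]] <- 1L
    expect_true(all(classify_condyles(with_f)$category >= got$category))
  }
})

test_that("worst-side aggregation is commutative and idempotent over all 9 pairs", {
  cats <- c("normal", "indeterminate", "osteoarthrosis")
  pairs <- expand.grid(left = cats, right = cats,
                       stringsAsFactors = FALSE)
  d <- tibble::tibble(
    subject_id = rep(sprintf("p%d", seq_len(nrow(pairs))), each = 2),
    side = rep(c("left", "right"), nrow(pairs)),
    category = as.vector(rbind(pairs$left, pairs$right)))
  agg <- aggregate_patients(d)
  d_sw <- d
  d_sw$side <- rep(c("right", "left"), nrow(pairs))
  agg_sw <- aggregate_patients(d_sw)
  expect_equal(as.character(agg$patient_category),
               as.character(agg_sw$patient_category))
  expect_equal(agg$laterality, agg_sw$laterality)
  # worst side wins; equal sides are bilateral
  sev <- function(x) match(x, cats)
  expect_equal(sev(as.character(agg$patient_category)),
               pmax(sev(pairs$left), sev(pairs$right)))
  expect_equal(agg$laterality,
               ifelse(pairs$left == pairs$right, "bilateral", "unilateral"))
})

test_that("aggregation rejects a missing side", {
  d <- tibble::tibble(subject_id = c("a", "a", "b"),
                      side = c("left", "right", "left"),
                      category = "normal")
  expect_error(aggregate_patients(d), "missing right-condyle.*b")
})

test_that("cohort summary satisfies the record-counting identity on random rosters", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    f <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      dplyr::bind_rows(
        feature_row(sprintf("p%02d", i), "left",
                    sample(all_flags, rpois(1, 1.2), replace = FALSE)),
        feature_row(sprintf("p%02d", i), "right",
                    sample(all_flags, rpois(1, 1.2), replace = FALSE)))
    }))
    pat <- aggregate_patients(classify_condyles(f))
    s <- summarize_cohort(pat, f)
    flags <- as.matrix(f[all_flags])
    expect_equal(s$n_records, sum(rowSums(flags) == 0) + sum(flags))
    expect_equal(sum(s$patients$total), n)
    expect_equal(sum(s$features$pct), 100, tolerance = 1e-9)
    # rounded percentages still sum to ~100
    expect_lt(abs(sum(round(s$features$pct, 1)) - 100), 0.5)
  }
})

test_that("a flagless patient contributes two normal records at 100%", {
  f <- dplyr::bind_rows(feature_row("p1", "left"), feature_row("p1", "right"))
  s <- summarize_cohort(aggregate_patients(classify_condyles(f)), f)
  expect_equal(s$features$n[s$features$feature == "normal"], 2L)
  expect_equal(s$features$pct[s$features$feature == "normal"], 100)
  expect_equal(s$n_records, 2L)
})

test_that("duplicate subject-side records are rejected", {
  f <- dplyr::bind_rows(feature_row("p1", "left"), feature_row("p1", "left"))
  expect_error(summarize_cohort(tibble::tibble(), f), "duplicate")
})
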