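## Synthetic condylar feature rosters: per-condyle flag tables whose
## classification and worst-side aggregation reproduce a prescribed
## patient table, with per-feature record tallies matched exactly.

#' Reference cohort roster specification
#'
#' The 83-patient roster reconstructed from the reference cohort's
#' patient table and results: 17 bilaterally normal, 19 bilaterally
#' indeterminate, 2 unilateral indeterminate (contralateral normal), 39
#' bilateral osteoarthrosis, 3 unilateral osteoarthrosis with a normal
#' contralateral condyle and 3 with an indeterminate contralateral
#' condyle; plus per-feature record tallies (183 records in total, the
#' 39 flagless condyles each contributing one "normal" record).
#'
#' @return A list of class `tmj_roster_spec` with `patterns` (tibble:
#'   `left`, `right`, `n`) and `feature_tallies` (named integer vector
#'   over the eight flags).
#' @export
tmjoa_roster_spec <- function() {
  patterns <- tibble::tribble(
    ~left,            ~right,           ~n,
    "normal",          "normal",         17L,
    "indeterminate",   "indeterminate",  19L,
    "indeterminate",   "normal",          2L,
    "osteoarthrosis",  "osteoarthrosis", 39L,
    "osteoarthrosis",  "normal",          3L,
    "osteoarthrosis",  "indeterminate",   3L)
  tallies <- c(subcortical_sclerosis = 11L, surface_flattening = 17L,
               subcortical_cyst = 0L, erosion = 26L, osteophyte = 28L,
               generalized_sclerosis = 13L, hypoplasia = 15L,
               short_condyle = 34L)
  roster_spec(patterns, tallies)
}

#' Build a roster specification
#'
#' @param patterns Tibble with columns `left`, `right` (diagnostic
#'   categories) and `n` (patient counts).
#' @param feature_tallies Optional named integer vector of per-feature
#'   record targets (names among the eight flags).  Features not named
#'   are sampled uniformly within the required tier.
#' @return A list of class `tmj_roster_spec`.
#' @export
roster_spec <- function(patterns, feature_tallies = NULL) {
  patterns <- tibble::as_tibble(patterns)
  stopifnot(all(c("left", "right", "n") %in% names(patterns)))
  if (!all(c(patterns$left, patterns$right) %in% TMJ_CATEGORIES)) {
    stop("pattern categories must be among ",
         paste(TMJ_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  if (any(patterns$n < 0)) stop("pattern counts must be non-negative",
                                call. = FALSE)
  if (!is.null(feature_tallies)) {
    bad <- setdiff(names(feature_tallies), TMJ_FEATURES)
    if (length(bad)) stop("unknown feature(s) in tallies: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(feature_tallies < 0)) stop("tallies must be non-negative",
                                       call. = FALSE)
  }
  structure(list(patterns = patterns, feature_tallies = feature_tallies),
            class = "tmj_roster_spec")
}

## Distribute a multiset of flags over condyles: every condyle in
## `must_have` receives at least one flag; remaining flags go to random
## eligible condyles that do not yet carry them.
allocate_flags <- function(flag_counts, must_have, optional) {
  total <- sum(flag_counts)
  n_must <- length(must_have)
  if (total < n_must) {
    stop(sprintf(
      "inconsistent roster spec: %d flags of this tier cannot cover %d condyles",
      total, n_must), call. = FALSE)
  }
  eligible <- c(must_have, optional)
  if (any(flag_counts > length(eligible))) {
    stop("inconsistent roster spec: a feature tally exceeds the eligible condyles",
         call. = FALSE)
  }
  for (attempt in 1:50) {
    pool <- sample(rep(names(flag_counts), flag_counts))
    assign <- stats::setNames(vector("list", length(eligible)), eligible)
    # one flag per required condyle first
    order1 <- sample(must_have)
    for (i in seq_len(n_must)) assign[[order1[i]]] <- pool[i]
    rest <- pool[-seq_len(n_must)]
    ok <- TRUE
    for (f in rest) {
      open <- eligible[!vapply(assign[eligible], function(a) f %in% a,
                               logical(1))]
      if (!length(open)) { ok <- FALSE; break }
      pick <- if (length(open) == 1L) open else sample(open, 1L)
      assign[[pick]] <- c(assign[[pick]], f)
    }
    if (ok) return(assign)
  }
  stop("could not allocate feature flags consistently with the tallies",
       call. = FALSE)
}

#' Generate a synthetic condylar feature roster
#'
#' Emits one feature-flag record per condyle such that
#' [classify_condyles()] followed by [aggregate_patients()] reproduces
#' the specification's patient table exactly, and the per-feature
#' record tallies match the specification where given (uniform within
#' the required tier otherwise).
#'
#' @param spec A roster specification ([tmjoa_roster_spec()] by
#'   default).
#' @param seed Optional integer seed (local to this call).
#' @return A per-condyle feature tibble (columns `subject_id`, `side`,
#'   eight 0/1 flags).
#' @export
generate_condylar_roster <- function(spec = tmjoa_roster_spec(), seed = NULL) {
  stopifnot(inherits(spec, "tmj_roster_spec"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_condylar_roster(spec)))
  }
  pat <- spec$patterns[rep(seq_len(nrow(spec$patterns)), spec$patterns$n), ]
  n_pat <- nrow(pat)
  ids <- sprintf("P%03d", seq_len(n_pat))
  condyles <- tibble::tibble(
    subject_id = rep(ids, each = 2L),
    side = rep(c("left", "right"), n_pat),
    target = as.vector(rbind(pat$left, pat$right)))

  tallies <- spec$feature_tallies
  tier_counts <- function(tier, n_needed) {
    if (is.null(tallies)) {
      # uniform within the tier: split n_needed as evenly as possible
      base <- rep(floor(n_needed / length(tier)), length(tier))
      extra <- n_needed - sum(base)
      if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
      setNames(base, tier)
    } else {
      out <- rep(0L, length(tier)); names(out) <- tier
      out[intersect(names(tallies), tier)] <-
        tallies[intersect(names(tallies), tier)]
      out
    }
  }
  ind_id <- which(condyles$target == "indeterminate")
  oa_id <- which(condyles$target == "osteoarthrosis")
  key <- function(i) {
    if (!length(i)) return(character(0))
    paste0(condyles$subject_id[i], "/", condyles$side[i])
  }

  flags <- matrix(0L, nrow(condyles), length(TMJ_FEATURES),
                  dimnames = list(key(seq_len(nrow(condyles))), TMJ_FEATURES))

  ind_alloc <- allocate_flags(tier_counts(TMJ_IND_TIER, length(ind_id)),
                              must_have = key(ind_id),
                              optional = key(oa_id))
  oa_alloc <- allocate_flags(tier_counts(TMJ_OA_TIER, length(oa_id)),
                             must_have = key(oa_id), optional = character(0))
  for (k in names(ind_alloc)) flags[k, ind_alloc[[k]]] <- 1L
  for (k in names(oa_alloc)) flags[k, oa_alloc[[k]]] <- 1L

  out <- dplyr::bind_cols(condyles[, c("subject_id", "side")],
                          tibble::as_tibble(flags))
  # self-check: the roster must classify back to its own specification
  diag <- aggregate_patients(classify_condyles(out))
  canon <- function(l, r) {
    l <- as.character(l); r <- as.character(r)
    sort(paste(pmin(l, r), pmax(l, r)))  # unordered side pairs
  }
  if (!identical(canon(diag$left_category, diag$right_category),
                 canon(pat$left, pat$right))) {
    stop("internal error: generated roster does not classify back to the spec",
         call. = FALSE)
  }
  out
}
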