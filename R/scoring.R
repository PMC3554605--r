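#' Scoring and candidate-test parameters
#'
#' All tunable constants of the match-score equations and candidate tests.
#'
#' @param s steepness of the score transformation (> 0); together with `t`
#'   it shapes [transform_snms()] from near-linear (`s` close to 0, `t = 0`)
#'   through logistic (`s > 1`, `t = 0`) to double-logistic (`s > 1`,
#'   `t >= 1`) forms.
#' @param t center-size parameter of the transformation (>= 0).
#' @param name_weight,author_weight weights of the transformed name score
#'   and the author score in the overall match score; must sum to 1.
#' @param wrong_rank_penalty penalty subtracted from a component's partial
#'   match score when the submitted rank indicator ("var.", "subsp.", ...)
#'   is present but not the correct one.
#' @param unmatched_text_penalty fixed penalty subtracted from the overall
#'   score when the submission contained text matched to nothing.
#' @param maxedr_short,maxedr_long maximum edit-distance ratio of the match
#'   threshold test for short (`MSL < msl_short_cutoff`) and long
#'   components. The short-string value is laxer to offset the bias against
#'   matching short strings.
#' @param msl_short_cutoff component length at which the stricter ratio
#'   starts to apply.
#' @param max_ed_per_part per-name-part budget of the maximum-ED test: a
#'   candidate's total edit distance must not exceed
#'   `max_ed_per_part * (number of name parts)`. Rank indicators are not
#'   name parts.
#' @param min_oms minimum overall match score a candidate must reach to be
#'   reported (the "match accuracy" control; 0 reports everything, 1 demands
#'   a perfect match).
#' @param max_block block length cap of [mdld()].
#' @param genus_ed_budget edit-distance budget for the genus pre-filter of
#'   the hierarchical search.
#' @return an object of class `scoring_params` (a validated list).
#' @export
scoring_params <- function(s = 2, t = 1,
                           name_weight = 0.8, author_weight = 0.2,
                           wrong_rank_penalty = 0.3,
                           unmatched_text_penalty = 0.1,
                           maxedr_short = 0.5, maxedr_long = 0.3334,
                           msl_short_cutoff = 6L,
                           max_ed_per_part = 2L,
                           min_oms = 0,
                           max_block = 4L,
                           genus_ed_budget = 2L) {
  stopifnot(s > 0, t >= 0,
            abs(name_weight + author_weight - 1) < 1e-9,
            wrong_rank_penalty >= 0, unmatched_text_penalty >= 0,
            maxedr_short > 0, maxedr_long > 0,
            msl_short_cutoff >= 1, max_ed_per_part >= 1,
            min_oms >= 0, min_oms <= 1)
  structure(list(
    s = s, t = t, name_weight = name_weight, author_weight = author_weight,
    wrong_rank_penalty = wrong_rank_penalty,
    unmatched_text_penalty = unmatched_text_penalty,
    maxedr_short = maxedr_short, maxedr_long = maxedr_long,
    msl_short_cutoff = as.integer(msl_short_cutoff),
    max_ed_per_part = as.integer(max_ed_per_part),
    min_oms = min_oms,
    max_block = as.integer(max_block),
    genus_ed_budget = as.integer(genus_ed_budget)
  ), class = "scoring_params")
}

#' Partial match score of one name component
#'
#' `PMS = 1 - 2 * ED / MaxED`, where `MaxED` is the length of the longer of
#' the two strings, so PMS runs from 1 (identical) to -1 (nothing shared).
#' When the submitted rank indicator for the component is present but wrong
#' ("fo." submitted against a stored "var."), `wrong_rank_penalty` is
#' subtracted; the result is clamped to at least -1.
#'
#' @param ed integer edit distance(s).
#' @param max_ed length of the longer string in each comparison.
#' @param rank_indicator_wrong logical; wrong-rank-indicator penalty flag.
#' @param params a [scoring_params()] object.
#' @return numeric vector of partial match scores in \eqn{[-1, 1]}.
#' @examples
#' partial_match_score(1, 5)                            # Fucus vs Ficus: 0.6
#' partial_match_score(0, 7, rank_indicator_wrong = TRUE) # 0.7
#' @export
partial_match_score <- function(ed, max_ed, rank_indicator_wrong = FALSE,
                                params = scoring_params()) {
  stopifnot(all(max_ed > 0))
  pms <- 1 - 2 * ed / max_ed
  pms <- pms - ifelse(rank_indicator_wrong, params$wrong_rank_penalty, 0)
  pmax(pms, -1)
}

#' Transform the scientific-name match score to \eqn{[0, 1]}
#'
#' The raw scientific-name match score `SNMS` (the sum of the per-component
#' partial scores) runs from `-k` to `k` for `k` components. It is rescaled
#' with a sign-preserving arctangent transformation,
#' \deqn{SNMS_{tr} = \frac{\mathrm{atan}\!\big((s \cdot SNMS / k)^{2t+1}\big)}
#'   {2\,\mathrm{atan}\!\big(s^{2t+1}\big)} + \frac{1}{2},}
#' which maps `-k`, `0` and `k` to 0, 0.5 and 1 for any `s > 0`, `t >= 0`,
#' is strictly increasing in `SNMS`, and with the defaults `s = 2`, `t = 1`
#' has two flat regions of certainty at the extremes, a flat central region
#' of uncertainty, and two steep regions of discrimination in between. With
#' `s` near 0 and `t = 0` it approaches a linear rescaling.
#'
#' @param snms raw score, in \eqn{[-k, k]}.
#' @param k number of name components scored.
#' @param params a [scoring_params()] object.
#' @return transformed score in \eqn{[0, 1]}.
#' @export
transform_snms <- function(snms, k, params = scoring_params()) {
  stopifnot(k >= 1)
  if (any(snms < -k - 1e-9) || any(snms > k + 1e-9)) {
    stop("snms must lie in [-k, k]")
  }
  s <- params$s
  e <- 2 * params$t + 1
  z <- s * snms / k
  val <- sign(z) * atan(abs(z)^e) / (2 * atan(s^e)) + 0.5
  pmin(pmax(val, 0), 1)
}

#' Overall match score
#'
#' Blends the transformed name score with the author score when an author
#' comparison was possible (`OMS = 0.8 * SNMS_tr + 0.2 * AMS - p` with the
#' default weights), or passes the name score through unchanged when it was
#' not (`OMS = SNMS_tr - p`). The penalty `p` is `unmatched_text_penalty`
#' when the submission contained unmatched text, else 0. The result is
#' clamped to \eqn{[0, 1]}. Perfect verbatim matches found during
#' pre-processing bypass this calculation and score 1.0.
#'
#' @param snms_tr transformed name score.
#' @param ams author match score, or `NA` when no author comparison was
#'   made.
#' @param has_unmatched_text logical penalty flag.
#' @param params a [scoring_params()] object.
#' @return overall match score in \eqn{[0, 1]}.
#' @export
overall_score <- function(snms_tr, ams = NA_real_,
                          has_unmatched_text = FALSE,
                          params = scoring_params()) {
  p <- ifelse(has_unmatched_text, params$unmatched_text_penalty, 0)
  oms <- ifelse(is.na(ams),
                snms_tr - p,
                params$name_weight * snms_tr + params$author_weight * ams - p)
  pmin(pmax(oms, 0), 1)
}

#' Score a candidate match
#'
#' Runs the four scoring steps for one candidate: per-component partial
#' match scores (unmatched query components — those deeper than the
#' reference record — contribute -1 each), their sum `SNMS`, the
#' transformation [transform_snms()], and the author blend
#' [overall_score()].
#'
#' @param candidate a candidate produced by [hierarchical_search()].
#' @param params a [scoring_params()] object.
#' @return the candidate with a `scores` element: list with `pms` (named
#'   numeric), `snms`, `snms_tr`, `ams`, `oms` and `k`.
#' @export
score_candidate <- function(candidate, params = scoring_params()) {
  comps <- candidate$components
  pms <- partial_match_score(comps$ed, comps$max_ed, comps$wrong_rank,
                             params)
  names(pms) <- comps$component
  if (length(candidate$unmatched_components)) {
    miss <- stats::setNames(rep(-1, length(candidate$unmatched_components)),
                            candidate$unmatched_components)
    pms <- c(pms, miss)
  }
  k <- length(pms)
  snms <- sum(pms)
  snms_tr <- transform_snms(snms, k, params)
  ams <- NA_real_
  if (nzchar(candidate$query_author %||% "") &&
      nzchar(candidate$reference_author %||% "")) {
    ams <- author_similarity(candidate$query_author,
                             candidate$reference_author)$ams
  }
  oms <- overall_score(snms_tr, ams, isTRUE(candidate$has_unmatched_text),
                       params)
  candidate$scores <- list(pms = pms, snms = snms, snms_tr = snms_tr,
                           ams = ams, oms = oms, k = k)
  candidate
}
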