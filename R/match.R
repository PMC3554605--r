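#' Maximum edit distance test
#'
#' A candidate qualifies only if its total edit distance across components
#' satisfies `ED <= max_ed_per_part * n_parts`. Rank indicators are not
#' counted as name parts, so a binomial has 2 parts (budget 4 with the
#' default) and a variety has 3 (budget 6).
#'
#' @param total_ed summed edit distance across compared components.
#' @param n_parts number of name parts compared.
#' @param params a [scoring_params()] object.
#' @return logical.
#' @export
max_ed_test <- function(total_ed, n_parts, params = scoring_params()) {
  stopifnot(n_parts >= 1)
  total_ed <= params$max_ed_per_part * n_parts
}

#' Per-component match threshold test
#'
#' Orthographic plausibility test applied to each name component: the edit
#' distance, scaled by the length of the shorter string (`MSL`), must not
#' exceed the maximum edit-distance ratio (0.5 for `MSL < 6`, 0.3334
#' otherwise), and larger distances must be anchored at the start of the
#' word — `2 <= ED < 4` requires the first character to match and `ED = 4`
#' requires the first three. Distances of 0 or 1 pass unconditionally
#' (the printed conjunction would otherwise reject near-exact matches), and
#' `ED > 4` always fails, leaving phonetic equality as the only rescue.
#'
#' @param ed component edit distance.
#' @param msl length of the shorter of the two strings.
#' @param query,reference the compared strings (for the first-character
#'   anchoring).
#' @param params a [scoring_params()] object.
#' @return logical.
#' @examples
#' threshold_test(2, 8, "Marsilleya", "Marsilea") # TRUE
#' threshold_test(2, 4, "Ulleya", "Ulea")         # TRUE only at ratio 0.5
#' @export
threshold_test <- function(ed, msl, query, reference,
                           params = scoring_params()) {
  if (ed <= 1) return(TRUE)
  if (ed > 4) return(FALSE)
  maxedr <- if (msl < params$msl_short_cutoff) params$maxedr_short
            else params$maxedr_long
  if (ed / msl > maxedr) return(FALSE)
  q <- tolower(query)
  r <- tolower(reference)
  if (ed < 4) {
    substr(q, 1, 1) == substr(r, 1, 1)
  } else {
    substr(q, 1, 3) == substr(r, 1, 3)
  }
}

# Component-level pass used for staged pruning: a component can appear in a
# retained candidate only if it is phonetically equal or passes the
# threshold test. The genus stage additionally keeps anything within the
# small fixed ED budget.
component_pass <- function(ed, msl, query, reference, phonetic_equal,
                           params, budget = NULL) {
  pass <- phonetic_equal |
    mapply(threshold_test, ed, msl, query, reference,
           MoreArgs = list(params = params))
  if (!is.null(budget)) pass <- pass | ed <= budget
  pass
}

component_row <- function(component, query, reference, phonetic_equal,
                          wrong_rank = FALSE, params) {
  data.frame(
    component = component,
    query = query,
    reference = reference,
    ed = mdld(query, reference, params$max_block),
    max_ed = pmax(nchar(query), nchar(reference)),
    msl = pmin(nchar(query), nchar(reference)),
    phonetic_equal = phonetic_equal,
    wrong_rank = wrong_rank,
    stringsAsFactors = FALSE
  )
}

# Assemble one candidate (components, tests, flags) for a reference row.
build_candidate <- function(row, parsed, params, family_scored) {
  comps <- list()
  if (family_scored && nzchar(parsed$family) && nzchar(row$family)) {
    comps$family <- component_row(
      "family", parsed$family, row$family,
      phonetic_key(parsed$family) == row$family_key, FALSE, params)
  }
  if (row$rank != "family" && nzchar(parsed$genus)) {
    comps$genus <- component_row(
      "genus", parsed$genus, row$genus,
      phonetic_key(parsed$genus) == row$genus_key, FALSE, params)
  }
  if (nzchar(row$specific_epithet) && nzchar(parsed$specific_epithet)) {
    comps$species <- component_row(
      "species", parsed$specific_epithet, row$specific_epithet,
      phonetic_key(parsed$specific_epithet, epithet = TRUE) ==
        row$epithet_key, FALSE, params)
  }
  if (nzchar(row$infraspecific_epithet) &&
      nzchar(parsed$infraspecific_epithet)) {
    wrong <- nzchar(parsed$rank_indicator) &&
      parsed$rank_indicator != row$infra_rank_indicator
    comps$infraspecies <- component_row(
      "infraspecies", parsed$infraspecific_epithet,
      row$infraspecific_epithet,
      phonetic_key(parsed$infraspecific_epithet, epithet = TRUE) ==
        row$infra_key, wrong, params)
  }
  if (nzchar(row$infra2_epithet) && nzchar(parsed$infraspecific_epithet2)) {
    wrong <- nzchar(parsed$rank_indicator2) &&
      parsed$rank_indicator2 != row$infra2_rank_indicator
    comps$infraspecies2 <- component_row(
      "infraspecies2", parsed$infraspecific_epithet2, row$infra2_epithet,
      wrong = wrong,
      phonetic_equal = phonetic_key(parsed$infraspecific_epithet2,
                                    epithet = TRUE) == row$infra2_key,
      params = params)
  }
  comps <- do.call(rbind, comps)
  rownames(comps) <- NULL

  q_depth <- rank_depth(parsed$submitted_rank)
  r_depth <- record_depth(row)
  unmatched <- character(0)
  if (q_depth > r_depth) {
    ladder <- c("genus", "species", "infraspecies", "infraspecies2")
    unmatched <- ladder[seq_len(q_depth)]
    if (r_depth >= 1) unmatched <- unmatched[-seq_len(r_depth)]
  }

  thr <- mapply(threshold_test, comps$ed, comps$msl, comps$query,
                comps$reference, MoreArgs = list(params = params))
  total_ed <- sum(comps$ed)
  passed_max_ed <- max_ed_test(total_ed, nrow(comps), params)
  passed_phonetic <- all(comps$phonetic_equal)
  passed_threshold <- all(thr)

  list(
    name_id = row$name_id,
    reference = row,
    source_id = row$source_id,
    components = comps,
    unmatched_components = unmatched,
    is_partial = r_depth < q_depth,
    query_author = parsed$author,
    reference_author = row$author,
    has_unmatched_text = nzchar(parsed$unmatched_text),
    total_ed = total_ed,
    passed_max_ed = passed_max_ed,
    passed_phonetic = passed_phonetic,
    passed_threshold = passed_threshold,
    retained = passed_max_ed && (passed_phonetic || passed_threshold)
  )
}

#' Genus-first hierarchical candidate search
#'
#' The Taxamatch-style search that makes fuzzy matching tractable: candidate
#' genera are found first (phonetic key equality, the small genus ED budget,
#' or the per-component threshold test), species are evaluated only within
#' qualifying genera, and infraspecific taxa only under qualifying species.
#' When a family accompanies the name, candidate genera are restricted to
#' the families passing the same component tests, which also resolves many
#' homonyms. Reference records shallower than the submitted rank (e.g. a
#' genus record for a species query) are returned as partial-match
#' candidates.
#'
#' Every returned candidate passed the retention rule: the maximum-ED test,
#' plus either all components phonetically equal or all components passing
#' the match threshold test. The result is identical to filtering every
#' reference record through the same tests; the staging only prunes work.
#'
#' @param parsed a [parse_name()] result with a genus (or a family for
#'   family-rank queries).
#' @param db a [taxon_db].
#' @param params a [scoring_params()] object.
#' @return list of candidate matches (unscored; see [score_candidate()]).
#' @export
hierarchical_search <- function(parsed, db, params = scoring_params()) {
  nm <- db$names
  family_scored <- FALSE
  allowed_families <- NULL

  if (nzchar(parsed$family)) {
    fam <- nm[nm$rank == "family", , drop = FALSE]
    if (nrow(fam)) {
      fed <- mdld(parsed$family, fam$canonical, params$max_block)
      fphon <- phonetic_key(parsed$family) == fam$family_key
      fmsl <- pmin(nchar(parsed$family), nchar(fam$canonical))
      fpass <- component_pass(fed, fmsl, parsed$family, fam$canonical,
                              fphon, params, budget = params$genus_ed_budget)
      if (any(fpass)) {
        family_scored <- TRUE
        allowed_families <- fam$canonical[fpass]
      }
    }
  }

  if (!nzchar(parsed$genus)) {
    # family-rank query
    if (!family_scored) return(list())
    fam <- nm[nm$rank == "family" & nm$canonical %in% allowed_families, ,
              drop = FALSE]
    out <- lapply(seq_len(nrow(fam)), function(i) {
      build_candidate(fam[i, , drop = FALSE], parsed, params,
                      family_scored = TRUE)
    })
    return(Filter(function(cand) cand$retained, out))
  }

  pool <- nm[nm$rank != "family", , drop = FALSE]
  if (!is.null(allowed_families)) {
    pool <- pool[pool$family %in% allowed_families, , drop = FALSE]
  }
  if (!nrow(pool)) return(list())

  # Stage 1: genera.
  gtab <- unique(pool[, c("genus", "genus_key")])
  ged <- mdld(parsed$genus, gtab$genus, params$max_block)
  gphon <- phonetic_key(parsed$genus) == gtab$genus_key
  gmsl <- pmin(nchar(parsed$genus), nchar(gtab$genus))
  gpass <- component_pass(ged, gmsl, parsed$genus, gtab$genus, gphon,
                          params, budget = params$genus_ed_budget)
  genera <- gtab$genus[gpass]
  if (!length(genera)) return(list())
  pool <- pool[pool$genus %in% genera, , drop = FALSE]

  q_depth <- rank_depth(parsed$submitted_rank)
  pool <- pool[vapply(seq_len(nrow(pool)), function(i) {
    record_depth(pool[i, , drop = FALSE]) <= q_depth
  }, logical(1)), , drop = FALSE]
  if (!nrow(pool)) return(list())

  # Stage 2: species epithets within qualifying genera.
  if (q_depth >= 2) {
    deep <- nzchar(pool$specific_epithet)
    if (any(deep) && nzchar(parsed$specific_epithet)) {
      sub <- pool[deep, , drop = FALSE]
      eed <- mdld(parsed$specific_epithet, sub$specific_epithet,
                  params$max_block)
      ephon <- phonetic_key(parsed$specific_epithet, epithet = TRUE) ==
        sub$epithet_key
      emsl <- pmin(nchar(parsed$specific_epithet),
                   nchar(sub$specific_epithet))
      epass <- component_pass(eed, emsl, parsed$specific_epithet,
                              sub$specific_epithet, ephon, params,
                              budget = params$genus_ed_budget)
      pool <- rbind(pool[!deep, , drop = FALSE], sub[epass, , drop = FALSE])
    } else if (nzchar(parsed$specific_epithet)) {
      pool <- pool[!deep, , drop = FALSE]
    }
  }
  if (!nrow(pool)) return(list())

  # Stage 3: infraspecific epithets under qualifying species.
  if (q_depth >= 3 && nzchar(parsed$infraspecific_epithet)) {
    deep <- nzchar(pool$infraspecific_epithet)
    if (any(deep)) {
      sub <- pool[deep, , drop = FALSE]
      ied <- mdld(parsed$infraspecific_epithet, sub$infraspecific_epithet,
                  params$max_block)
      iphon <- phonetic_key(parsed$infraspecific_epithet, epithet = TRUE) ==
        sub$infra_key
      imsl <- pmin(nchar(parsed$infraspecific_epithet),
                   nchar(sub$infraspecific_epithet))
      ipass <- component_pass(ied, imsl, parsed$infraspecific_epithet,
                              sub$infraspecific_epithet, iphon, params,
                              budget = params$genus_ed_budget)
      pool <- rbind(pool[!deep, , drop = FALSE], sub[ipass, , drop = FALSE])
    }
  }
  if (!nrow(pool)) return(list())

  out <- lapply(seq_len(nrow(pool)), function(i) {
    build_candidate(pool[i, , drop = FALSE], parsed, params, family_scored)
  })
  Filter(function(cand) cand$retained, out)
}
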