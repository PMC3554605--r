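STATUS_RANK <- c(accepted = 1, synonym = 2, illegitimate = 2, invalid = 2,
                 no_opinion = 3)

#' Run settings for batch resolution
#'
#' Mirrors the user-facing name-processing and best-match controls: full
#' resolution vs parse-only mode, the minimum overall match score
#' ("match accuracy"), whether partial matches to a higher rank are allowed,
#' the two best-match constraints (by higher taxonomy, by source), the
#' source priority order, and the cap on reported alternatives.
#'
#' @param mode `"resolve"` (full name resolution) or `"parse_only"`.
#' @param min_oms minimum overall match score for reported candidates.
#' @param allow_partial allow matching a higher taxonomic component when the
#'   full name cannot be matched.
#' @param constrain_by_higher_taxonomy select the best match by ranking each
#'   name component separately, starting with the highest.
#' @param constrain_by_source rank all candidates from the top-priority
#'   source above those from lower-priority sources.
#' @param source_order optional ordered character vector of source ids
#'   (first = highest priority); defaults to load order.
#' @param max_alternatives cap on stored alternative matches per name.
#' @param output_path optional default output path for [run_batch()].
#' @param log_level one of `"quiet"`, `"info"`.
#' @return an object of class `run_settings`.
#' @export
run_settings <- function(mode = c("resolve", "parse_only"),
                         min_oms = 0,
                         allow_partial = TRUE,
                         constrain_by_higher_taxonomy = FALSE,
                         constrain_by_source = FALSE,
                         source_order = NULL,
                         max_alternatives = 20L,
                         output_path = NULL,
                         log_level = "info") {
  mode <- match.arg(mode)
  stopifnot(min_oms >= 0, min_oms <= 1, max_alternatives >= 1)
  structure(list(
    mode = mode, min_oms = min_oms, allow_partial = allow_partial,
    constrain_by_higher_taxonomy = constrain_by_higher_taxonomy,
    constrain_by_source = constrain_by_source,
    source_order = source_order,
    max_alternatives = as.integer(max_alternatives),
    output_path = output_path,
    log_level = log_level
  ), class = "run_settings")
}

cand_field <- function(cands, field, default = NA_real_) {
  vapply(cands, function(candidate) {
    v <- candidate$scores[[field]]
    if (is.null(v) || is.na(v)) default else v
  }, numeric(1))
}

cand_pms <- function(cands, component) {
  vapply(cands, function(candidate) {
    v <- candidate$scores$pms[component]
    if (is.na(v)) -1 else unname(v)
  }, numeric(1))
}

cand_status_rank <- function(cands) {
  vapply(cands, function(candidate) {
    unname(STATUS_RANK[candidate$reference$status])
  }, numeric(1))
}

cand_canonical <- function(cands) {
  vapply(cands, function(candidate) candidate$reference$canonical,
         character(1))
}

near <- function(a, b) abs(a - b) < 1e-9

#' Rank candidates without taxonomic constraints
#'
#' Orders candidate matches by descending raw name score (SNMS), descending
#' overall score (OMS) and taxonomic status (`accepted` before `synonym` —
#' with `illegitimate` and `invalid` ranked as synonyms — before
#' `no_opinion`), breaking exact ties alphabetically on the matched name.
#' A tie on all score and status keys between the two leading candidates is
#' flagged as an ambiguous match.
#'
#' @param cands list of scored candidates (see [score_candidate()]).
#' @return list with `cands` (reordered) and `ambiguous` (logical).
#' @export
rank_unconstrained <- function(cands) {
  if (!length(cands)) return(list(cands = cands, ambiguous = FALSE))
  snms <- cand_field(cands, "snms")
  oms <- cand_field(cands, "oms")
  st <- cand_status_rank(cands)
  canon <- cand_canonical(cands)
  ord <- order(-snms, -oms, st, canon,
               vapply(cands, function(x) x$name_id, character(1)))
  amb <- length(ord) >= 2 &&
    near(snms[ord[1]], snms[ord[2]]) && near(oms[ord[1]], oms[ord[2]]) &&
    st[ord[1]] == st[ord[2]]
  list(cands = cands[ord], ambiguous = amb)
}

#' Rank candidates constrained by higher taxonomy
#'
#' Ranks component-by-component starting from the highest submitted
#' component (family when one was submitted, then genus, species and
#' infraspecific epithets), so that a perfectly matching genus — even as a
#' partial match — outranks a species-level match in a misspelled genus.
#' Remaining ties fall back to the unconstrained keys.
#'
#' @param cands list of scored candidates.
#' @param family_submitted logical; was a family part of the submission?
#' @return list with `cands` (reordered) and `ambiguous` (logical).
#' @export
rank_constrained <- function(cands, family_submitted = FALSE) {
  if (!length(cands)) return(list(cands = cands, ambiguous = FALSE))
  keys <- list()
  if (family_submitted) keys$family <- -cand_pms(cands, "family")
  keys$genus <- -cand_pms(cands, "genus")
  keys$species <- -cand_pms(cands, "species")
  keys$infraspecies <- -cand_pms(cands, "infraspecies")
  keys$infraspecies2 <- -cand_pms(cands, "infraspecies2")
  snms <- cand_field(cands, "snms")
  oms <- cand_field(cands, "oms")
  st <- cand_status_rank(cands)
  canon <- cand_canonical(cands)
  ord <- do.call(order, c(unname(keys),
                          list(-snms, -oms, st, canon,
                               vapply(cands, function(x) x$name_id,
                                      character(1)))))
  first_two_tie <- length(ord) >= 2 &&
    all(vapply(keys, function(k) near(k[ord[1]], k[ord[2]]), logical(1))) &&
    near(snms[ord[1]], snms[ord[2]]) && near(oms[ord[1]], oms[ord[2]]) &&
    st[ord[1]] == st[ord[2]]
  list(cands = cands[ord], ambiguous = first_two_tie)
}

#' Re-rank candidates by source priority
#'
#' Stable partition of an already-ranked candidate list so that all
#' candidates from higher-priority sources precede all candidates from
#' lower-priority sources, preserving the within-source order. With a
#' single source this is a no-op.
#'
#' @param cands ranked list of candidates.
#' @param source_priority ordered character vector of source ids (first =
#'   highest priority).
#' @return reordered list.
#' @export
rank_by_source <- function(cands, source_priority) {
  if (length(cands) <= 1 || length(source_priority) <= 1) return(cands)
  src <- vapply(cands, function(x) x$source_id, character(1))
  pr <- match(src, source_priority)
  pr[is.na(pr)] <- length(source_priority) + 1L
  cands[order(pr, seq_along(cands))]
}

different_higher_taxon <- function(a, b) {
  ga <- a$reference$genus
  gb <- b$reference$genus
  if (nzchar(ga) || nzchar(gb)) return(!identical(ga, gb))
  !identical(a$reference$family, b$reference$family)
}

#' Assign warnings to a resolution result
#'
#' Fills the four warning classes for both ranking modes: `partial_match`
#' (matched rank is higher than submitted), `ambiguous_match` (tie on all
#' ranking keys), `better_spelling_match_in_different_higher_taxon` (on the
#' constrained best, when the unconstrained best scores higher in a
#' different higher taxon) and `better_higher_taxonomic_match_available`
#' (on the unconstrained best, when the constrained winner differs).
#'
#' @param result a `name_resolution` in construction (internal use; exposed
#'   for testing).
#' @return the result with `warnings_unconstrained`,
#'   `warnings_constrained` filled.
#' @export
assign_warnings <- function(result) {
  w_un <- character(0)
  w_con <- character(0)
  bu <- result$best_unconstrained
  bc <- result$best_constrained
  if (!is.null(bu)) {
    if (isTRUE(bu$is_partial)) w_un <- c(w_un, "partial_match")
    if (isTRUE(result$ambiguous_unconstrained)) {
      w_un <- c(w_un, "ambiguous_match")
    }
  }
  if (!is.null(bc)) {
    if (isTRUE(bc$is_partial)) w_con <- c(w_con, "partial_match")
    if (isTRUE(result$ambiguous_constrained)) {
      w_con <- c(w_con, "ambiguous_match")
    }
  }
  if (!is.null(bu) && !is.null(bc) && !identical(bu$name_id, bc$name_id)) {
    w_un <- c(w_un, "better_higher_taxonomic_match_available")
    if (bu$scores$oms > bc$scores$oms && different_higher_taxon(bu, bc)) {
      w_con <- c(w_con, "better_spelling_match_in_different_higher_taxon")
    }
  }
  result$warnings_unconstrained <- unique(w_un)
  result$warnings_constrained <- unique(w_con)
  result
}

exact_candidate <- function(row, parsed_or_null) {
  list(
    name_id = row$name_id,
    reference = row,
    source_id = row$source_id,
    components = NULL,
    unmatched_components = character(0),
    is_partial = FALSE,
    query_author = "",
    reference_author = row$author,
    has_unmatched_text = FALSE,
    total_ed = 0L,
    passed_max_ed = TRUE, passed_phonetic = TRUE, passed_threshold = TRUE,
    retained = TRUE,
    scores = list(pms = NULL, snms = NA_real_, snms_tr = 1, ams = NA_real_,
                  oms = 1, k = NA_integer_)
  )
}

empty_result <- function(raw, id, parsed = NULL, pp = NULL) {
  structure(list(
    submitted = raw, submitted_id = id,
    preprocess = pp, parsed = parsed,
    best_unconstrained = NULL, best_constrained = NULL,
    alternatives = list(),
    ambiguous_unconstrained = FALSE, ambiguous_constrained = FALSE,
    warnings_unconstrained = character(0),
    warnings_constrained = character(0),
    warnings = character(0),
    accepted = NULL,
    status_of_match = "none",
    exact = FALSE
  ), class = "name_resolution")
}

resolve_one <- function(raw, id, db, params, settings) {
  res <- empty_result(raw, id)
  pp <- preprocess(raw, db,
                   source_ids = settings$source_order)
  res$preprocess <- pp

  if (settings$mode == "parse_only") {
    if (!pp$degenerate) {
      parsed <- parse_name(pp$cleaned)
      if (nzchar(pp$family_prefix) && !nzchar(parsed$family)) {
        parsed$family <- pp$family_prefix
      }
      parsed$annotations <- pp$removed_annotations
      res$parsed <- parsed
    }
    return(res)
  }

  # Exact verbatim hit: OMS 1.0, fuzzy matching skipped.
  if (!is.null(pp$exact_hit)) {
    hits <- pp$exact_hit
    cands <- lapply(seq_len(nrow(hits)), function(i) {
      exact_candidate(hits[i, , drop = FALSE])
    })
    res$exact <- TRUE
    res$alternatives <- cands
    best <- cands[[1]]
    res$best_unconstrained <- best
    res$best_constrained <- best
    if (length(cands) >= 2) {
      same_status <- hits$status[1] == hits$status[2]
      same_prio <- is.null(settings$source_order) ||
        identical(match(hits$source_id[1], settings$source_order),
                  match(hits$source_id[2], settings$source_order))
      amb <- same_status && same_prio
      res$ambiguous_unconstrained <- amb
      res$ambiguous_constrained <- amb
    }
    res <- assign_warnings(res)
    res <- finish_result(res, db, settings)
    return(res)
  }

  if (pp$degenerate && !nzchar(pp$family_prefix)) return(res)

  parsed <- if (pp$degenerate) {
    p <- empty_parsed(raw)
    p$family <- pp$family_prefix
    p$submitted_rank <- "family"
    p$parse_quality <- "salvage"
    p
  } else {
    parse_name(pp$cleaned)
  }
  if (nzchar(pp$family_prefix) && !nzchar(parsed$family)) {
    parsed$family <- pp$family_prefix
  }
  parsed$annotations <- pp$removed_annotations
  res$parsed <- parsed
  if (identical(parsed$parse_quality, "failed")) return(res)

  cands <- hierarchical_search(parsed, db, params)

  # Partial fallback to family rank: only when a family accompanied the
  # name and nothing at genus rank or deeper survived.
  if (!length(cands) && nzchar(parsed$family) && settings$allow_partial) {
    fam_parsed <- empty_parsed(raw)
    fam_parsed$family <- parsed$family
    fam_parsed$submitted_rank <- "family"
    fam_parsed$parse_quality <- parsed$parse_quality
    fam_cands <- hierarchical_search(fam_parsed, db, params)
    fam_cands <- lapply(fam_cands, function(candidate) {
      candidate$is_partial <- rank_depth(parsed$submitted_rank) > 0
      q_depth <- rank_depth(parsed$submitted_rank)
      if (q_depth >= 1) {
        ladder <- c("genus", "species", "infraspecies", "infraspecies2")
        candidate$unmatched_components <- ladder[seq_len(q_depth)]
      }
      candidate
    })
    cands <- fam_cands
  }

  if (!settings$allow_partial) {
    cands <- Filter(function(candidate) !candidate$is_partial, cands)
  }
  cands <- lapply(cands, score_candidate, params = params)
  if (settings$min_oms > 0) {
    cands <- Filter(function(candidate) {
      candidate$scores$oms >= settings$min_oms
    }, cands)
  }
  if (!length(cands)) return(res)

  family_submitted <- nzchar(parsed$family)
  un <- rank_unconstrained(cands)
  con <- rank_constrained(cands, family_submitted)
  source_order <- settings$source_order %||%
    db$sources$source_id[order(db$sources$priority)]
  if (settings$constrain_by_source) {
    un$cands <- rank_by_source(un$cands, source_order)
    con$cands <- rank_by_source(con$cands, source_order)
  }
  res$best_unconstrained <- un$cands[[1]]
  res$best_constrained <- con$cands[[1]]
  res$ambiguous_unconstrained <- un$ambiguous
  res$ambiguous_constrained <- con$ambiguous
  active <- if (settings$constrain_by_higher_taxonomy) con$cands else
    un$cands
  res$alternatives <- utils::head(active, settings$max_alternatives)
  res <- assign_warnings(res)
  finish_result(res, db, settings)
}

finish_result <- function(res, db, settings) {
  active_best <- if (settings$constrain_by_higher_taxonomy) {
    res$best_constrained
  } else {
    res$best_unconstrained
  }
  res$warnings <- if (settings$constrain_by_higher_taxonomy) {
    res$warnings_constrained
  } else {
    res$warnings_unconstrained
  }
  if (is.null(active_best)) {
    res$status_of_match <- "none"
    return(res)
  }
  res$status_of_match <- active_best$reference$status
  res$accepted <- tryCatch(resolve_accepted(db, active_best$name_id),
                           error = function(e) NULL)
  res
}

#' Resolve a batch of scientific names
#'
#' The full pipeline, applied independently to each submitted name:
#' pre-processing (with the exact-match shortcut), parsing, genus-first
#' fuzzy matching, scoring, candidate tests, ranking under both best-match
#' modes, warning assignment and synonym-to-accepted-name conversion.
#' Batch order never affects per-name results.
#'
#' @param queries a character vector of names, or a data.frame with columns
#'   `id` and `name`.
#' @param db a [taxon_db] reference store.
#' @param params a [scoring_params()] object.
#' @param settings a [run_settings()] object.
#' @return an object of class `resolution_set`: a list of `name_resolution`
#'   objects with a [as.data.frame.resolution_set()] method.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' tax <- generate_taxonomy(fixture_spec(n_species = 10, seed = 7), tsv)
#' db <- load_exchange_file(tsv, "demo")
#' res <- resolve_names(db$names$canonical[db$names$rank == "species"][1:2],
#'                      db)
#' as.data.frame(res)[, c("submitted_name", "matched_name", "overall_score")]
#' @export
resolve_names <- function(queries, db, params = scoring_params(),
                          settings = run_settings()) {
  stopifnot(inherits(db, "taxon_db"))
  if (is.data.frame(queries)) {
    ids <- as.character(queries$id)
    names_in <- as.character(queries$name)
  } else {
    ids <- rep(NA_character_, length(queries))
    names_in <- as.character(queries)
  }
  out <- vector("list", length(names_in))
  for (i in seq_along(names_in)) {
    out[[i]] <- resolve_one(names_in[i], ids[i], db, params, settings)
  }
  structure(list(results = out, settings = settings, params = params),
            class = "resolution_set")
}

best_of <- function(res, settings) {
  if (settings$constrain_by_higher_taxonomy) res$best_constrained
  else res$best_unconstrained
}

#' @export
print.name_resolution <- function(x, ...) {
  cat("<name_resolution> ", x$submitted, "\n", sep = "")
  best <- x$best_unconstrained
  if (is.null(best)) {
    cat("  no match\n")
  } else {
    cat(sprintf("  best: %s %s [OMS %.2f, %s]\n",
                best$reference$canonical, best$reference$author,
                best$scores$oms, x$status_of_match))
    if (length(x$warnings)) {
      cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
    }
  }
  invisible(x)
}

#' @export
print.resolution_set <- function(x, ...) {
  df <- as.data.frame(x)
  n <- nrow(df)
  matched <- sum(df$taxonomic_status != "none")
  cat("<resolution_set> ", n, " name(s): ", matched, " matched, ",
      sum(df$is_partial, na.rm = TRUE), " partial, ",
      sum(grepl("ambiguous_match", df$warnings)), " ambiguous, ",
      n - matched, " unmatched\n", sep = "")
  invisible(x)
}

#' Tabulate a resolution set
#'
#' One row per submitted name with the best match under the active ranking
#' mode: matched name and author, rank, the overall/name/author scores,
#' taxonomic status, the accepted name after synonym conversion, source,
#' warnings and the number of stored alternatives.
#'
#' @param x a [resolve_names()] result.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a data.frame.
#' @export
as.data.frame.resolution_set <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  settings <- x$settings
  rows <- lapply(x$results, function(res) {
    best <- best_of(res, settings)
    if (is.null(best)) {
      data.frame(
        submitted_id = res$submitted_id, submitted_name = res$submitted,
        matched_name = "", matched_author = "", match_rank = "",
        overall_score = NA_real_, name_score = NA_real_,
        author_score = NA_real_,
        taxonomic_status = "none", accepted_name = "", accepted_author = "",
        source = "", warnings = paste(res$warnings, collapse = ";"),
        is_partial = NA, alternatives_count = 0L,
        stringsAsFactors = FALSE
      )
    } else {
      acc <- res$accepted
      data.frame(
        submitted_id = res$submitted_id, submitted_name = res$submitted,
        matched_name = best$reference$canonical,
        matched_author = best$reference$author,
        match_rank = best$reference$rank,
        overall_score = round(best$scores$oms, 4),
        name_score = round(best$scores$snms_tr, 4),
        author_score = if (is.na(best$scores$ams)) NA_real_ else
          round(best$scores$ams, 4),
        taxonomic_status = res$status_of_match,
        accepted_name = if (is.null(acc)) "" else acc$canonical,
        accepted_author = if (is.null(acc)) "" else acc$author,
        source = best$source_id,
        warnings = paste(res$warnings, collapse = ";"),
        is_partial = isTRUE(best$is_partial),
        alternatives_count = length(res$alternatives),
        stringsAsFactors = FALSE
      )
    }
  })
  if (!length(rows)) {
    return(data.frame(
      submitted_id = character(0), submitted_name = character(0),
      matched_name = character(0), matched_author = character(0),
      match_rank = character(0), overall_score = numeric(0),
      name_score = numeric(0), author_score = numeric(0),
      taxonomic_status = character(0), accepted_name = character(0),
      accepted_author = character(0), source = character(0),
      warnings = character(0), is_partial = logical(0),
      alternatives_count = integer(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
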