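#' Read a query name file
#'
#' One name per line, UTF-8, optionally preceded by an integer ID and a
#' tab. Blank lines are skipped.
#'
#' @param path input file path.
#' @return data.frame with columns `id` and `name`.
#' @export
read_queries <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  has_id <- vapply(parts, function(p) {
    length(p) >= 2 && grepl("^\\s*[0-9]+\\s*$", p[1])
  }, logical(1))
  data.frame(
    id = ifelse(has_id, vapply(parts, `[`, character(1), 1),
                NA_character_),
    name = ifelse(has_id,
                  vapply(parts, function(p) paste(p[-1], collapse = " "),
                         character(1)),
                  trimws(lines)),
    stringsAsFactors = FALSE
  )
}

#' Read a configuration file
#'
#' A single YAML document with optional `scoring:` and `run:` sections
#' whose keys are the arguments of [scoring_params()] and
#' [run_settings()].
#'
#' @param path path to the YAML file.
#' @return list with elements `params` and `settings`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- do.call(scoring_params, cfg$scoring %||% list())
  settings <- do.call(run_settings, cfg$run %||% list())
  list(params = params, settings = settings)
}

settings_report <- function(settings, params, sources) {
  vals <- c(
    mode = settings$mode,
    min_oms = settings$min_oms,
    allow_partial = settings$allow_partial,
    constrain_by_higher_taxonomy = settings$constrain_by_higher_taxonomy,
    constrain_by_source = settings$constrain_by_source,
    source_order = paste(sources, collapse = ","),
    max_alternatives = settings$max_alternatives,
    s = params$s, t = params$t,
    name_weight = params$name_weight, author_weight = params$author_weight,
    wrong_rank_penalty = params$wrong_rank_penalty,
    unmatched_text_penalty = params$unmatched_text_penalty,
    maxedr_short = params$maxedr_short, maxedr_long = params$maxedr_long,
    msl_short_cutoff = params$msl_short_cutoff,
    max_ed_per_part = params$max_ed_per_part
  )
  paste0("# ", names(vals), ": ", unname(vals))
}

parse_only_table <- function(results) {
  rows <- lapply(results$results, function(res) {
    p <- res$parsed
    if (is.null(p)) p <- empty_parsed(res$submitted)
    data.frame(
      submitted_id = res$submitted_id, submitted_name = res$submitted,
      family = p$family, genus = p$genus,
      specific_epithet = p$specific_epithet,
      rank_indicator = p$rank_indicator,
      infraspecific_epithet = p$infraspecific_epithet,
      rank_indicator2 = p$rank_indicator2,
      infraspecific_epithet2 = p$infraspecific_epithet2,
      author = p$author, annotations = paste(p$annotations,
                                             collapse = ";"),
      unmatched_text = p$unmatched_text,
      submitted_rank = p$submitted_rank,
      parse_quality = p$parse_quality,
      is_hybrid = p$is_hybrid,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resolve a batch of names from files
#'
#' File-level wrapper around [resolve_names()]: loads one or more reference
#' exchange files (priorities follow their order), reads a query file, runs
#' the pipeline and writes an RFC-4180 CSV of best matches (or parsed
#' components in parse-only mode) preceded by a `#`-commented settings
#' report. Output is deterministic for fixed inputs and settings.
#'
#' @param input path to the query file (see [read_queries()]).
#' @param reference a [taxon_db], or a character vector of exchange-file
#'   paths loaded as sources `src1`, `src2`, ... in priority order.
#' @param settings a [run_settings()] object.
#' @param params a [scoring_params()] object.
#' @param output path for the CSV; `NULL` skips writing.
#' @return the results data.frame, invisibly; the full `resolution_set` is
#'   attached as attribute `"results"`.
#' @export
run_batch <- function(input, reference, settings = run_settings(),
                      params = scoring_params(),
                      output = settings$output_path) {
  if (inherits(reference, "taxon_db")) {
    db <- reference
  } else {
    db <- NULL
    for (i in seq_along(reference)) {
      db <- load_exchange_file(reference[i], source_id = paste0("src", i),
                               priority = i, db = db)
    }
  }
  queries <- read_queries(input)
  results <- resolve_names(queries, db, params, settings)
  df <- if (settings$mode == "parse_only") {
    parse_only_table(results)
  } else {
    as.data.frame(results)
  }
  if (!is.null(output)) {
    hdr <- settings_report(settings, params,
                           settings$source_order %||%
                             db$sources$source_id[order(db$sources$priority)])
    con <- file(output, open = "w", encoding = "UTF-8")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  attr(df, "results") <- results
  invisible(df)
}
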