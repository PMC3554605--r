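#' Default annotation vocabulary
#'
#' Tokens recognized (case-insensitively) as identification annotations and
#' removed before parsing: uncertainty markers (`cf.`, `aff.`, `?`),
#' indeterminate markers (`indet.`, `sp.`, `spp.`, with `nov.`/`nova`
#' following `sp.`), nomenclatural notes (`ined.`, `s.l.`, `s.s.`). The
#' vocabulary is config-extensible: pass your own vector to the cleaning
#' functions.
#'
#' @return character vector of annotation tokens.
#' @export
annotation_vocabulary <- function() {
  c("cf.", "cf", "aff.", "aff", "indet.", "indet", "sp.", "sp", "spp.",
    "spp", "ined.", "ined", "?", "s.l.", "s.s.")
}

#' Strip a pre-pended family name
#'
#' Field and legacy datasets often prefix species names with the family
#' ("Fabaceae Inga edulis"). The leading token is split off when it carries a
#' standard family ending (`-aceae`, `-idae`) or is one of the conserved
#' family names without the standard ending (Gramineae, Compositae, ...).
#' Matching is case-insensitive and the returned family is title-cased.
#'
#' @param raw a single name string.
#' @param conserved conserved-family list; extensible for other
#'   nomenclatural codes.
#' @return list with elements `family` (possibly `""`) and `remainder`.
#' @examples
#' strip_family("Fabaceae Indet. sp. 21")
#' @export
strip_family <- function(raw, conserved = CONSERVED_FAMILIES) {
  x <- squish(raw)
  if (!nzchar(x)) return(list(family = "", remainder = ""))
  toks <- strsplit(x, " ", fixed = TRUE)[[1]]
  if (is_family_token(toks[1], conserved)) {
    list(family = title_case(toks[1]),
         remainder = paste(toks[-1], collapse = " "))
  } else {
    list(family = "", remainder = x)
  }
}

is_morpho_code <- function(tok) {
  # digits, single letters, or short alphanumeric codes ("21", "A", "3a")
  grepl("^[0-9]+[a-z]?$", tok, ignore.case = TRUE) ||
    grepl("^[A-Za-z]$", tok) ||
    grepl("^[A-Za-z0-9-]{2,8}$", tok) && grepl("[0-9]", tok)
}

is_accession_code <- function(tok) {
  # trailing all-caps/alphanumeric codes with at least one digit ("AB123")
  nchar(tok) >= 2L && grepl("[0-9]", tok) &&
    grepl("^[A-Z0-9_-]+$", tok)
}

#' Remove identification annotations and morphospecies codes
#'
#' Scans the token stream for annotation vocabulary (case-insensitive),
#' morphospecies codes following `sp.`/`spp.` (digits, single letters, short
#' alphanumeric codes, `nov.`, `nova`), embedded question marks, and
#' trailing accession-style codes (two or more characters containing a
#' digit). Removed tokens are recorded in order.
#'
#' @param raw a single name string.
#' @param vocabulary annotation token list, see [annotation_vocabulary()].
#' @return list with elements `cleaned` and `removed` (character vector).
#' @examples
#' remove_annotations("Poa cf. annua")
#' remove_annotations("Fabaceae sp. 21")
#' @export
remove_annotations <- function(raw, vocabulary = annotation_vocabulary()) {
  x <- squish(raw)
  if (!nzchar(x)) return(list(cleaned = "", removed = character(0)))
  # embedded question marks attached to tokens
  removed <- character(0)
  if (grepl("\\?", x)) {
    nq <- lengths(regmatches(x, gregexpr("\\?", x)))
    removed <- c(removed, rep("?", nq))
    x <- squish(gsub("\\?", " ", x))
    if (!nzchar(x)) return(list(cleaned = "", removed = removed))
  }
  toks <- strsplit(x, " ", fixed = TRUE)[[1]]
  keep <- rep(TRUE, length(toks))
  vocab <- tolower(vocabulary)
  after_sp <- FALSE
  for (i in seq_along(toks)) {
    low <- tolower(toks[i])
    if (low %in% vocab) {
      keep[i] <- FALSE
      removed <- c(removed, toks[i])
      after_sp <- low %in% c("sp.", "sp", "spp.", "spp")
      next
    }
    if (after_sp && (is_morpho_code(toks[i]) ||
                     low %in% c("nov.", "nov", "nova"))) {
      keep[i] <- FALSE
      removed <- c(removed, toks[i])
      next
    }
    after_sp <- FALSE
  }
  # trailing accession-style codes
  j <- length(toks)
  while (j >= 1L && keep[j] && is_accession_code(toks[j])) {
    keep[j] <- FALSE
    removed <- c(removed, toks[j])
    j <- j - 1L
  }
  list(cleaned = paste(toks[keep], collapse = " "), removed = removed)
}

#' Adjust the case of an all-capitals name
#'
#' Name parsing is case sensitive, so names submitted in all capital letters
#' ("QUERCUS ALBA") are rewritten by capitalizing the first letter and
#' lower-casing the rest. Mixed-case input is returned unchanged.
#'
#' @param raw a single name string.
#' @return the adjusted string.
#' @export
normalize_case <- function(raw) {
  x <- as.character(raw)
  if (grepl("[A-Za-z]", x) && identical(toupper(x), x)) {
    title_case(x)
  } else {
    x
  }
}

#' Clean a submitted name and short-circuit perfect matches
#'
#' The full pre-processing pipeline applied to each submitted string before
#' parsing and fuzzy matching: underscores become spaces (phylogeny tip
#' labels), a pre-pended family is stripped, annotations and morphospecies
#' codes are removed, all-caps input is case-adjusted, and the cleaned
#' string is looked up verbatim in the reference store. A complete match
#' skips fuzzy matching entirely and carries an overall match score of 1.0.
#'
#' @param raw a single name string.
#' @param db optional [taxon_db] store for the exact-match shortcut.
#' @param source_ids optional source filter/priority order for the lookup.
#' @param vocabulary annotation vocabulary.
#' @return an object of class `preprocess_result`: list with `family_prefix`,
#'   `cleaned`, `removed_annotations`, `was_all_caps`, `degenerate` (nothing
#'   left to match) and `exact_hit` (a reference record row or `NULL`).
#' @examples
#' preprocess("FABACEAE CF. INGA EDULIS")
#' @export
preprocess <- function(raw, db = NULL, source_ids = NULL,
                       vocabulary = annotation_vocabulary()) {
  x <- squish(gsub("_", " ", as.character(raw)))
  fam <- strip_family(x)
  ann <- remove_annotations(fam$remainder, vocabulary)
  was_caps <- grepl("[A-Za-z]", ann$cleaned) &&
    identical(toupper(ann$cleaned), ann$cleaned)
  cleaned <- normalize_case(ann$cleaned)
  degenerate <- !nzchar(cleaned)

  exact_hit <- NULL
  if (!degenerate && !is.null(db)) {
    hits <- exact_lookup_full(db, cleaned, source_ids)
    if (nrow(hits) && nzchar(fam$family)) {
      # a submitted family disambiguates exact homonym hits
      byfam <- hits[tolower(hits$family) == tolower(fam$family), ,
                    drop = FALSE]
      if (nrow(byfam)) hits <- byfam
    }
    if (nrow(hits)) exact_hit <- hits
  }
  structure(list(
    family_prefix = fam$family,
    cleaned = cleaned,
    removed_annotations = ann$removed,
    was_all_caps = was_caps,
    degenerate = degenerate,
    exact_hit = exact_hit
  ), class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("<preprocess_result>\n")
  cat("  cleaned: ", x$cleaned, "\n", sep = "")
  if (nzchar(x$family_prefix)) {
    cat("  family prefix: ", x$family_prefix, "\n", sep = "")
  }
  if (length(x$removed_annotations)) {
    cat("  removed: ", paste(x$removed_annotations, collapse = " "), "\n",
        sep = "")
  }
  if (!is.null(x$exact_hit)) cat("  exact hit (OMS 1.0)\n")
  invisible(x)
}
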