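# Recognized infraspecific rank indicator spellings, standardized.
RANK_INDICATOR_MAP <- c(
  "var"     = "var.",   "var."    = "var.",
  "subsp"   = "subsp.", "subsp."  = "subsp.",
  "ssp"     = "subsp.", "ssp."    = "subsp.",
  "fo"      = "fo.",    "fo."     = "fo.",
  "f"       = "fo.",    "f."      = "fo.",
  "subvar"  = "subvar.", "subvar." = "subvar.",
  "subf"    = "subfo.", "subf."   = "subfo.", "subfo." = "subfo."
)

#' Standardize an infraspecific rank indicator
#'
#' Maps the variant spellings of rank indicators onto one standard form:
#' `"ssp"`, `"ssp."` and `"subsp"` become `"subsp."`; `"f."` and `"fo"`
#' become `"fo."`; `"var"` becomes `"var."`. Unrecognized tokens are
#' returned unchanged.
#'
#' @param x character vector of rank indicator tokens.
#' @return character vector of standardized indicators.
#' @export
standardize_rank_indicator <- function(x) {
  m <- RANK_INDICATOR_MAP[tolower(as.character(x))]
  out <- ifelse(is.na(m), as.character(x), m)
  unname(out)
}

is_rank_indicator <- function(tok) !is.na(RANK_INDICATOR_MAP[tolower(tok)])

CONSERVED_FAMILIES <- c("Gramineae", "Compositae", "Leguminosae", "Cruciferae",
                        "Umbelliferae", "Labiatae", "Palmae", "Guttiferae")

title_case <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), tolower(substring(x, 2L)))
}

is_family_token <- function(tok, conserved = CONSERVED_FAMILIES) {
  low <- tolower(tok)
  grepl("^[A-Za-z-]+$", tok) &
    (endsWith(low, "aceae") | endsWith(low, "idae") |
       low %in% tolower(conserved))
}

# Genus-like token: capitalized latin word. Returns "strict", "relaxed"
# (diacritics tolerated) or NA.
genus_likeness <- function(tok) {
  if (grepl("^[A-Z][a-z-]+$", tok)) return("strict")
  f <- fold_diacritics(tok)
  if (grepl("^[A-Z][a-z-]+$", f)) return("relaxed")
  NA_character_
}

epithet_likeness <- function(tok) {
  if (grepl("^[a-z][a-z-]+$", tok)) return("strict")
  f <- fold_diacritics(tok)
  if (grepl("^[a-z][a-z-]+$", f)) return("relaxed")
  NA_character_
}

empty_parsed <- function(raw = "") {
  structure(list(
    raw = raw,
    family = "", genus = "", specific_epithet = "",
    rank_indicator = "", infraspecific_epithet = "",
    rank_indicator2 = "", infraspecific_epithet2 = "",
    author = "", basionym_author = "", combining_author = "",
    annotations = character(0),
    unmatched_text = "",
    is_hybrid = FALSE,
    submitted_rank = "none",
    parse_quality = "failed"
  ), class = "parsed_name")
}

#' Atomize a scientific name string
#'
#' Splits a (pre-cleaned) scientific name into genus, specific and
#' infraspecific epithets, standardized rank indicators, and authorship,
#' using the casing conventions of botanical names: the genus is the leading
#' capitalized word, epithets are lower-case, a parenthesized author is the
#' basionym author and trailing name-cased tokens are the combining author.
#' Parsing is case sensitive; tokens that fit no slot are preserved in
#' `unmatched_text`. Hybrid markers (`×` or a free-standing `x`) set
#' `is_hybrid` and only the leading parent name is atomized.
#'
#' `parse_quality` records how much tolerance was needed: `"strict"` (clean
#' input), `"relaxed"` (diacritics, doubled parentheses or bracketed years
#' tolerated), `"salvage"` (a leading canonical name was extracted and the
#' rest set aside) or `"failed"` (no genus or family could be identified; the
#' whole input is in `unmatched_text`).
#'
#' @param raw a single name string.
#' @return an object of class `parsed_name`; see Details for fields.
#' @examples
#' p <- parse_name("Bromus inermis var. confinis (Nees ex Steud.) Stapf")
#' p$genus; p$infraspecific_epithet; p$combining_author
#' @export
parse_name <- function(raw) {
  stopifnot(length(raw) == 1L)
  out <- empty_parsed(raw)
  x <- squish(raw)
  if (!nzchar(x)) {
    return(out)
  }

  relaxed <- FALSE
  salvage <- FALSE

  # Hybrid markers: leading marker is stripped; an internal marker truncates
  # to the leading parent name.
  if (grepl("×", x) || grepl("\\s[xX]\\s", x)) {
    lead <- sub("^\\s*×\\s*", "", x)
    if (!identical(lead, x)) {
      out$is_hybrid <- TRUE
      relaxed <- TRUE
      x <- lead
    }
    pieces <- strsplit(x, "\\s*×\\s*|\\s[xX]\\s")[[1]]
    if (length(pieces) > 1L) {
      out$is_hybrid <- TRUE
      salvage <- TRUE
      dropped <- sub(paste0("^\\Q", pieces[1], "\\E"), "", x)
      out$unmatched_text <- squish(dropped)
      x <- squish(pieces[1])
    }
  }

  toks <- strsplit(x, " ", fixed = TRUE)[[1]]
  n <- length(toks)
  unmatched <- character(0)
  i <- 1L

  if (i <= n && is_family_token(toks[i]) && !is.na(genus_likeness(toks[i]))) {
    out$family <- title_case(toks[i])
    i <- i + 1L
  }

  if (i <= n) {
    gl <- genus_likeness(toks[i])
    if (!is.na(gl) && !is_family_token(toks[i])) {
      out$genus <- toks[i]
      if (gl == "relaxed") relaxed <- TRUE
      i <- i + 1L
    }
  }

  if (!nzchar(out$genus) && !nzchar(out$family)) {
    out$unmatched_text <- x
    out$parse_quality <- "failed"
    out$submitted_rank <- "none"
    return(out)
  }

  # Name region: epithets and rank indicators.
  pending_rank <- ""
  author_start <- NA_integer_
  if (nzchar(out$genus)) {
    while (i <= n) {
      tok <- toks[i]
      if (is_rank_indicator(tok)) {
        if (nzchar(pending_rank)) unmatched <- c(unmatched, pending_rank)
        pending_rank <- standardize_rank_indicator(tok)
        i <- i + 1L
        next
      }
      el <- epithet_likeness(tok)
      if (!is.na(el)) {
        if (el == "relaxed") relaxed <- TRUE
        if (!nzchar(out$specific_epithet)) {
          out$specific_epithet <- tok
          if (nzchar(pending_rank)) unmatched <- c(unmatched, pending_rank)
        } else if (!nzchar(out$infraspecific_epithet)) {
          out$infraspecific_epithet <- tok
          out$rank_indicator <- pending_rank
        } else if (nzchar(pending_rank) &&
                   !nzchar(out$infraspecific_epithet2)) {
          out$infraspecific_epithet2 <- tok
          out$rank_indicator2 <- pending_rank
        } else {
          unmatched <- c(unmatched, if (nzchar(pending_rank)) pending_rank,
                         tok)
        }
        pending_rank <- ""
        i <- i + 1L
        next
      }
      author_start <- i
      break
    }
    if (nzchar(pending_rank)) unmatched <- c(unmatched, pending_rank)
  } else {
    # Family-only name: remaining tokens may still carry an author.
    if (i <= n) author_start <- i
  }

  if (!is.na(author_start)) {
    astr <- paste(toks[author_start:n], collapse = " ")
    if (grepl("\\[", astr)) relaxed <- TRUE
    if (startsWith(astr, "(")) {
      if (startsWith(astr, "((")) relaxed <- TRUE
      m <- regmatches(astr, regexec("^\\(+([^()]*)\\)+\\s*(.*)$", astr))[[1]]
      if (length(m) == 3L) {
        out$basionym_author <- trimws(m[2])
        out$combining_author <- trimws(m[3])
        out$author <- if (nzchar(out$combining_author)) {
          paste0("(", out$basionym_author, ") ", out$combining_author)
        } else {
          paste0("(", out$basionym_author, ")")
        }
      } else {
        # Unbalanced parentheses: keep the raw string as the author.
        relaxed <- TRUE
        out$author <- astr
      }
    } else {
      out$author <- astr
    }
  }

  if (length(unmatched)) {
    out$unmatched_text <- squish(paste(c(out$unmatched_text, unmatched),
                                       collapse = " "))
  }
  if (nzchar(out$unmatched_text)) salvage <- TRUE

  out$submitted_rank <- parsed_rank(out)
  out$parse_quality <- if (salvage) "salvage" else if (relaxed) "relaxed"
                       else "strict"
  out
}

parsed_rank <- function(p) {
  if (!nzchar(p$genus)) {
    if (nzchar(p$family)) "family" else "none"
  } else if (!nzchar(p$specific_epithet)) {
    "genus"
  } else if (!nzchar(p$infraspecific_epithet)) {
    "species"
  } else if (!nzchar(p$infraspecific_epithet2)) {
    "infraspecies"
  } else {
    "infraspecies2"
  }
}

#' Overall taxonomic rank of a parsed name
#'
#' The deepest rank for which an epithet is present: `"family"`, `"genus"`,
#' `"species"`, `"infraspecies"` (trinomial) or `"infraspecies2"`
#' (quadrinomial).
#'
#' @param parsed a [parse_name()] result.
#' @return a rank string.
#' @export
rank_of <- function(parsed) {
  stopifnot(inherits(parsed, "parsed_name"))
  parsed_rank(parsed)
}

#' Canonical form of a parsed name
#'
#' Genus plus epithets with standardized rank indicators, single-spaced, no
#' authorship. For a family-rank parse the family name is returned.
#'
#' @param parsed a [parse_name()] result with `parse_quality != "failed"`.
#' @return a single string.
#' @export
canonical_name <- function(parsed) {
  stopifnot(inherits(parsed, "parsed_name"))
  if (identical(parsed$parse_quality, "failed")) {
    stop("cannot build a canonical form from a failed parse")
  }
  if (!nzchar(parsed$genus)) return(parsed$family)
  parts <- c(parsed$genus,
             if (nzchar(parsed$specific_epithet)) parsed$specific_epithet,
             if (nzchar(parsed$infraspecific_epithet))
               c(if (nzchar(parsed$rank_indicator)) parsed$rank_indicator,
                 parsed$infraspecific_epithet),
             if (nzchar(parsed$infraspecific_epithet2))
               c(if (nzchar(parsed$rank_indicator2)) parsed$rank_indicator2,
                 parsed$infraspecific_epithet2))
  paste(parts, collapse = " ")
}

#' @export
print.parsed_name <- function(x, ...) {
  cat("<parsed_name>", if (nzchar(x$raw)) x$raw else "(empty)", "\n")
  cat("  rank:", x$submitted_rank, " quality:", x$parse_quality,
      if (x$is_hybrid) " [hybrid]" else "", "\n", sep = "")
  show <- c("family", "genus", "specific_epithet", "rank_indicator",
            "infraspecific_epithet", "rank_indicator2",
            "infraspecific_epithet2", "author", "unmatched_text")
  for (f in show) {
    if (nzchar(x[[f]])) cat("  ", f, ": ", x[[f]], "\n", sep = "")
  }
  invisible(x)
}
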