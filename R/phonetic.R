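# Diacritic folding used before phonetic keying and in the ASCII pass of
# author comparison. Multi-character ligatures first, then 1:1 via chartr,
# then iconv transliteration as a backstop; anything still non-ASCII is
# dropped.
DIACRITIC_MAP <- c(
  "á" = "a", "à" = "a", "â" = "a", "ä" = "a",
  "ã" = "a", "å" = "a", "ç" = "c",
  "é" = "e", "è" = "e", "ê" = "e", "ë" = "e",
  "í" = "i", "ì" = "i", "î" = "i", "ï" = "i",
  "ñ" = "n", "ó" = "o", "ò" = "o", "ô" = "o",
  "ö" = "o", "õ" = "o", "ø" = "o",
  "ú" = "u", "ù" = "u", "û" = "u", "ü" = "u",
  "ý" = "y", "ÿ" = "y",
  "š" = "s", "ž" = "z", "ć" = "c", "č" = "c",
  "đ" = "d", "ł" = "l",
  "ß" = "ss", "œ" = "oe", "æ" = "ae"
)

fold_diacritics <- function(x) {
  x <- as.character(x)
  for (i in seq_along(DIACRITIC_MAP)) {
    pat <- names(DIACRITIC_MAP)[i]
    x <- gsub(pat, DIACRITIC_MAP[[i]], x, fixed = TRUE)
    x <- gsub(toupper(pat), toupper(DIACRITIC_MAP[[i]]), x, fixed = TRUE)
  }
  y <- suppressWarnings(iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT"))
  x <- ifelse(is.na(y), x, y)
  gsub("[^\x01-\x7f]", "", x, useBytes = TRUE)
}

#' Stem a species or infraspecific epithet
#'
#' Latin epithets vary their ending with the gender of the genus. Stemming
#' equates the endings `-is`, `-us`, `-ys`, `-es`, `-um`, `-as` and `-os`
#' with `-a` by rewriting them all to `-a`, so that e.g. `"nitidus"`,
#' `"nitidum"` and `"nitida"` share one stemmed form. Exactly one trailing
#' ending is replaced; strings without a listed ending (or too short to
#' leave a two-letter stem) are returned unchanged. The function is
#' idempotent.
#'
#' @param x character vector of lower-case epithets.
#' @return character vector of stemmed epithets.
#' @examples
#' stem_epithet(c("nitidus", "nitidum", "nitida", "repens"))
#' @export
stem_epithet <- function(x) {
  x <- as.character(x)
  ends <- c("is", "us", "ys", "es", "um", "as", "os")
  vapply(x, function(w) {
    n <- nchar(w)
    if (is.na(w) || n < 4L) return(w)
    for (e in ends) {
      if (endsWith(w, e)) return(paste0(substr(w, 1L, n - 2L), "a"))
    }
    w
  }, character(1), USE.NAMES = FALSE)
}

#' Phonetic substitution table
#'
#' The ordered substitution rules applied by [phonetic_key()]. Each row has a
#' `pattern`, a `replacement` and a `scope`: `"initial"` (applies only at the
#' start of the string), `"noninitial"` (everywhere except across the first
#' character) or `"any"`. The default table encodes the usual lexical
#' conventions of latinized names: ae/oe monophthongs, ph/th/ch spellings,
#' y-for-i, k-for-c, and the Mc/Mac, X-/Z- and silent-initial ps/pt/ts
#' conventions. A custom table can be supplied as a tab-separated file with
#' columns `pattern`, `replacement`, `scope`.
#'
#' @param path optional path to a tab-separated substitution file; `NULL`
#'   returns the built-in table.
#' @return data.frame with columns `pattern`, `replacement`, `scope`.
#' @export
phonetic_table <- function(path = NULL) {
  if (!is.null(path)) {
    tab <- utils::read.delim(path, sep = "\t", colClasses = "character",
                             stringsAsFactors = FALSE)
    need <- c("pattern", "replacement", "scope")
    if (!all(need %in% names(tab))) {
      stop("phonetic table must have columns pattern, replacement, scope")
    }
    return(tab[need])
  }
  data.frame(
    pattern = c("mc", "x", "ps", "pt", "ts",
                "ae", "oe", "ph", "th", "sz", "ch", "y", "k"),
    replacement = c("mac", "z", "s", "t", "s",
                    "e", "e", "f", "t", "s", "c", "i", "c"),
    scope = c("initial", "initial", "initial", "initial", "initial",
              "any", "any", "any", "any", "any", "noninitial", "any", "any"),
    stringsAsFactors = FALSE
  )
}

apply_phonetic_table <- function(x, table) {
  for (r in seq_len(nrow(table))) {
    pat <- table$pattern[r]
    rep <- table$replacement[r]
    scope <- table$scope[r]
    if (scope == "initial") {
      hit <- startsWith(x, pat)
      x[hit] <- paste0(rep, substring(x[hit], nchar(pat) + 1L))
    } else if (scope == "noninitial") {
      x <- paste0(substr(x, 1L, 1L),
                  gsub(pat, rep, substring(x, 2L), fixed = TRUE))
    } else {
      x <- gsub(pat, rep, x, fixed = TRUE)
    }
  }
  x
}

#' Phonetic key of a name component
#'
#' Deterministic normalization that maps a name component to a simplified
#' phonetic equivalent: lower-casing, diacritic folding, removal of
#' non-letters, optional epithet stemming (see [stem_epithet()]), the ordered
#' substitutions of [phonetic_table()], and collapsing of doubled letters.
#' Two components "phonetically match" when their keys are identical, which
#' makes phonetic matching an exact lookup on precomputed keys.
#'
#' @param x character vector of name components.
#' @param epithet logical; apply epithet stemming first (use `TRUE` for
#'   specific and infraspecific epithets, `FALSE` for genus and family
#'   names).
#' @param table substitution table, see [phonetic_table()].
#' @return character vector of phonetic keys.
#' @examples
#' phonetic_key("Zygophyllum") == phonetic_key("Zigofillum")
#' phonetic_key("nitidus", epithet = TRUE) == phonetic_key("nitida", epithet = TRUE)
#' @export
phonetic_key <- function(x, epithet = FALSE, table = phonetic_table()) {
  x <- tolower(trimws(as.character(x)))
  x <- fold_diacritics(x)
  x <- gsub("[^a-z]", "", x)
  if (epithet) x <- stem_epithet(x)
  x <- apply_phonetic_table(x, table)
  gsub("([a-z])\\1+", "\\1", x)
}
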