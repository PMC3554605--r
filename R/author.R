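# Cache for the built-in abbreviation dictionary.
.taxresolve_env <- new.env(parent = emptyenv())

#' Botanical author abbreviation dictionary
#'
#' Named character vector mapping standard author abbreviations (as written,
#' including trailing periods) to expanded surnames. The built-in dictionary
#' ships a sample of common botanical authors; a custom dictionary can be
#' supplied as a tab-separated file with two columns, `abbreviation` and
#' `expansion`.
#'
#' @param path optional path to a tab-separated dictionary file; `NULL`
#'   returns the built-in dictionary.
#' @return named character vector (names are abbreviations).
#' @export
author_abbreviations <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.taxresolve_env$abbrev)) {
      builtin <- system.file("extdata", "author_abbreviations.txt",
                             package = "taxresolve")
      .taxresolve_env$abbrev <- read_abbrev_file(builtin)
    }
    return(.taxresolve_env$abbrev)
  }
  read_abbrev_file(path)
}

read_abbrev_file <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = FALSE, comment.char = "#",
                           colClasses = "character", stringsAsFactors = FALSE)
  stats::setNames(trimws(tab[[2]]), trimws(tab[[1]]))
}

# Token-wise expansion of known abbreviations (case-sensitive, matched with
# the trailing period).
expand_author_abbreviations <- function(x, dict = author_abbreviations()) {
  vapply(as.character(x), function(s) {
    if (!nzchar(s)) return(s)
    toks <- strsplit(squish(s), " ", fixed = TRUE)[[1]]
    hit <- match(toks, names(dict))
    toks[!is.na(hit)] <- unname(dict[hit[!is.na(hit)]])
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Lower-case, strip punctuation, collapse whitespace. Initials survive as
# bare letters ("M." -> "m").
normalize_author <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[.,;:()&]", " ", x)
  squish(x)
}

# Character n-grams of a string, no boundary padding.
char_ngrams <- function(x, n) {
  L <- nchar(x)
  if (L < n) return(character(0))
  starts <- seq_len(L - n + 1L)
  substring(x, starts, starts + n - 1L)
}

# Dice coefficient on n-gram multisets.
dice_ngram <- function(a, b, n) {
  ga <- char_ngrams(a, n)
  gb <- char_ngrams(b, n)
  if (length(ga) == 0L && length(gb) == 0L) return(1)
  if (length(ga) == 0L || length(gb) == 0L) return(0)
  ta <- table(ga)
  tb <- table(gb)
  common <- intersect(names(ta), names(tb))
  shared <- sum(pmin(ta[common], tb[common]))
  2 * shared / (length(ga) + length(gb))
}

#' Blended bigram/trigram string similarity
#'
#' Dice-style n-gram overlap, blended as 2/3 bigram + 1/3 trigram
#' similarity. This is the single-pass primitive behind
#' [author_similarity()].
#'
#' @param a,b single strings (already normalized).
#' @return similarity in \eqn{[0, 1]}.
#' @export
ngram_similarity <- function(a, b) {
  2 / 3 * dice_ngram(a, b, 2L) + 1 / 3 * dice_ngram(a, b, 3L)
}

#' Author string similarity (AMS)
#'
#' Authorship strings vary in spelling, abbreviation and diacritics, so they
#' are compared with a relaxed n-gram measure rather than edit distance.
#' Known abbreviations are first expanded from `abbreviations`; the blended
#' 2/3-bigram + 1/3-trigram similarity is then computed twice, once on the
#' original (UTF-8) normalized strings and once on diacritic-folded ASCII
#' versions, and the author match score (AMS) is the unweighted mean of the
#' two passes. Averaging scores variants such as `"Guédès"` vs `"Guedes"` as
#' similar but not identical.
#'
#' @param a,b author strings; empty strings are allowed.
#' @param abbreviations named character vector, see [author_abbreviations()].
#' @return an object of class `author_score`: a list with elements `ams`
#'   (mean of the two passes, or `NA` when both strings are empty — no
#'   author comparison), `utf8_similarity` and `ascii_similarity`.
#' @examples
#' author_similarity("L.", "Linnaeus")$ams # 1
#' @export
author_similarity <- function(a, b, abbreviations = author_abbreviations()) {
  a <- if (length(a) == 0L || is.na(a)) "" else as.character(a)
  b <- if (length(b) == 0L || is.na(b)) "" else as.character(b)
  if (!nzchar(trimws(a)) && !nzchar(trimws(b))) {
    out <- list(ams = NA_real_, utf8_similarity = NA_real_,
                ascii_similarity = NA_real_)
    class(out) <- "author_score"
    return(out)
  }
  ea <- normalize_author(expand_author_abbreviations(a, abbreviations))
  eb <- normalize_author(expand_author_abbreviations(b, abbreviations))
  utf8 <- ngram_similarity(ea, eb)
  ascii <- ngram_similarity(fold_diacritics(ea), fold_diacritics(eb))
  out <- list(ams = (utf8 + ascii) / 2,
              utf8_similarity = utf8,
              ascii_similarity = ascii)
  class(out) <- "author_score"
  out
}

#' @export
print.author_score <- function(x, ...) {
  if (is.na(x$ams)) {
    cat("<author_score> no author comparison\n")
  } else {
    cat(sprintf("<author_score> AMS %.3f (utf8 %.3f, ascii %.3f)\n",
                x$ams, x$utf8_similarity, x$ascii_similarity))
  }
  invisible(x)
}
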