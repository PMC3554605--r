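recycle_pair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  list(a = rep_len(a, n), b = rep_len(b, n))
}

#' Modified Damerau-Levenshtein distance with block transpositions
#'
#' Edit distance between two name components allowing single-character
#' insertion, deletion and substitution (cost 1), transposition of two
#' adjacent characters (cost 1), and transposition of two adjacent blocks of
#' up to `max_block` characters each, at a cost equal to the length of the
#' longer block. The block move is what lets transposed syllables such as
#' `"vecusilosus"` / `"vesiculosus"` score 2 instead of the 4 substitutions
#' that a plain Damerau-Levenshtein alignment would charge. Comparison is
#' case-insensitive.
#'
#' @param a,b character vectors of name components, recycled to a common
#'   length.
#' @param max_block maximum block length considered for a block
#'   transposition. The default 4 covers transposed syllables while keeping
#'   pathological long-range rearrangements expensive.
#' @return integer vector of edit distances.
#' @examples
#' mdld("vecusilosus", "vesiculosus") # 2
#' mdld("Nais", "Nias")               # 1
#' mdld("Ficus", "Fucus")             # 1
#' @seealso [classic_dl()] for the distance without block moves.
#' @export
mdld <- function(a, b, max_block = 4L) {
  p <- recycle_pair(a, b)
  mdld_cpp(tolower(p$a), tolower(p$b), as.integer(max_block)[1])
}

#' Damerau-Levenshtein distance (optimal string alignment)
#'
#' Unit-cost insertion, deletion, substitution and adjacent single-character
#' transposition, without the multi-character block moves of [mdld()]. Used
#' internally as an upper bound on [mdld()] and in property tests.
#'
#' @inheritParams mdld
#' @return integer vector of edit distances.
#' @examples
#' classic_dl("vecusilosus", "vesiculosus") # 4
#' classic_dl("Nais", "Nias")               # 1
#' @export
classic_dl <- function(a, b) {
  p <- recycle_pair(a, b)
  osa_distance_cpp(tolower(p$a), tolower(p$b))
}
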