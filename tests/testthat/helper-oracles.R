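# Independent oracles used by the property tests. These deliberately avoid
# the package's C++ dynamic-programming code paths.

# Damerau-Levenshtein with adjacent transpositions (optimal string
# alignment), as a memoized suffix recursion over the two strings.
osa_oracle <- function(a, b) {
  a <- tolower(a)
  b <- tolower(b)
  memo <- new.env(parent = emptyenv())
  rec <- function(x, y) {
    if (!nzchar(x)) return(nchar(y))
    if (!nzchar(y)) return(nchar(x))
    # values below stay integer: every branch adds 1L to an integer

    key <- paste(x, y, sep = "\r")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    x1 <- substr(x, 1, 1)
    y1 <- substr(y, 1, 1)
    if (x1 == y1) {
      v <- rec(substring(x, 2), substring(y, 2))
    } else {
      v <- min(1L + rec(substring(x, 2), y),        # delete
               1L + rec(x, substring(y, 2)),        # insert
               1L + rec(substring(x, 2), substring(y, 2)))  # substitute
      if (nchar(x) >= 2 && nchar(y) >= 2 &&
          x1 == substr(y, 2, 2) && substr(x, 2, 2) == y1) {
        v <- min(v, 1L + rec(substring(x, 3), substring(y, 3)))
      }
    }
    memo[[key]] <- v
    v
  }
  rec(a, b)
}

# All strings of length 1..max_len over a small alphabet.
all_strings <- function(alphabet, max_len) {
  out <- alphabet
  prev <- alphabet
  for (len in seq_len(max_len - 1)) {
    prev <- as.vector(outer(prev, alphabet, paste0))
    out <- c(out, prev)
  }
  out
}

# Brute-force transitive closure of the parent pointers.
closure_descendants <- function(records, id) {
  kids <- split(records$taxonID, records$parentNameUsageID)
  out <- character(0)
  frontier <- id
  while (length(frontier)) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

# Whole-database candidate filter: every reference record at the submitted
# rank or shallower is pushed through the per-component tests and the
# retention rule, with no genus-first staging.
brute_force_candidates <- function(parsed, db, params = scoring_params()) {
  nm <- db$names
  allowed <- NULL
  if (nzchar(parsed$family)) {
    fam <- nm[nm$rank == "family", , drop = FALSE]
    fkey <- phonetic_key(parsed$family)
    ok <- vapply(seq_len(nrow(fam)), function(i) {
      ed <- mdld(parsed$family, fam$canonical[i])
      msl <- min(nchar(parsed$family), nchar(fam$canonical[i]))
      fkey == fam$family_key[i] || ed <= params$genus_ed_budget ||
        threshold_test(ed, msl, parsed$family, fam$canonical[i], params)
    }, logical(1))
    if (any(ok)) allowed <- fam$canonical[ok]
  }
  q_depth <- taxresolve:::rank_depth(parsed$submitted_rank)

  if (q_depth == 0) {
    if (is.null(allowed)) return(character(0))
    fam <- nm[nm$rank == "family" & nm$canonical %in% allowed, ,
              drop = FALSE]
    keep <- vapply(seq_len(nrow(fam)), function(i) {
      ed <- mdld(parsed$family, fam$canonical[i])
      msl <- min(nchar(parsed$family), nchar(fam$canonical[i]))
      phon <- phonetic_key(parsed$family) == fam$family_key[i]
      thr <- threshold_test(ed, msl, parsed$family, fam$canonical[i],
                            params)
      max_ed_test(ed, 1, params) && (phon || thr)
    }, logical(1))
    return(sort(fam$name_id[keep]))
  }

  gkey <- phonetic_key(parsed$genus)
  ekey <- if (nzchar(parsed$specific_epithet)) {
    phonetic_key(parsed$specific_epithet, epithet = TRUE)
  } else ""
  ikey <- if (nzchar(parsed$infraspecific_epithet)) {
    phonetic_key(parsed$infraspecific_epithet, epithet = TRUE)
  } else ""

  ids <- character(0)
  for (i in seq_len(nrow(nm))) {
    row <- nm[i, , drop = FALSE]
    if (row$rank == "family") next
    if (!is.null(allowed) && !(row$family %in% allowed)) next
    if (taxresolve:::record_depth(row) > q_depth) next

    eds <- integer(0)
    phons <- logical(0)
    thrs <- logical(0)
    add_comp <- function(q, r, key_q, key_r) {
      ed <- mdld(q, r)
      msl <- min(nchar(q), nchar(r))
      eds <<- c(eds, ed)
      phons <<- c(phons, key_q == key_r)
      thrs <<- c(thrs, threshold_test(ed, msl, q, r, params))
    }
    if (!is.null(allowed) && nzchar(row$family)) {
      add_comp(parsed$family, row$family, phonetic_key(parsed$family),
               row$family_key)
    }
    add_comp(parsed$genus, row$genus, gkey, row$genus_key)
    if (nzchar(row$specific_epithet) && nzchar(parsed$specific_epithet)) {
      add_comp(parsed$specific_epithet, row$specific_epithet, ekey,
               row$epithet_key)
    }
    if (nzchar(row$infraspecific_epithet) &&
        nzchar(parsed$infraspecific_epithet)) {
      add_comp(parsed$infraspecific_epithet, row$infraspecific_epithet,
               ikey, row$infra_key)
    }
    if (nzchar(row$infra2_epithet) &&
        nzchar(parsed$infraspecific_epithet2)) {
      add_comp(parsed$infraspecific_epithet2, row$infra2_epithet,
               phonetic_key(parsed$infraspecific_epithet2, epithet = TRUE),
               row$infra2_key)
    }
    retained <- max_ed_test(sum(eds), length(eds), params) &&
      (all(phons) || all(thrs))
    if (retained) ids <- c(ids, row$name_id)
  }
  sort(ids)
}

# Generate a fixture taxonomy, write it, and load it as a taxon_db.
make_fixture_db <- function(spec, source_id = "fx") {
  path <- tempfile(fileext = ".tsv")
  tax <- generate_taxonomy(spec, path)
  db <- load_exchange_file(path, source_id)
  list(db = db, tax = tax, path = path)
}
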