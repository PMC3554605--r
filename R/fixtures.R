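#' Specification of a synthetic reference taxonomy
#'
#' Controls for [generate_taxonomy()]: counts of families, genera and
#' species records, the fraction of species records that are synonyms, the
#' fraction of accepted species carrying an infraspecific taxon, the number
#' of cross-family homonym pairs, the query corruption profile and the RNG
#' seed. The defaults emulate a small herbarium-checklist-sized source with
#' a realistic level of synonymy (about one synonym for every four accepted
#' names) and occasional infraspecific taxa.
#'
#' @param n_families,n_genera,n_species record counts (species records
#'   include the synonyms).
#' @param synonym_fraction fraction of species records stored as synonyms
#'   of accepted congeners or cross-genus accepted names.
#' @param infraspecific_fraction fraction of accepted species that carry
#'   one infraspecific taxon (adds extra records).
#' @param homonym_pairs number of cross-family homonym pairs to plant (each
#'   adds one genus and one species record duplicating an existing
#'   canonical name in a different family).
#' @param corruption named probability vector over corruption operations,
#'   see [corruption_profile()].
#' @param seed integer RNG seed; generation is fully deterministic per
#'   seed.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_families = 3L, n_genera = 10L, n_species = 50L,
                         synonym_fraction = 0.2,
                         infraspecific_fraction = 0.1,
                         homonym_pairs = 0L,
                         corruption = corruption_profile(),
                         seed = 1L) {
  stopifnot(n_families >= 1, n_genera >= 1, n_species >= 1,
            synonym_fraction >= 0, synonym_fraction < 1,
            infraspecific_fraction >= 0, infraspecific_fraction <= 1,
            homonym_pairs >= 0)
  if (homonym_pairs > n_species / 2) {
    stop("homonym_pairs may not exceed half the species count")
  }
  structure(list(
    n_families = as.integer(n_families), n_genera = as.integer(n_genera),
    n_species = as.integer(n_species),
    synonym_fraction = synonym_fraction,
    infraspecific_fraction = infraspecific_fraction,
    homonym_pairs = as.integer(homonym_pairs),
    corruption = corruption, seed = as.integer(seed)
  ), class = "fixture_spec")
}

#' Corruption profile for query generation
#'
#' Independent application probabilities for each corruption operation that
#' [corrupt_name()] may apply to a reference name: character-level edits
#' (`substitute`, `insert`, `delete`, `transpose`, `block_transpose`),
#' gender `ending_swap` on the epithet (phonetically equal but nonzero edit
#' distance), `rank_indicator_swap` (triggers the wrong-rank penalty),
#' formatting noise (`all_caps`, `prepend_family`) and vocabulary noise
#' (`append_annotation`, `append_morphospecies`). The defaults mirror the
#' error classes observed in real heterogeneous datasets: misspellings
#' dominate, with occasional all-caps entries, family prefixes and
#' annotations.
#'
#' @param substitute,insert,delete,transpose,block_transpose,ending_swap,rank_indicator_swap,all_caps,prepend_family,append_annotation,append_morphospecies
#'   probabilities in \eqn{[0, 1]}.
#' @return named numeric vector.
#' @export
corruption_profile <- function(substitute = 0.3, insert = 0.15,
                               delete = 0.15, transpose = 0.1,
                               block_transpose = 0.05, ending_swap = 0.1,
                               rank_indicator_swap = 0, all_caps = 0.05,
                               prepend_family = 0.1,
                               append_annotation = 0.1,
                               append_morphospecies = 0.05) {
  out <- c(substitute = substitute, insert = insert, delete = delete,
           transpose = transpose, block_transpose = block_transpose,
           ending_swap = ending_swap,
           rank_indicator_swap = rank_indicator_swap,
           all_caps = all_caps, prepend_family = prepend_family,
           append_annotation = append_annotation,
           append_morphospecies = append_morphospecies)
  stopifnot(all(out >= 0), all(out <= 1))
  out
}

CONSONANTS <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t",
                "v")
VOWELS <- c("a", "e", "i", "o", "u")
STEM_ENDINGS <- c("a", "us", "um", "is")

# Pronounceable pseudo-Latin word: CV syllables plus a stemmable ending.
random_word <- function(min_len, max_len) {
  repeat {
    n_syll <- sample(2:4, 1)
    syll <- vapply(seq_len(n_syll), function(i) {
      paste0(sample(CONSONANTS, 1), sample(VOWELS, 1),
             if (stats::runif(1) < 0.25) sample(CONSONANTS, 1) else "")
    }, character(1))
    w <- paste0(paste(syll, collapse = ""), sample(STEM_ENDINGS, 1))
    if (nchar(w) >= min_len && nchar(w) <= max_len) return(w)
  }
}

# Draw words pairwise well-separated in edit distance and phonetic key so
# that a corrupted query has a unique nearest reference name.
draw_separated <- function(n, min_len, max_len, min_dist = 5L,
                           epithet = FALSE, max_tries = 500L * n) {
  words <- character(0)
  keys <- character(0)
  tries <- 0L
  while (length(words) < n) {
    tries <- tries + 1L
    if (tries > max_tries) stop("could not draw ", n, " separated names")
    w <- random_word(min_len, max_len)
    k <- phonetic_key(w, epithet = epithet)
    if (length(words) &&
        (any(mdld(w, words) < min_dist) || k %in% keys)) next
    words <- c(words, w)
    keys <- c(keys, k)
  }
  words
}

#' Generate a synthetic reference taxonomy
#'
#' Builds a hierarchical reference taxonomy of pseudo-Latin names (families
#' ending in `-aceae`, genera and species with stemmable Latin endings),
#' with configurable synonymy, infraspecific taxa and cross-family homonym
#' pairs, and optionally writes it in the exchange format that
#' [load_exchange_file()] reads. Names are drawn pairwise well-separated in
#' edit distance and phonetic key (homonym copies excepted), so corrupted
#' queries have a unique intended target; generation is deterministic for a
#' given seed. Generated names are invented, never real genera.
#'
#' @param spec a [fixture_spec()].
#' @param path optional path for the exchange TSV.
#' @return list with `records` (the exchange-format data.frame), `spec` and
#'   `path`.
#' @export
generate_taxonomy <- function(spec = fixture_spec(), path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    fam_stems <- draw_separated(spec$n_families, 6L, 9L, min_dist = 5L)
    families <- paste0(title_case(fam_stems), "aceae")
    genera <- title_case(draw_separated(spec$n_genera, 7L, 10L))
    epithet_pool <- draw_separated(spec$n_species +
                                     ceiling(spec$infraspecific_fraction *
                                               spec$n_species) + 5L,
                                   6L, 10L, epithet = TRUE)

    fam_of_genus <- families[c(seq_len(spec$n_families),
                               sample.int(spec$n_families,
                                          max(0, spec$n_genera -
                                                spec$n_families),
                                          replace = TRUE))]
    fam_of_genus <- fam_of_genus[seq_len(spec$n_genera)]

    rows <- list()
    for (i in seq_len(spec$n_families)) {
      rows[[length(rows) + 1L]] <- c(
        taxonID = paste0("f", i), scientificName = families[i],
        scientificNameAuthorship = "", taxonRank = "family",
        parentNameUsageID = "", acceptedNameUsageID = "",
        taxonomicStatus = "accepted", family = families[i])
    }
    for (i in seq_len(spec$n_genera)) {
      rows[[length(rows) + 1L]] <- c(
        taxonID = paste0("g", i), scientificName = genera[i],
        scientificNameAuthorship = "L.", taxonRank = "genus",
        parentNameUsageID = paste0("f", match(fam_of_genus[i], families)),
        acceptedNameUsageID = "", taxonomicStatus = "accepted",
        family = fam_of_genus[i])
    }

    n_syn <- floor(spec$synonym_fraction * spec$n_species)
    n_acc <- spec$n_species - n_syn
    genus_of_species <- c(seq_len(min(spec$n_genera, spec$n_species)),
                          sample.int(spec$n_genera,
                                     max(0, spec$n_species - spec$n_genera),
                                     replace = TRUE))
    genus_of_species <- genus_of_species[seq_len(spec$n_species)]
    is_syn <- rep(FALSE, spec$n_species)
    if (n_syn > 0) is_syn[sample.int(spec$n_species, n_syn)] <- TRUE
    # Ensure at least one accepted species exists.
    if (all(is_syn)) is_syn[1] <- FALSE
    acc_ids <- paste0("s", which(!is_syn))
    for (i in seq_len(spec$n_species)) {
      gi <- genus_of_species[i]
      acc_target <- if (is_syn[i]) sample(acc_ids, 1) else ""
      rows[[length(rows) + 1L]] <- c(
        taxonID = paste0("s", i),
        scientificName = paste(genera[gi], epithet_pool[i]),
        scientificNameAuthorship = sample(c("L.", "Kunth", "Benth.",
                                            "(L.) DC."), 1),
        taxonRank = "species",
        parentNameUsageID = paste0("g", gi),
        acceptedNameUsageID = acc_target,
        taxonomicStatus = if (is_syn[i]) "synonym" else "accepted",
        family = fam_of_genus[gi])
    }

    n_inf <- floor(spec$infraspecific_fraction * n_acc)
    if (n_inf > 0) {
      host <- sample(which(!is_syn), n_inf)
      for (j in seq_len(n_inf)) {
        i <- host[j]
        gi <- genus_of_species[i]
        rk <- sample(c("variety", "subspecies", "forma"), 1)
        ind <- rank_indicator_for(rk)
        ep <- epithet_pool[spec$n_species + j]
        rows[[length(rows) + 1L]] <- c(
          taxonID = paste0("i", j),
          scientificName = paste(genera[gi], epithet_pool[i], ind, ep),
          scientificNameAuthorship = "Hook.f.",
          taxonRank = rk,
          parentNameUsageID = paste0("s", i),
          acceptedNameUsageID = "",
          taxonomicStatus = "accepted",
          family = fam_of_genus[gi])
      }
    }

    if (spec$homonym_pairs > 0) {
      if (spec$n_families < 2) stop("homonym pairs need >= 2 families")
      donors <- sample(which(!is_syn), spec$homonym_pairs)
      for (j in seq_len(spec$homonym_pairs)) {
        i <- donors[j]
        gi <- genus_of_species[i]
        other_fams <- setdiff(families, fam_of_genus[gi])
        fam2 <- sample(other_fams, 1)
        rows[[length(rows) + 1L]] <- c(
          taxonID = paste0("hg", j), scientificName = genera[gi],
          scientificNameAuthorship = "Mill.", taxonRank = "genus",
          parentNameUsageID = paste0("f", match(fam2, families)),
          acceptedNameUsageID = "", taxonomicStatus = "accepted",
          family = fam2)
        rows[[length(rows) + 1L]] <- c(
          taxonID = paste0("hs", j),
          scientificName = paste(genera[gi], epithet_pool[i]),
          scientificNameAuthorship = "Mill.", taxonRank = "species",
          parentNameUsageID = paste0("hg", j),
          acceptedNameUsageID = "", taxonomicStatus = "accepted",
          family = fam2)
      }
    }

    records <- as.data.frame(do.call(rbind, rows),
                             stringsAsFactors = FALSE)
    if (!is.null(path)) {
      utils::write.table(records, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, fileEncoding = "UTF-8")
    }
    list(records = records, spec = spec, path = path)
  })
}

swap_ending <- function(w) {
  ends <- c("is", "us", "ys", "es", "um", "as", "os")
  for (e in c(ends, "a")) {
    if (endsWith(w, e)) {
      alt <- setdiff(c(ends, "a"), e)
      alt <- alt[nchar(alt) > 0]
      return(paste0(substr(w, 1, nchar(w) - nchar(e)), sample(alt, 1)))
    }
  }
  w
}

# Character-level edits keep the first character intact so the corrupted
# component still anchors the match threshold test.
apply_char_op <- function(w, op) {
  n <- nchar(w)
  chars <- strsplit(w, "")[[1]]
  if (op == "substitute" && n >= 2) {
    p <- sample(2:n, 1)
    chars[p] <- sample(setdiff(letters, chars[p]), 1)
  } else if (op == "insert") {
    p <- sample(2:(n + 1), 1)
    chars <- append(chars, sample(letters, 1), after = p - 1)
  } else if (op == "delete" && n >= 5) {
    p <- sample(2:n, 1)
    chars <- chars[-p]
  } else if (op == "transpose" && n >= 3) {
    cand <- which(chars[2:(n - 1)] != chars[3:n]) + 1
    if (length(cand)) {
      p <- if (length(cand) == 1) cand else sample(cand, 1)
      tmp <- chars[p]; chars[p] <- chars[p + 1]; chars[p + 1] <- tmp
    }
  } else if (op == "block_transpose" && n >= 6) {
    p <- sample(2:(n - 3), 1)
    b1 <- chars[p:(p + 1)]
    b2 <- chars[(p + 2):(p + 3)]
    if (!identical(b1, b2)) chars[p:(p + 3)] <- c(b2, b1)
  }
  paste(chars, collapse = "")
}

#' Corrupt a reference name into a ground-truthed query
#'
#' Applies the sampled corruption operations of a [corruption_profile()] to
#' one reference record and returns the corrupted query string together
#' with its ground truth: the true record id, the operations applied, and
#' the realized per-component edit distance (recomputed with [mdld()], so
#' the stored distance is exact even when random edits cancel).
#'
#' @param record one reference record (a row of [generate_taxonomy()]
#'   records or of a [taxon_db]).
#' @param profile a [corruption_profile()].
#' @param seed integer seed.
#' @return list with `raw`, `true_name_id`, `applied_operations`,
#'   `intended_ed`.
#' @export
corrupt_name <- function(record, profile = corruption_profile(),
                         seed = 1L) {
  with_seed(seed, {
    p <- parse_name(record$scientificName %||% record$canonical)
    comps <- list(genus = p$genus)
    if (nzchar(p$specific_epithet)) comps$species <- p$specific_epithet
    if (nzchar(p$infraspecific_epithet)) {
      comps$infraspecies <- p$infraspecific_epithet
    }
    orig <- comps
    ops <- character(0)

    for (op in c("substitute", "insert", "delete", "transpose",
                 "block_transpose")) {
      if (stats::runif(1) < profile[[op]]) {
        target <- sample(names(comps), 1)
        comps[[target]] <- apply_char_op(comps[[target]], op)
        ops <- c(ops, op)
      }
    }
    if (!is.null(comps$species) &&
        stats::runif(1) < profile[["ending_swap"]]) {
      comps$species <- swap_ending(comps$species)
      ops <- c(ops, "ending_swap")
    }
    indicator <- p$rank_indicator
    if (nzchar(indicator) &&
        stats::runif(1) < profile[["rank_indicator_swap"]]) {
      indicator <- sample(setdiff(c("var.", "subsp.", "fo."), indicator), 1)
      ops <- c(ops, "rank_indicator_swap")
    }

    raw <- paste(c(comps$genus, comps$species,
                   if (!is.null(comps$infraspecies))
                     c(indicator, comps$infraspecies)),
                 collapse = " ")
    if (stats::runif(1) < profile[["append_annotation"]]) {
      ann <- sample(c("cf.", "aff."), 1)
      raw <- sub(" ", paste0(" ", ann, " "), raw)
      ops <- c(ops, "append_annotation")
    }
    if (stats::runif(1) < profile[["append_morphospecies"]]) {
      raw <- paste(raw, sample(c("sp. 1", "sp. 2", "AB123"), 1))
      ops <- c(ops, "append_morphospecies")
    }
    if (stats::runif(1) < profile[["prepend_family"]]) {
      fam <- record$family
      if (nzchar(fam)) {
        raw <- paste(fam, raw)
        ops <- c(ops, "prepend_family")
      }
    }
    if (stats::runif(1) < profile[["all_caps"]]) {
      raw <- toupper(raw)
      ops <- c(ops, "all_caps")
    }

    ed <- sum(vapply(names(orig), function(nm2) {
      mdld(orig[[nm2]], comps[[nm2]])
    }, integer(1)))
    id <- record$taxonID %||% record$name_id
    list(raw = raw, true_name_id = id, applied_operations = ops,
         intended_ed = as.integer(ed))
  })
}

#' Generate a ground-truthed corrupted query set
#'
#' Samples species-rank records from a generated taxonomy and corrupts each
#' with [corrupt_name()] under per-query derived seeds. Optionally writes
#' the query file (`id<TAB>name` per line) and a ground-truth TSV.
#'
#' @param taxonomy a [generate_taxonomy()] result.
#' @param n number of queries.
#' @param profile a [corruption_profile()].
#' @param seed integer seed.
#' @param query_path,truth_path optional output paths.
#' @return data.frame with columns `id`, `name`, `true_name_id`,
#'   `operations`, `intended_ed`.
#' @export
make_query_set <- function(taxonomy, n, profile = corruption_profile(),
                           seed = 1L, query_path = NULL,
                           truth_path = NULL) {
  recs <- taxonomy$records
  sp <- recs[recs$taxonRank == "species", , drop = FALSE]
  stopifnot(nrow(sp) >= 1)
  idx <- with_seed(seed, sample.int(nrow(sp), n, replace = n > nrow(sp)))
  out <- lapply(seq_len(n), function(i) {
    seed_i <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    q <- corrupt_name(sp[idx[i], , drop = FALSE], profile, seed = seed_i)
    data.frame(id = i, name = q$raw, true_name_id = q$true_name_id,
               operations = paste(q$applied_operations, collapse = ";"),
               intended_ed = q$intended_ed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(query_path)) {
    writeLines(paste(out$id, out$name, sep = "\t"), query_path)
  }
  if (!is.null(truth_path)) {
    utils::write.table(out, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
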