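EXCHANGE_COLUMNS <- c("taxonID", "scientificName", "scientificNameAuthorship",
                      "taxonRank", "parentNameUsageID", "acceptedNameUsageID",
                      "taxonomicStatus", "family")
RANK_TOKENS <- c("family", "genus", "species", "subspecies", "variety",
                 "forma")
STATUS_TOKENS <- c("accepted", "synonym", "illegitimate", "invalid",
                   "no_opinion")
INFRA_RANKS <- c("subspecies", "variety", "forma")

rank_indicator_for <- function(rank) {
  switch(rank, subspecies = "subsp.", variety = "var.", forma = "fo.", "")
}

# Depth used to compare query and reference ranks. Family does not count as
# a name part, so it sits at depth 0.
rank_depth <- function(rank) {
  unname(c(none = -1, family = 0, genus = 1, species = 2,
           subspecies = 3, variety = 3, forma = 3,
           infraspecies = 3, infraspecies2 = 4)[rank])
}

record_depth <- function(rec) {
  d <- rank_depth(rec$rank)
  ifelse(d == 3 & nzchar(rec$infra2_epithet), 4, d)
}

#' Reference taxonomy store
#'
#' @description
#' A `taxon_db` is an in-memory reference store built from one or more
#' Darwin-Core-style exchange files by [load_exchange_file()]. It holds the
#' normalized name records, a nested-set index over the parent-child
#' hierarchy (for constant-form descendant queries), and the precomputed
#' phonetic keys and epithet stems used by the fuzzy matcher.
#'
#' The exchange format is UTF-8 TSV with a header and columns `taxonID`,
#' `scientificName` (the canonical form, without authorship),
#' `scientificNameAuthorship`, `taxonRank` (one of `family`, `genus`,
#' `species`, `subspecies`, `variety`, `forma`), `parentNameUsageID`,
#' `acceptedNameUsageID`, `taxonomicStatus` (`accepted`, `synonym`,
#' `illegitimate`, `invalid`, `no opinion`) and `family`. Empty string means
#' null.
#'
#' @param path path to an exchange TSV file.
#' @param source_id identifier for the taxonomic source being loaded.
#' @param priority integer source priority (1 = consulted first). Defaults
#'   to load order.
#' @param db an existing `taxon_db` to append to, or `NULL`.
#' @return a `taxon_db` object.
#' @name taxon_db
NULL

#' Load a reference taxonomy exchange file
#'
#' Reads, validates and indexes one taxonomic source. Validation errors name
#' the offending row: duplicate `taxonID`, unknown rank or status tokens,
#' dangling `parentNameUsageID`/`acceptedNameUsageID`, missing components
#' for the declared rank, and synonym cycles are all rejected. Synonym
#' chains (synonym pointing at synonym) are collapsed to the terminal
#' accepted record at load time. The nested-set index and the fuzzy-match
#' keys are rebuilt after every load.
#'
#' @rdname taxon_db
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(paste(c("taxonID\tscientificName\tscientificNameAuthorship\ttaxonRank\tparentNameUsageID\tacceptedNameUsageID\ttaxonomicStatus\tfamily",
#'   "f1\tMoraceae\t\tfamily\t\t\taccepted\tMoraceae",
#'   "g1\tFicus\tL.\tgenus\tf1\t\taccepted\tMoraceae",
#'   "s1\tFicus insipida\tWilld.\tspecies\tg1\t\taccepted\tMoraceae"),
#'   collapse = "\n"), tsv)
#' db <- load_exchange_file(tsv, source_id = "demo")
#' db
#' @export
load_exchange_file <- function(path, source_id, priority = NULL, db = NULL) {
  raw <- utils::read.delim(path, sep = "\t", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = character(0), encoding = "UTF-8")
  missing_cols <- setdiff(EXCHANGE_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("exchange file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[EXCHANGE_COLUMNS]
  raw[] <- lapply(raw, trimws)

  ids <- raw$taxonID
  if (any(!nzchar(ids))) stop("empty taxonID in row(s) ",
                              paste(which(!nzchar(ids)), collapse = ", "))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate taxonID: ", paste(unique(dup),
                                                     collapse = ", "))

  bad_rank <- !(raw$taxonRank %in% RANK_TOKENS)
  if (any(bad_rank)) {
    stop("unknown taxonRank token '", raw$taxonRank[which(bad_rank)[1]],
         "' for taxonID ", ids[which(bad_rank)[1]])
  }
  status <- gsub(" ", "_", tolower(raw$taxonomicStatus))
  bad_status <- !(status %in% STATUS_TOKENS)
  if (any(bad_status)) {
    stop("unknown taxonomicStatus '",
         raw$taxonomicStatus[which(bad_status)[1]], "' for taxonID ",
         ids[which(bad_status)[1]])
  }

  dangling_parent <- nzchar(raw$parentNameUsageID) &
    !(raw$parentNameUsageID %in% ids)
  if (any(dangling_parent)) {
    stop("parentNameUsageID '",
         raw$parentNameUsageID[which(dangling_parent)[1]],
         "' of taxonID ", ids[which(dangling_parent)[1]],
         " refers to no record")
  }
  dangling_acc <- nzchar(raw$acceptedNameUsageID) &
    !(raw$acceptedNameUsageID %in% ids)
  if (any(dangling_acc)) {
    stop("acceptedNameUsageID '",
         raw$acceptedNameUsageID[which(dangling_acc)[1]],
         "' of taxonID ", ids[which(dangling_acc)[1]],
         " refers to no record")
  }

  # Atomize scientificName and build component columns.
  n <- nrow(raw)
  genus <- character(n); sp <- character(n)
  infra_rank <- character(n); infra <- character(n)
  infra2_rank <- character(n); infra2 <- character(n)
  family_name <- raw$family
  for (i in seq_len(n)) {
    p <- parse_name(raw$scientificName[i])
    rk <- raw$taxonRank[i]
    if (rk == "family") {
      if (!nzchar(p$family) && nzchar(p$genus)) {
        # a family name without a standard ending parses as a genus token
        p$family <- p$genus
        p$genus <- ""
      }
      if (!nzchar(p$family)) {
        stop("cannot read family name '", raw$scientificName[i],
             "' for taxonID ", ids[i])
      }
      if (!nzchar(family_name[i])) family_name[i] <- p$family
    } else {
      if (!nzchar(p$genus)) {
        stop("cannot read genus from '", raw$scientificName[i],
             "' for taxonID ", ids[i])
      }
      genus[i] <- p$genus
      sp[i] <- p$specific_epithet
      infra[i] <- p$infraspecific_epithet
      infra_rank[i] <- p$rank_indicator
      infra2[i] <- p$infraspecific_epithet2
      infra2_rank[i] <- p$rank_indicator2
      if (rk %in% INFRA_RANKS) {
        deepest_default <- rank_indicator_for(rk)
        if (nzchar(infra2[i])) {
          if (!nzchar(infra2_rank[i])) infra2_rank[i] <- deepest_default
        } else if (!nzchar(infra_rank[i]) && nzchar(infra[i])) {
          infra_rank[i] <- deepest_default
        }
      }
    }
    if (rk == "species" && !nzchar(sp[i])) {
      stop("rank species but no specific epithet in '",
           raw$scientificName[i], "' (taxonID ", ids[i], ")")
    }
    if (rk %in% INFRA_RANKS && !nzchar(infra[i])) {
      stop("rank ", rk, " but no infraspecific epithet in '",
           raw$scientificName[i], "' (taxonID ", ids[i], ")")
    }
  }

  canonical <- vapply(seq_len(n), function(i) {
    if (raw$taxonRank[i] == "family") return(family_name[i])
    paste(c(genus[i],
            if (nzchar(sp[i])) sp[i],
            if (nzchar(infra[i])) c(if (nzchar(infra_rank[i])) infra_rank[i],
                                    infra[i]),
            if (nzchar(infra2[i])) c(if (nzchar(infra2_rank[i]))
              infra2_rank[i], infra2[i])),
          collapse = " ")
  }, character(1))

  # Collapse synonym chains; detect cycles; validate terminal status.
  acc <- raw$acceptedNameUsageID
  names(acc) <- ids
  status_by_id <- stats::setNames(status, ids)
  resolved_acc <- character(n)
  for (i in seq_len(n)) {
    st <- status[i]
    if (st == "accepted") {
      if (nzchar(acc[i]) && acc[i] != ids[i]) {
        stop("accepted record ", ids[i],
             " has acceptedNameUsageID pointing elsewhere (", acc[i], ")")
      }
      resolved_acc[i] <- ""
      next
    }
    if (st == "no_opinion") {
      resolved_acc[i] <- ""
      next
    }
    if (!nzchar(acc[i])) {
      stop("record ", ids[i], " has status '", st,
           "' but no acceptedNameUsageID")
    }
    seen <- ids[i]
    cur <- acc[[i]]
    while (status_by_id[[cur]] != "accepted") {
      if (cur %in% seen) stop("synonym cycle involving taxonID ", cur)
      if (status_by_id[[cur]] == "no_opinion") {
        stop("record ", ids[i], " resolves to no_opinion record ", cur,
             " rather than an accepted name")
      }
      seen <- c(seen, cur)
      nxt <- acc[[cur]]
      if (!nzchar(nxt)) {
        stop("record ", cur, " has status '", status_by_id[[cur]],
             "' but no acceptedNameUsageID")
      }
      cur <- nxt
    }
    resolved_acc[i] <- cur
  }

  recs <- data.frame(
    name_id = ids,
    source_id = rep(as.character(source_id), n),
    rank = raw$taxonRank,
    family = family_name,
    genus = genus,
    specific_epithet = sp,
    infra_rank_indicator = infra_rank,
    infraspecific_epithet = infra,
    infra2_rank_indicator = infra2_rank,
    infra2_epithet = infra2,
    author = raw$scientificNameAuthorship,
    status = status,
    accepted_name_id = resolved_acc,
    parent_id = raw$parentNameUsageID,
    canonical = canonical,
    stringsAsFactors = FALSE
  )

  if (!is.null(db)) {
    stopifnot(inherits(db, "taxon_db"))
    clash <- intersect(recs$name_id, db$names$name_id)
    if (length(clash)) {
      stop("duplicate name_id across sources: ",
           paste(utils::head(clash, 5), collapse = ", "))
    }
    if (is.null(priority)) priority <- max(db$sources$priority) + 1L
    sources <- rbind(db$sources,
                     data.frame(source_id = as.character(source_id),
                                priority = as.integer(priority),
                                stringsAsFactors = FALSE))
    recs <- rbind(db$names[names(recs)], recs)
  } else {
    if (is.null(priority)) priority <- 1L
    sources <- data.frame(source_id = as.character(source_id),
                          priority = as.integer(priority),
                          stringsAsFactors = FALSE)
  }

  build_taxon_db(recs, sources)
}

build_taxon_db <- function(recs, sources) {
  ns <- build_nested_set(recs)
  recs$left_bound <- ns$left
  recs$right_bound <- ns$right
  recs <- add_match_index(recs)
  out <- list(names = recs, sources = sources)
  class(out) <- "taxon_db"
  out
}

# Nested-set (preorder interval) labels over the parent-pointer forest.
build_nested_set <- function(recs) {
  n <- nrow(recs)
  idx <- stats::setNames(seq_len(n), recs$name_id)
  parent <- ifelse(nzchar(recs$parent_id), idx[recs$parent_id], NA_integer_)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  left <- integer(n)
  right <- integer(n)
  counter <- 0L
  # iterative DFS: stack of (node, child position)
  roots <- which(is.na(parent))
  for (root in roots) {
    stack_node <- root
    stack_pos <- 1L
    counter <- counter + 1L
    left[root] <- counter
    while (length(stack_node)) {
      top <- length(stack_node)
      node <- stack_node[top]
      pos <- stack_pos[top]
      kids <- children[[node]]
      if (pos <= length(kids)) {
        stack_pos[top] <- pos + 1L
        child <- kids[pos]
        counter <- counter + 1L
        left[child] <- counter
        stack_node <- c(stack_node, child)
        stack_pos <- c(stack_pos, 1L)
      } else {
        counter <- counter + 1L
        right[node] <- counter
        stack_node <- stack_node[-top]
        stack_pos <- stack_pos[-top]
      }
    }
  }
  if (any(left == 0L)) {
    bad <- recs$name_id[which(left == 0L)[1]]
    stop("parent-child links contain a cycle involving taxonID ", bad)
  }
  list(left = left, right = right)
}

# Precompute the phonetic keys and stems the matcher uses at query time.
add_match_index <- function(recs) {
  recs$family_key <- phonetic_key(recs$family)
  recs$genus_key <- phonetic_key(recs$genus)
  recs$epithet_stem <- stem_epithet(tolower(recs$specific_epithet))
  recs$epithet_key <- phonetic_key(recs$specific_epithet, epithet = TRUE)
  recs$infra_key <- phonetic_key(recs$infraspecific_epithet, epithet = TRUE)
  recs$infra2_key <- phonetic_key(recs$infra2_epithet, epithet = TRUE)
  recs
}

#' @export
print.taxon_db <- function(x, ...) {
  cat("<taxon_db> ", nrow(x$names), " records from ",
      nrow(x$sources), " source(s)\n", sep = "")
  tab <- table(x$names$rank)
  cat("  ranks:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

db_row <- function(db, name_id) {
  i <- match(name_id, db$names$name_id)
  if (is.na(i)) stop("unknown name_id: ", name_id)
  db$names[i, , drop = FALSE]
}

#' Descendants of a taxon
#'
#' All records whose nested-set interval is strictly contained in the query
#' record's interval, i.e. the full subtree below the taxon, excluding the
#' taxon itself.
#'
#' @param db a [taxon_db].
#' @param name_id record identifier.
#' @return character vector of descendant `name_id`s.
#' @export
descendants <- function(db, name_id) {
  row <- db_row(db, name_id)
  sel <- db$names$left_bound > row$left_bound &
    db$names$right_bound < row$right_bound
  db$names$name_id[sel]
}

#' Resolve a record to its accepted name
#'
#' Returns the record itself when its status is `accepted` or `no_opinion`;
#' otherwise the accepted record referenced by `accepted_name_id` (synonym
#' chains were already collapsed at load time, so at most one hop is
#' followed).
#'
#' @param db a [taxon_db].
#' @param name_id record identifier.
#' @return a one-row data.frame (the reference record).
#' @export
resolve_accepted <- function(db, name_id) {
  row <- db_row(db, name_id)
  if (row$status %in% c("accepted", "no_opinion")) return(row)
  if (!nzchar(row$accepted_name_id)) {
    stop("record ", name_id, " has status '", row$status,
         "' but no accepted_name_id")
  }
  db_row(db, row$accepted_name_id)
}

#' Exact lookup of a canonical name
#'
#' Case-sensitive exact match on the canonical form; the author is compared
#' only when supplied. Results are ordered by source priority (or by the
#' order of `source_ids` when given), then by status and name.
#'
#' @param db a [taxon_db].
#' @param canonical canonical name string.
#' @param author optional author string to require.
#' @param source_ids optional ordered list of sources to search.
#' @return data.frame of matching records (zero rows when there is no hit).
#' @export
exact_lookup <- function(db, canonical, author = NULL, source_ids = NULL) {
  stopifnot(inherits(db, "taxon_db"), nzchar(canonical))
  sel <- db$names$canonical == canonical
  if (!is.null(author) && nzchar(author)) {
    sel <- sel & db$names$author == author
  }
  if (!is.null(source_ids)) {
    sel <- sel & db$names$source_id %in% source_ids
  }
  hits <- db$names[sel, , drop = FALSE]
  order_hits(hits, db, source_ids)
}

order_hits <- function(hits, db, source_ids = NULL) {
  if (!nrow(hits)) return(hits)
  prio <- if (!is.null(source_ids)) {
    match(hits$source_id, source_ids)
  } else {
    db$sources$priority[match(hits$source_id, db$sources$source_id)]
  }
  st <- match(hits$status, c("accepted", "synonym", "illegitimate",
                             "invalid", "no_opinion"))
  hits[order(prio, st, hits$canonical, hits$name_id), , drop = FALSE]
}

# Exact match of a full cleaned string: either the canonical form alone or
# canonical + author.
exact_lookup_full <- function(db, cleaned, source_ids = NULL) {
  with_author <- trimws(paste(db$names$canonical, db$names$author))
  sel <- db$names$canonical == cleaned | with_author == cleaned
  if (!is.null(source_ids)) sel <- sel & db$names$source_id %in% source_ids
  order_hits(db$names[sel, , drop = FALSE], db, source_ids)
}

#' Export a store back to the exchange format
#'
#' Writes the records of a [taxon_db] (optionally one source) as an exchange
#' TSV that [load_exchange_file()] can re-read; a load/export/load
#' round-trip reproduces identical records.
#'
#' @param db a [taxon_db].
#' @param path output file path.
#' @param source_id optional source filter.
#' @return the path, invisibly.
#' @export
export_taxonomy <- function(db, path, source_id = NULL) {
  recs <- db$names
  if (!is.null(source_id)) recs <- recs[recs$source_id %in% source_id, ]
  out <- data.frame(
    taxonID = recs$name_id,
    scientificName = recs$canonical,
    scientificNameAuthorship = recs$author,
    taxonRank = recs$rank,
    parentNameUsageID = recs$parent_id,
    acceptedNameUsageID = recs$accepted_name_id,
    taxonomicStatus = gsub("_", " ", recs$status),
    family = recs$family,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
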