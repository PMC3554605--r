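five_row_file <- function(synonym_target = "s1") {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste(EXCHANGE_HEADER, collapse = "\t"),
    "f1\tPoaceae\t\tfamily\t\t\taccepted\tPoaceae",
    "g1\tPoa\tL.\tgenus\tf1\t\taccepted\tPoaceae",
    "s1\tPoa annua\tL.\tspecies\tg1\t\taccepted\tPoaceae",
    paste0("s2\tPoa spuria\tKunth\tspecies\tg1\t", synonym_target,
           "\tsynonym\tPoaceae"),
    "s3\tPoa infirma\tKunth\tspecies\tg1\t\tno opinion\tPoaceae"
  ), path)
  path
}
EXCHANGE_HEADER <- c("taxonID", "scientificName", "scientificNameAuthorship",
                     "taxonRank", "parentNameUsageID", "acceptedNameUsageID",
                     "taxonomicStatus", "family")

test_that("a small exchange file loads and links resolve", {
  db <- load_exchange_file(five_row_file(), "t")
  expect_equal(nrow(db$names), 5)
  expect_equal(db$names$status[db$names$name_id == "s2"], "synonym")
  acc <- resolve_accepted(db, "s2")
  expect_equal(acc$name_id, "s1")
  # accepted and no-opinion records resolve to themselves
  expect_equal(resolve_accepted(db, "s1")$name_id, "s1")
  noop <- resolve_accepted(db, "s3")
  expect_equal(noop$name_id, "s3")
  expect_equal(noop$status, "no_opinion")
})

test_that("dangling links, duplicates and unknown tokens are rejected", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c(paste(EXCHANGE_HEADER, collapse = "\t"),
               "s1\tPoa annua\tL.\tspecies\t\tzz9\tsynonym\tPoaceae"), bad)
  expect_error(load_exchange_file(bad, "t"), "zz9")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c(paste(EXCHANGE_HEADER, collapse = "\t"),
               "s1\tPoa annua\tL.\tspecies\t\t\taccepted\tPoaceae",
               "s1\tPoa infirma\tL.\tspecies\t\t\taccepted\tPoaceae"), dup)
  expect_error(load_exchange_file(dup, "t"), "duplicate")

  rank <- tempfile(fileext = ".tsv")
  writeLines(c(paste(EXCHANGE_HEADER, collapse = "\t"),
               "s1\tPoa annua\tL.\ttribe\t\t\taccepted\tPoaceae"), rank)
  expect_error(load_exchange_file(rank, "t"), "taxonRank")

  orphan <- tempfile(fileext = ".tsv")
  writeLines(c(paste(EXCHANGE_HEADER, collapse = "\t"),
               "s1\tPoa annua\tL.\tspecies\tg9\t\taccepted\tPoaceae"),
             orphan)
  expect_error(load_exchange_file(orphan, "t"), "g9")
})

test_that("synonym chains collapse to one hop and cycles are rejected", {
  chain <- tempfile(fileext = ".tsv")
  writeLines(c(paste(EXCHANGE_HEADER, collapse = "\t"),
               "s1\tPoa annua\tL.\tspecies\t\t\taccepted\tPoaceae",
               "s2\tPoa spuria\tL.\tspecies\t\ts3\tsynonym\tPoaceae",
               "s3\tPoa media\tL.\tspecies\t\ts1\tsynonym\tPoaceae"), chain)
  db <- load_exchange_file(chain, "t")
  expect_equal(db$names$accepted_name_id[db$names$name_id == "s2"], "s1")
  expect_equal(resolve_accepted(db, "s2")$name_id, "s1")

  cyc <- tempfile(fileext = ".tsv")
  writeLines(c(paste(EXCHANGE_HEADER, collapse = "\t"),
               "s1\tPoa annua\tL.\tspecies\t\ts2\tsynonym\tPoaceae",
               "s2\tPoa spuria\tL.\tspecies\t\ts1\tsynonym\tPoaceae"), cyc)
  expect_error(load_exchange_file(cyc, "t"), "cycle")
})

test_that("a generated fixture loads cleanly and its intervals nest", {
  fx <- make_fixture_db(fixture_spec(n_families = 3, n_genera = 10,
                                     n_species = 50,
                                     infraspecific_fraction = 0,
                                     homonym_pairs = 0, seed = 5))
  db <- fx$db
  expect_equal(nrow(db$names), 63)
  expect_true(all(db$names$left_bound < db$names$right_bound))
  # nested-set containment equals the parent-pointer transitive closure
  for (id in db$names$name_id) {
    expect_equal(sort(descendants(db, id)),
                 closure_descendants(fx$tax$records, id), info = id)
  }
})

test_that("descendant queries behave at the extremes", {
  db <- load_exchange_file(five_row_file(), "t")
  expect_length(descendants(db, "s1"), 0)      # leaf
  expect_setequal(descendants(db, "f1"), c("g1", "s1", "s2", "s3"))
  expect_error(descendants(db, "nope"), "unknown")
})

test_that("exact lookup is case-sensitive, author-aware and priority-ordered", {
  db <- load_exchange_file(five_row_file(), "A", priority = 1)
  two <- tempfile(fileext = ".tsv")
  writeLines(c(paste(EXCHANGE_HEADER, collapse = "\t"),
               "b1\tPoa annua\tauct.\tspecies\t\t\taccepted\tPoaceae"), two)
  db <- load_exchange_file(two, "B", priority = 2, db = db)

  hits <- exact_lookup(db, "Poa annua")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$source_id, c("A", "B")) # ordered by priority
  expect_equal(nrow(exact_lookup(db, "Poa annuaa")), 0)
  expect_equal(exact_lookup(db, "Poa annua", author = "auct.")$name_id,
               "b1")
  # explicit source order overrides stored priority
  hits2 <- exact_lookup(db, "Poa annua", source_ids = c("B", "A"))
  expect_equal(hits2$source_id, c("B", "A"))
})

test_that("an exported store reloads to identical records", {
  fx <- make_fixture_db(fixture_spec(n_species = 20, seed = 9,
                                     infraspecific_fraction = 0.2))
  out <- tempfile(fileext = ".tsv")
  export_taxonomy(fx$db, out)
  db2 <- load_exchange_file(out, "fx")
  core <- c("name_id", "rank", "family", "genus", "specific_epithet",
            "infra_rank_indicator", "infraspecific_epithet", "author",
            "status", "accepted_name_id", "parent_id", "canonical")
  expect_equal(db2$names[core], fx$db$names[core])
})

test_that("stored phonetic keys equal recomputation with the matcher", {
  fx <- make_fixture_db(fixture_spec(n_species = 25, seed = 13,
                                     infraspecific_fraction = 0.2))
  nm <- fx$db$names
  expect_equal(nm$genus_key, phonetic_key(nm$genus))
  expect_equal(nm$epithet_key, phonetic_key(nm$specific_epithet,
                                            epithet = TRUE))
  expect_equal(nm$infra_key, phonetic_key(nm$infraspecific_epithet,
                                          epithet = TRUE))
  expect_equal(nm$epithet_stem, stem_epithet(tolower(nm$specific_epithet)))
})
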