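test_that("generation is deterministic per seed", {
  spec <- fixture_spec(n_species = 20, seed = 77)
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  generate_taxonomy(spec, p1)
  generate_taxonomy(spec, p2)
  expect_identical(readLines(p1), readLines(p2))
  p3 <- tempfile(fileext = ".tsv")
  generate_taxonomy(fixture_spec(n_species = 20, seed = 78), p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("synonym fraction zero gives an all-accepted taxonomy", {
  tax <- generate_taxonomy(fixture_spec(n_species = 15,
                                        synonym_fraction = 0, seed = 2))
  expect_true(all(tax$records$taxonomicStatus == "accepted"))
})

test_that("generated taxonomies load with zero validation errors", {
  for (seed in c(1, 99)) {
    fx <- make_fixture_db(fixture_spec(n_species = 30,
                                       synonym_fraction = 0.3,
                                       infraspecific_fraction = 0.2,
                                       homonym_pairs = 1, seed = seed))
    expect_s3_class(fx$db, "taxon_db")
  }
})

test_that("impossible homonym counts are refused", {
  expect_error(fixture_spec(n_species = 4, homonym_pairs = 3),
               "homonym_pairs")
})

test_that("an all-zero corruption profile returns the name unchanged", {
  tax <- generate_taxonomy(fixture_spec(n_species = 10, seed = 8))
  sp <- tax$records[tax$records$taxonRank == "species", ][1, ]
  zero <- corruption_profile(substitute = 0, insert = 0, delete = 0,
                             transpose = 0, block_transpose = 0,
                             ending_swap = 0, all_caps = 0,
                             prepend_family = 0, append_annotation = 0,
                             append_morphospecies = 0)
  q <- corrupt_name(sp, zero, seed = 4)
  expect_equal(q$raw, sp$scientificName)
  expect_equal(q$intended_ed, 0L)
  expect_length(q$applied_operations, 0)
})

test_that("recorded edit distances equal recomputation on the components", {
  tax <- generate_taxonomy(fixture_spec(n_species = 12, seed = 19))
  sp <- tax$records[tax$records$taxonRank == "species", ]
  profile <- corruption_profile(substitute = 1, insert = 0.5, delete = 0,
                                transpose = 0, block_transpose = 0,
                                ending_swap = 0, all_caps = 0,
                                prepend_family = 0, append_annotation = 0,
                                append_morphospecies = 0)
  for (i in seq_len(6)) {
    q <- corrupt_name(sp[i, , drop = FALSE], profile, seed = i * 7)
    true_parts <- strsplit(sp$scientificName[i], " ")[[1]]
    got_parts <- strsplit(q$raw, " ")[[1]]
    expect_equal(q$intended_ed,
                 sum(mdld(true_parts, got_parts)), info = q$raw)
    expect_gte(q$intended_ed, 1L)
  }
})

test_that("ending swaps stay phonetically equal at nonzero edit distance", {
  tax <- generate_taxonomy(fixture_spec(n_species = 10, seed = 23))
  sp <- tax$records[tax$records$taxonRank == "species", ]
  profile <- corruption_profile(substitute = 0, insert = 0, delete = 0,
                                transpose = 0, block_transpose = 0,
                                ending_swap = 1, all_caps = 0,
                                prepend_family = 0, append_annotation = 0,
                                append_morphospecies = 0)
  hits <- 0
  for (i in seq_len(nrow(sp))) {
    q <- corrupt_name(sp[i, , drop = FALSE], profile, seed = i)
    ep_true <- strsplit(sp$scientificName[i], " ")[[1]][2]
    ep_got <- strsplit(q$raw, " ")[[1]][2]
    expect_equal(phonetic_key(ep_got, epithet = TRUE),
                 phonetic_key(ep_true, epithet = TRUE))
    if (ep_got != ep_true) hits <- hits + 1
  }
  expect_gt(hits, 0)
})

test_that("homonyms are ambiguous without a family and resolve with one", {
  fx <- make_fixture_db(fixture_spec(n_families = 3, n_genera = 6,
                                     n_species = 18, homonym_pairs = 1,
                                     synonym_fraction = 0, seed = 37))
  rec <- fx$tax$records
  dup <- rec[rec$taxonID == "hs1", ]
  bare <- resolve_names(dup$scientificName, fx$db)$results[[1]]
  expect_true("ambiguous_match" %in% bare$warnings)
  hinted <- resolve_names(paste(dup$family, dup$scientificName),
                          fx$db)$results[[1]]
  expect_false("ambiguous_match" %in% hinted$warnings)
  expect_equal(hinted$best_unconstrained$reference$family, dup$family)
})
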