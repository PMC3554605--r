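test_that("the maximum-ED budget scales with the number of name parts", {
  expect_true(max_ed_test(4, 2))   # binomial budget is 4
  expect_false(max_ed_test(5, 2))
  expect_true(max_ed_test(6, 3))   # varietal budget is 6
  expect_false(max_ed_test(7, 3))
  expect_true(max_ed_test(0, 1))
})

test_that("the threshold test applies the length-scaled ratio and anchors", {
  expect_true(threshold_test(2, 8, "Marsilleya", "Marsilea"))  # 0.25 <= 0.3334
  expect_true(threshold_test(2, 4, "Ulleya", "Ulea"))          # 0.5 at MSL < 6
  p_strict <- scoring_params(maxedr_short = 0.3334)
  expect_false(threshold_test(2, 4, "Ulleya", "Ulea", p_strict))
  expect_true(threshold_test(0, 3, "Poa", "Poa"))
  expect_true(threshold_test(1, 4, "Pooa", "Poa"))
  # first-character anchoring for ED 2-3, three characters for ED 4
  expect_false(threshold_test(2, 8, "Xarsillea", "Marsilea"))
  expect_true(threshold_test(4, 12, "marsileaceae", "marsilallceae"))
  expect_false(threshold_test(4, 12, "maxsileaceae", "mabsilallceae"))
  expect_false(threshold_test(5, 20, "aaaaaaaaaaaaaaaaaaaa",
                              "aaaaaaaaaaaaaaabbbbb"))
})

test_that("search finds both the cross-genus species and the exact genus", {
  db <- load_exchange_file(system.file("extdata", "example_taxonomy.tsv",
                                       package = "taxresolve"), "demo")
  cands <- hierarchical_search(parse_name("Fucus insipida"), db)
  canon <- vapply(cands, function(x) x$reference$canonical, character(1))
  expect_true("Ficus insipida" %in% canon)
  expect_true("Fucus" %in% canon)
  ficus <- cands[[which(canon == "Ficus insipida")]]
  expect_equal(ficus$components$ed[ficus$components$component == "genus"],
               1L)
})

test_that("an exact stored binomial yields an all-zero-ED candidate", {
  db <- load_exchange_file(system.file("extdata", "example_taxonomy.tsv",
                                       package = "taxresolve"), "demo")
  cands <- hierarchical_search(parse_name("Bromus inermis"), db)
  canon <- vapply(cands, function(x) x$reference$canonical, character(1))
  hit <- cands[[which(canon == "Bromus inermis")]]
  expect_true(all(hit$components$ed == 0))
  expect_true(hit$passed_phonetic && hit$passed_threshold &&
                hit$passed_max_ed)
  expect_false(hit$is_partial)
})

test_that("retention needs the ED budget plus phonetic or threshold", {
  db <- load_exchange_file(system.file("extdata", "example_taxonomy.tsv",
                                       package = "taxresolve"), "demo")
  # 5 edits on a binomial: outside the budget, no candidate at species rank
  cands <- hierarchical_search(parse_name("Bromus ixxxxxs"), db)
  canon <- vapply(cands, function(x) x$reference$canonical, character(1))
  expect_false("Bromus inermis" %in% canon)
  # gender-swapped epithet: phonetic equality rescues a nonzero ED
  cands2 <- hierarchical_search(parse_name("Poa annuus"), db)
  canon2 <- vapply(cands2, function(x) x$reference$canonical, character(1))
  expect_true("Poa annua" %in% canon2)
  hit <- cands2[[which(canon2 == "Poa annua")]]
  expect_true(hit$passed_phonetic)
})

test_that("a submitted family restricts candidate genera and resolves homonyms", {
  fx <- make_fixture_db(fixture_spec(n_families = 3, n_genera = 6,
                                     n_species = 18, homonym_pairs = 2,
                                     seed = 31))
  db <- fx$db
  rec <- fx$tax$records
  dup <- rec[startsWith(rec$taxonID, "hs"), ][1, ]
  plain <- parse_name(dup$scientificName)
  both <- hierarchical_search(plain, db)
  ids <- vapply(both, function(x) x$name_id, character(1))
  expect_gte(sum(rec$scientificName[match(ids, rec$taxonID)] ==
                   dup$scientificName), 2)
  withfam <- parse_name(paste(dup$family, dup$scientificName))
  onefam <- hierarchical_search(withfam, db)
  fams <- vapply(onefam, function(x) x$reference$family, character(1))
  expect_true(all(fams == dup$family))
})

test_that("genus-first search equals whole-database brute force", {
  set.seed(100)
  for (rep in 1:6) {
    spec <- fixture_spec(n_families = sample(2:4, 1),
                         n_genera = sample(4:10, 1),
                         n_species = sample(20:60, 1),
                         infraspecific_fraction = 0.2,
                         homonym_pairs = sample(0:2, 1),
                         seed = 500 + rep)
    fx <- make_fixture_db(spec)
    sp <- fx$tax$records[fx$tax$records$taxonRank == "species", ]
    queries <- c(
      sp$scientificName[1],
      corrupt_name(sp[2, , drop = FALSE],
                   corruption_profile(substitute = 1, transpose = 1,
                                      all_caps = 0, prepend_family = 0,
                                      append_annotation = 0,
                                      append_morphospecies = 0,
                                      ending_swap = 0, insert = 0,
                                      delete = 0, block_transpose = 0),
                   seed = rep)$raw,
      sub(" .*$", "", sp$scientificName[3])
    )
    for (q in queries) {
      parsed <- parse_name(q)
      got <- sort(vapply(hierarchical_search(parsed, fx$db),
                         function(x) x$name_id, character(1)))
      want <- brute_force_candidates(parsed, fx$db)
      expect_equal(got, want, info = paste("seed", 500 + rep, "query", q))
    }
  }
})
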