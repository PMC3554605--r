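example_db <- function() {
  load_exchange_file(system.file("extdata", "example_taxonomy.tsv",
                                 package = "taxresolve"), "demo")
}

test_that("ranking prefers accepted status and breaks ties alphabetically", {
  db <- example_db()
  parsed <- parse_name("Poa annua")
  cands <- lapply(hierarchical_search(parsed, db), score_candidate)
  # synthetic tie: give two candidates identical scores, different status
  syn <- cands[[1]]; acc <- cands[[1]]
  syn$reference$status <- "synonym"; syn$name_id <- "zz"
  syn$reference$canonical <- "Aaa aaa"
  r <- rank_unconstrained(list(syn, acc))
  expect_equal(r$cands[[1]]$reference$status, "accepted")
  expect_false(r$ambiguous)
  # same status and scores: alphabetical head plus ambiguity
  syn2 <- acc; syn2$name_id <- "zz2"; syn2$reference$canonical <- "Aaa aaa"
  r2 <- rank_unconstrained(list(acc, syn2))
  expect_equal(r2$cands[[1]]$reference$canonical, "Aaa aaa")
  expect_true(r2$ambiguous)
  r3 <- rank_unconstrained(list(acc))
  expect_false(r3$ambiguous)
})

test_that("both ranking modes and all four warnings fire on Fucus insipida", {
  db <- example_db()
  res <- resolve_names("Fucus insipida", db)$results[[1]]
  expect_equal(res$best_unconstrained$reference$canonical, "Ficus insipida")
  expect_equal(round(res$best_unconstrained$scores$oms, 2), 0.96)
  expect_equal(res$best_constrained$reference$canonical, "Fucus")
  expect_equal(res$best_constrained$scores$oms, 0.5)
  expect_setequal(res$warnings_unconstrained,
                  "better_higher_taxonomic_match_available")
  expect_setequal(res$warnings_constrained,
                  c("partial_match",
                    "better_spelling_match_in_different_higher_taxon"))
  # active-mode selection follows the setting
  con <- resolve_names("Fucus insipida", db,
                       settings = run_settings(
                         constrain_by_higher_taxonomy = TRUE))$results[[1]]
  expect_equal(con$status_of_match, "accepted")
  expect_setequal(con$warnings, res$warnings_constrained)
})

test_that("an exact accepted binomial resolves cleanly", {
  db <- example_db()
  res <- resolve_names("Poa annua", db)$results[[1]]
  expect_equal(res$best_unconstrained$scores$oms, 1)
  expect_equal(res$status_of_match, "accepted")
  expect_length(res$warnings, 0)
})

test_that("a stored synonym carries its accepted name", {
  db <- example_db()
  res <- resolve_names("Poa supina", db)$results[[1]]
  expect_equal(res$status_of_match, "synonym")
  expect_equal(res$accepted$canonical, "Poa annua")
  expect_equal(res$best_unconstrained$scores$oms, 1)
})

test_that("misspelled genus with exact epithet: constrained mode flips the best", {
  fx <- make_fixture_db(fixture_spec(n_genera = 6, n_species = 18,
                                     seed = 41))
  sp <- fx$tax$records[fx$tax$records$taxonRank == "species", ][1, ]
  parts <- strsplit(sp$scientificName, " ")[[1]]
  bad_genus <- paste0(substr(parts[1], 1, nchar(parts[1]) - 2), "xz")
  q <- paste(bad_genus, parts[2])
  res <- resolve_names(q, fx$db)$results[[1]]
  expect_equal(res$best_unconstrained$name_id, sp$taxonID)
  con_best <- res$best_constrained
  g_pms_con <- con_best$scores$pms["genus"]
  g_pms_un <- res$best_unconstrained$scores$pms["genus"]
  expect_gte(g_pms_con, g_pms_un)
})

test_that("source priority partitions the ranking stably", {
  db <- example_db()
  parsed <- parse_name("Poa annua")
  cands <- lapply(hierarchical_search(parsed, db), score_candidate)
  expect_identical(rank_by_source(cands, "demo"), cands)  # single source
  a <- cands[[1]]; b <- cands[[1]]
  a$source_id <- "low"; a$name_id <- "a"
  b$source_id <- "high"; b$name_id <- "b"
  b$scores$oms <- 0.2  # low score in the priority source still wins
  out <- rank_by_source(list(a, b), c("high", "low"))
  expect_equal(out[[1]]$name_id, "b")
  expect_identical(rank_by_source(list(), c("x", "y")), list())
})

test_that("toggling constrain-by-source with one source is a no-op", {
  db <- example_db()
  r1 <- as.data.frame(resolve_names(c("Fucus insipida", "Poa anua"), db))
  r2 <- as.data.frame(resolve_names(
    c("Fucus insipida", "Poa anua"), db,
    settings = run_settings(constrain_by_source = TRUE)))
  expect_equal(r1, r2)
})

test_that("candidate order never affects the chosen best match", {
  db <- example_db()
  parsed <- parse_name("Fucus insipida")
  cands <- lapply(hierarchical_search(parsed, db), score_candidate)
  set.seed(1)
  for (i in 1:5) {
    perm <- sample(cands)
    expect_equal(rank_unconstrained(perm)$cands[[1]]$name_id,
                 rank_unconstrained(cands)$cands[[1]]$name_id)
    expect_equal(rank_constrained(perm)$cands[[1]]$name_id,
                 rank_constrained(cands)$cands[[1]]$name_id)
  }
})

test_that("the unconstrained best never scores below the constrained best", {
  fx <- make_fixture_db(fixture_spec(n_species = 30, seed = 51))
  queries <- make_query_set(fx$tax, 20,
                            corruption_profile(all_caps = 0,
                                               prepend_family = 0.3),
                            seed = 6)
  res <- resolve_names(queries[, c("id", "name")], fx$db)
  for (r in res$results) {
    if (!is.null(r$best_unconstrained) && !is.null(r$best_constrained)) {
      expect_gte(r$best_unconstrained$scores$oms,
                 r$best_constrained$scores$oms - 1e-9)
    }
  }
})

test_that("partial matches can be disabled and min_oms filters candidates", {
  db <- example_db()
  off <- resolve_names("Fucus insipida", db,
                       settings = run_settings(allow_partial = FALSE))
  alts <- off$results[[1]]$alternatives
  expect_false(any(vapply(alts, function(x) x$is_partial, logical(1))))
  high <- resolve_names("Fucus insipida", db,
                        settings = run_settings(min_oms = 0.9))
  alts2 <- high$results[[1]]$alternatives
  expect_true(all(vapply(alts2, function(x) x$scores$oms, numeric(1)) >=
                    0.9))
})

test_that("family-only submissions resolve to the family record", {
  fx <- make_fixture_db(fixture_spec(n_species = 10, seed = 61))
  fam <- fx$tax$records$scientificName[fx$tax$records$taxonRank ==
                                         "family"][1]
  res <- resolve_names(paste(fam, "Indet. sp. 21"), fx$db)$results[[1]]
  expect_false(is.null(res$best_unconstrained))
  expect_equal(res$best_unconstrained$reference$canonical, fam)
  expect_equal(res$best_unconstrained$reference$rank, "family")
})

test_that("an empty query list returns an empty result set", {
  db <- example_db()
  res <- resolve_names(character(0), db)
  expect_length(res$results, 0)
  expect_equal(nrow(as.data.frame(res)), 0)
})
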