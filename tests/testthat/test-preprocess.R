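test_that("pre-pended families are stripped, conserved names included", {
  expect_equal(strip_family("Fabaceae Indet. sp. 21"),
               list(family = "Fabaceae", remainder = "Indet. sp. 21"))
  expect_equal(strip_family("Poa annua"),
               list(family = "", remainder = "Poa annua"))
  expect_equal(strip_family("Compositae Aster cordifolius")$family,
               "Compositae")
  expect_equal(strip_family("FABACEAE Inga edulis")$family, "Fabaceae")
})

test_that("annotations and morphospecies codes are removed and recorded", {
  r <- remove_annotations("Poa cf. annua")
  expect_equal(r$cleaned, "Poa annua")
  expect_equal(r$removed, "cf.")
  r2 <- remove_annotations("Fabaceae sp. 21")
  expect_equal(r2$cleaned, "Fabaceae")
  expect_equal(r2$removed, c("sp.", "21"))
  expect_equal(remove_annotations("Poa annua"),
               list(cleaned = "Poa annua", removed = character(0)))
  r3 <- remove_annotations("Poa sp. nova")
  expect_equal(r3$cleaned, "Poa")
  r4 <- remove_annotations("Poa aff. annua s.l.")
  expect_equal(r4$cleaned, "Poa annua")
  expect_equal(r4$removed, c("aff.", "s.l."))
})

test_that("only all-caps input has its case adjusted", {
  expect_equal(normalize_case("QUERCUS ALBA"), "Quercus alba")
  expect_equal(normalize_case("Quercus alba"), "Quercus alba")
  expect_equal(normalize_case("QUERCUS Alba"), "QUERCUS Alba")
})

test_that("the pipeline composes family stripping, annotations and case", {
  pp <- preprocess("FABACEAE CF. INGA EDULIS")
  expect_equal(pp$family_prefix, "Fabaceae")
  expect_equal(pp$cleaned, "Inga edulis")
  expect_true(pp$was_all_caps)
  expect_equal(tolower(pp$removed_annotations), "cf.")
})

test_that("phylogeny tip labels lose underscores and accession codes", {
  pp <- preprocess("Poa_annua_AB123")
  expect_equal(pp$cleaned, "Poa annua")
  expect_true("AB123" %in% pp$removed_annotations)
})

test_that("names that clean to nothing are degenerate", {
  pp <- preprocess("Indet. sp.")
  expect_true(pp$degenerate)
  expect_equal(pp$family_prefix, "")
  pp2 <- preprocess("Fabaceae Indet. sp. 21")
  expect_true(pp2$degenerate)
  expect_equal(pp2$family_prefix, "Fabaceae")
})

test_that("a verbatim stored name short-circuits with an exact hit", {
  tsv <- system.file("extdata", "example_taxonomy.tsv",
                     package = "taxresolve")
  db <- load_exchange_file(tsv, "demo")
  pp <- preprocess("Poa annua", db)
  expect_false(is.null(pp$exact_hit))
  expect_equal(pp$exact_hit$name_id[1], "s2")
  # with author appended the full string still matches
  pp2 <- preprocess("Poa annua L.", db)
  expect_false(is.null(pp2$exact_hit))
  # near miss does not
  expect_null(preprocess("Poa annuaa", db)$exact_hit)
})

test_that("preprocessing is idempotent on its own output", {
  inputs <- c("FABACEAE CF. INGA EDULIS", "Poa cf. annua",
              "Poa_annua_AB123", "Gramineae POA ANNUA sp. 2")
  for (raw in inputs) {
    pp <- preprocess(raw)
    pp2 <- preprocess(pp$cleaned)
    expect_equal(pp2$cleaned, pp$cleaned, info = raw)
    expect_equal(pp2$family_prefix, "", info = raw)
    expect_length(pp2$removed_annotations, 0)
  }
})

test_that("generator-built messy queries clean back to the true name", {
  fx <- make_fixture_db(fixture_spec(n_species = 15, seed = 21))
  sp <- fx$tax$records[fx$tax$records$taxonRank == "species", ]
  profile <- corruption_profile(substitute = 0, insert = 0, delete = 0,
                                transpose = 0, block_transpose = 0,
                                ending_swap = 0, all_caps = 1,
                                prepend_family = 1, append_annotation = 1,
                                append_morphospecies = 1)
  for (i in seq_len(5)) {
    q <- corrupt_name(sp[i, , drop = FALSE], profile, seed = i)
    pp <- preprocess(q$raw)
    expect_equal(tolower(pp$cleaned), tolower(sp$scientificName[i]),
                 info = q$raw)
  }
})
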