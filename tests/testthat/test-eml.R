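fixture_eml <- system.file("extdata", "synthetic-eml-sample.xml",
                           package = "qudtmapper")

test_that("unit occurrences are extracted in document order", {
  occ <- extract_units(fixture_eml)
  expect_equal(nrow(occ), 2)  # three attributes, two with units
  expect_identical(occ$raw_unit, c("meter", "micromolesPerLiter"))
  expect_identical(occ$unit_kind, c("standardUnit", "customUnit"))
  expect_identical(occ$attribute_id, c("att.depth", "att.po4"))

  none <- write_eml_fixture(list())
  expect_equal(nrow(extract_units(none)), 0)
})

test_that("non-EML and pre-2.2 documents are rejected", {
  f <- tempfile(fileext = ".xml")
  writeLines("<notEml><x/></notEml>", f)
  expect_error(extract_units(f), "EML namespace")

  writeLines(paste0(
    '<eml:eml xmlns:eml="eml://ecoinformatics.org/eml-2.1.1" ',
    'packageId="p.1.1" system="s"><dataset/></eml:eml>'), f)
  expect_error(extract_units(f), "2.2")
})

test_that("annotation adds the QUDT triple for resolvable units", {
  res <- annotate_document(fixture_eml, fx_table, fx_vocab,
                           fx_pseudo, fx_qudt)
  expect_identical(res$report$matched, c(TRUE, TRUE))
  expect_identical(res$report$qudt_code, c("M", "MicroMOL-PER-L"))
  vals <- xml2::xml_find_all(res$doc, "//*[local-name()='valueURI']")
  expect_identical(
    xml2::xml_text(vals)[2],
    "http://qudt.org/vocab/unit/MicroMOL-PER-L")
  expect_true(all(nzchar(xml2::xml_attr(vals, "label"))))
  props <- xml2::xml_find_all(res$doc, "//*[local-name()='propertyURI']")
  expect_true(all(grepl("^https?://", xml2::xml_text(props))))
})

test_that("annotation is idempotent and the source is untouched", {
  before <- readLines(fixture_eml)
  res1 <- annotate_document(fixture_eml, fx_table, fx_vocab,
                            fx_pseudo, fx_qudt)
  res2 <- annotate_document(res1$doc, fx_table, fx_vocab,
                            fx_pseudo, fx_qudt)
  n1 <- length(xml2::xml_find_all(res1$doc, "//*[local-name()='annotation']"))
  n2 <- length(xml2::xml_find_all(res2$doc, "//*[local-name()='annotation']"))
  expect_equal(n1, 2)
  expect_equal(n2, 2)  # second run adds zero elements
  expect_identical(readLines(fixture_eml), before)
})

test_that("annotated output stays valid against the bundled subset schema", {
  expect_true(eml_validate_subset(fixture_eml))
  res <- annotate_document(fixture_eml, fx_table, fx_vocab,
                           fx_pseudo, fx_qudt)
  ok <- eml_validate_subset(res$doc)
  expect_true(ok, info = paste(attr(ok, "errors"), collapse = "; "))
  twice <- annotate_document(res$doc, fx_table, fx_vocab,
                             fx_pseudo, fx_qudt)
  expect_true(eml_validate_subset(twice$doc))
})

test_that("junk-only documents yield no annotations but a full report", {
  f <- write_eml_fixture(list(odd = c("customUnit", "martha stewart"),
                              odd2 = c("customUnit", "-9999")))
  res <- annotate_document(f, fx_table, fx_vocab, fx_pseudo, fx_qudt)
  expect_equal(length(xml2::xml_find_all(res$doc,
               "//*[local-name()='annotation']")), 0)
  expect_identical(res$report$matched, c(FALSE, FALSE))
  expect_identical(res$report$match_path, c("unmatched", "unmatched"))
})

test_that("revision bumping and id generation behave per contract", {
  f <- write_eml_fixture(list(depth = c("standardUnit", "meter")),
                         package_id = "knb-synth.12.7")
  res <- annotate_document(f, fx_table, fx_vocab, fx_pseudo, fx_qudt,
                           bump_revision = TRUE)
  expect_identical(xml2::xml_attr(res$doc, "packageId"), "knb-synth.12.8")

  f2 <- write_eml_fixture(list(depth = c("standardUnit", "meter")),
                          package_id = "no-revision-here")
  expect_error(annotate_document(f2, fx_table, fx_vocab, fx_pseudo,
                                 fx_qudt, bump_revision = TRUE),
               "revision")

  # without ids annotation is skipped; with add_ids it is deterministic
  f3 <- write_eml_fixture(list(depth = c("standardUnit", "meter")),
                          with_ids = FALSE)
  res3 <- annotate_document(f3, fx_table, fx_vocab, fx_pseudo, fx_qudt)
  expect_match(res3$report$note, "no id")
  resa <- annotate_document(f3, fx_table, fx_vocab, fx_pseudo, fx_qudt,
                            add_ids = TRUE)
  resb <- annotate_document(f3, fx_table, fx_vocab, fx_pseudo, fx_qudt,
                            add_ids = TRUE)
  expect_identical(as.character(resa$doc), as.character(resb$doc))
  expect_identical(resa$report$attribute_id, "attr1")
})
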