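test_that("json, xml and html renderings carry the same field values", {
  for (fmt in c("json", "xml", "html")) {
    resp <- handle_lookup("g/m2", fmt, fx_table, fx_vocab,
                          fx_pseudo, fx_qudt)
    expect_equal(resp$status, 200L)
    expect_true(resp$fields$matched)
    expect_identical(resp$fields$qudt_code, "GM-PER-M2")
    expect_true(grepl("GM-PER-M2", resp$body, fixed = TRUE))
  }
  j <- handle_lookup("g/m2", "json", fx_table, fx_vocab,
                     fx_pseudo, fx_qudt)
  parsed <- jsonlite::fromJSON(j$body)
  expect_true(endsWith(parsed$uri, "/GM-PER-M2"))
  expect_identical(parsed$label, "gram per square metre")
  expect_true(grepl("<annotation>", parsed$annotation, fixed = TRUE))
  expect_identical(j$content_type, "application/json")
})

test_that("unmatched queries and client errors are reported cleanly", {
  resp <- handle_lookup("martha stewart", "json", fx_table, fx_vocab,
                        fx_pseudo, fx_qudt)
  expect_equal(resp$status, 200L)
  expect_false(resp$fields$matched)
  expect_null(resp$fields$qudt_code)

  bad <- handle_lookup("g/m2", "yaml", fx_table, fx_vocab,
                       fx_pseudo, fx_qudt)
  expect_equal(bad$status, 400L)
  expect_match(bad$fields$error, "json, xml, html")

  empty <- handle_lookup("", "json", fx_table, fx_vocab,
                         fx_pseudo, fx_qudt)
  expect_equal(empty$status, 400L)
  expect_match(empty$fields$error, "rawunit")
})

test_that("HTTP GET request lines parse into path and query parameters", {
  p <- qudtmapper:::parse_http_request(
    "GET /unitsws?rawunit=g%2Fm2&returntype=json HTTP/1.1")
  expect_identical(p$path, "/unitsws")
  expect_identical(p$params$rawunit, "g/m2")
  expect_identical(p$params$returntype, "json")

  p <- qudtmapper:::parse_http_request("GET /lookup?rawunit=martha+stewart HTTP/1.1")
  expect_identical(p$params$rawunit, "martha stewart")

  expect_null(qudtmapper:::parse_http_request("POST / HTTP/1.1"))
  expect_null(qudtmapper:::parse_http_request(""))
})

test_that("cli map, normalize and convert print the documented results", {
  out <- capture.output(status <- units_cli(c("map", "g m-2")))
  expect_equal(status, 0L)
  expect_identical(out, "GM-PER-M2")

  out <- capture.output(status <- units_cli(c("normalize", "g/m^2")))
  expect_identical(out, "grampermetersquared")

  out <- capture.output(status <- units_cli(
    c("convert", "0", "--from", "DEG_C", "--to", "K")))
  expect_equal(status, 0L)
  expect_equal(as.numeric(out), 273.15)

  expect_equal(suppressMessages(units_cli(c("frobnicate"))), 1L)
  expect_equal(suppressMessages(units_cli(character(0))), 1L)
  expect_equal(suppressMessages(units_cli(
    c("convert", "1", "--from", "M", "--to", "SEC"))), 1L)
})

test_that("cli simulate is reproducible and stats reads its output", {
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  expect_equal(suppressMessages(units_cli(
    c("simulate", "--seed", "9", "--n", "60", "--out", f1))), 0L)
  expect_equal(suppressMessages(units_cli(
    c("simulate", "--seed", "9", "--n", "60", "--out", f2))), 0L)
  expect_identical(readLines(f1), readLines(f2))

  out <- capture.output(status <- units_cli(c("stats", "--corpus", f1)))
  expect_equal(status, 0L)
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(parsed$n_distinct, 60)
  expect_gte(parsed$instance_fraction_pct, 90)
})

test_that("cli build-table and resolve work against a serialized table", {
  tabf <- tempfile(fileext = ".tsv")
  expect_equal(suppressMessages(units_cli(
    c("build-table", "--out", tabf))), 0L)
  expect_true(file.exists(tabf))
  out <- capture.output(status <- units_cli(
    c("resolve", "g/m2", "--table", tabf)))
  expect_equal(status, 0L)
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_identical(parsed$qudt_code, "GM-PER-M2")
})
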