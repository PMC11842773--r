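test_that("a vocabulary-only table has one code row per unit and long UCUM rows", {
  n_units <- nrow(fx_vocab$units)
  n_long_ucum <- sum(nchar(names(fx_vocab$ucum_index)) > 2)
  kinds <- table(fx_table$records$key_kind)
  expect_equal(as.integer(kinds[["qudt_code"]]), n_units)
  expect_equal(as.integer(kinds[["ucum"]]), n_long_ucum)
  expect_false("raw" %in% names(kinds))
  # two-character UCUM aliases are deliberately excluded as ambiguous
  expect_false(any(nchar(fx_table$records$key[
    fx_table$records$key_kind == "ucum"]) <= 2))
})

test_that("corpus raw units land in the table with use counts, junk in the sidecar", {
  corpus <- data.frame(raw = c("g/m2", "g/m2", "martha stewart"),
                       org = c("EDI", "NEON", "EDI"),
                       n_uses = c(5L, 2L, 1L))
  tab <- build_lookup_table(corpus, fx_vocab, fx_pseudo, fx_qudt)
  raw_rows <- tab$records[tab$records$key_kind == "raw", ]
  expect_equal(nrow(raw_rows), 1)
  expect_identical(raw_rows$qudt_code, "GM-PER-M2")
  expect_equal(raw_rows$n_uses, 7L)  # pooled across organizations
  ps_rows <- tab$records[tab$records$key_kind == "pseudounit", ]
  expect_identical(ps_rows$key, "grampermetersquared")
  expect_equal(nrow(tab$unmatched), 1)
  expect_identical(tab$unmatched$key, "martha stewart")
})

test_that("each raw form keeps its own row even when pseudounits coincide", {
  corpus <- data.frame(raw = c("g/m2", "g m-2"), org = "EDI",
                       n_uses = c(3L, 2L))
  tab <- build_lookup_table(corpus, fx_vocab, fx_pseudo, fx_qudt)
  raw_rows <- tab$records[tab$records$key_kind == "raw", ]
  expect_equal(nrow(raw_rows), 2)
  expect_setequal(raw_rows$n_uses, c(3L, 2L))
  expect_equal(sum(tab$records$key_kind == "pseudounit"), 1)
})

test_that("resolution walks raw, code, ucum, then rewrite, first hit winning", {
  corpus <- data.frame(raw = "gramPerMeterSquared", org = "EDI", n_uses = 4L)
  tab <- build_lookup_table(corpus, fx_vocab, fx_pseudo, fx_qudt)

  r <- resolve("gramPerMeterSquared", tab, fx_vocab, fx_pseudo, fx_qudt)
  expect_identical(r$match_path, "direct_raw")
  expect_identical(r$matched_unit$code, "GM-PER-M2")

  r <- resolve("GM-PER-M2", tab, fx_vocab, fx_pseudo, fx_qudt)
  expect_identical(r$match_path, "direct_qudt_code")

  r <- resolve("kPa", tab, fx_vocab, fx_pseudo, fx_qudt)
  expect_identical(r$match_path, "ucum")
  expect_identical(r$matched_unit$code, "KiloPA")

  # not a key of any kind, but the rewrite pipeline gets there
  r <- resolve("grams per square meter", tab, fx_vocab, fx_pseudo, fx_qudt)
  expect_identical(r$match_path, "rewritten")
  expect_identical(r$matched_unit$code, "GM-PER-M2")

  r <- resolve("atlantis/alvin", tab, fx_vocab, fx_pseudo, fx_qudt)
  expect_identical(r$match_path, "unmatched")
})

test_that("every key already in the table resolves to its own code", {
  corpus <- data.frame(raw = c("g/m2", "mg/L", "celsius", "°C"),
                       org = "EDI", n_uses = 1L)
  tab <- build_lookup_table(corpus, fx_vocab, fx_pseudo, fx_qudt)
  for (i in seq_len(nrow(tab$records))) {
    r <- resolve(tab$records$key[i], tab, fx_vocab, fx_pseudo, fx_qudt)
    expect_identical(r$matched_unit$code, tab$records$qudt_code[i],
                     info = paste(tab$records$key_kind[i],
                                  tab$records$key[i]))
  }
})

test_that("table build and serialization are deterministic", {
  corpus <- data.frame(raw = c("g/m2", "junkword"), org = "EDI",
                       n_uses = c(2L, 1L))
  f1 <- tempfile(); f2 <- tempfile()
  write_lookup_table(build_lookup_table(corpus, fx_vocab, fx_pseudo,
                                        fx_qudt), f1)
  write_lookup_table(build_lookup_table(corpus, fx_vocab, fx_pseudo,
                                        fx_qudt), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and the round trip through text preserves the records
  back <- read_lookup_table(f1)
  expect_equal(nrow(back$records),
               nrow(build_lookup_table(corpus, fx_vocab)$records))
  r <- resolve("g/m2", back, fx_vocab, fx_pseudo, fx_qudt)
  expect_identical(r$matched_unit$code, "GM-PER-M2")
})

test_that("compatibility is exact dimension-vector equality", {
  u <- function(code) vocab_unit(fx_vocab, code)
  expect_true(compatible(u("GM-PER-M2"), u("KiloGM-PER-HA")))
  expect_false(compatible(u("MilliGM-PER-L"), u("MilliMOL-PER-L")))
  expect_true(compatible(u("M"), u("M")))

  nodv <- u("M"); nodv$dimension_vector <- NULL
  expect_error(compatible(nodv, u("M")), "absent")
})

test_that("conversions follow the multiplier/offset model and round-trip", {
  u <- function(code) vocab_unit(fx_vocab, code)
  expect_equal(convert_value(1, u("M"), u("CentiM")), 100)
  expect_equal(convert_value(0, u("DEG_C"), u("K")), 273.15)
  expect_equal(convert_value(1, u("GM-PER-M2"), u("KiloGM-PER-HA")), 10)
  expect_equal(convert_value(32, u("DEG_F"), u("DEG_C")), 0,
               tolerance = 1e-12)
  expect_error(convert_value(1, u("MilliGM-PER-L"), u("MilliMOL-PER-L")),
               "dimension")

  # round-trip identity over every compatible fixture pair
  codes <- fx_vocab$units$code
  for (a in codes) for (b in codes) {
    ua <- u(a); ub <- u(b)
    if (compatible(ua, ub)) {
      x <- 3.7
      expect_equal(convert_value(convert_value(x, ua, ub), ub, ua), x,
                   tolerance = 1e-9, info = paste(a, "<->", b))
    }
  }
})
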