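test_that("corpus tabulation computes distinct counts and org overlap", {
  corpus <- data.frame(raw = c("m", "m", "x"), org = c("A", "B", "A"),
                       n_uses = c(3L, 2L, 1L))
  s <- tabulate_corpus(corpus)
  expect_equal(s$n_distinct, 2)
  expect_equal(s$total_instances, 6)
  expect_equal(s$overlap$n_distinct[s$overlap$n_orgs == 2], 1)
  expect_equal(s$overlap$n_instances[s$overlap$n_orgs == 2], 5)
  expect_equal(s$overlap$n_instances[s$overlap$n_orgs == 1], 1)

  s0 <- tabulate_corpus(data.frame(raw = character(0), org = character(0),
                                   n_uses = integer(0)))
  expect_equal(s0$n_distinct, 0)
  expect_equal(s0$total_instances, 0)

  ones <- data.frame(raw = letters[1:5], org = "A", n_uses = 1L)
  s1 <- tabulate_corpus(ones)
  expect_equal(s1$histogram$n_distinct[s1$histogram$bin == "1"], 5)
})

test_that("tabulation conservation identities hold on random corpora", {
  set.seed(2024)
  for (i in 1:20) {
    n <- sample(1:60, 1)
    corpus <- data.frame(
      raw = sample(c(letters, gm_per_m2_variants), n, replace = TRUE),
      org = sample(c("EDI", "NEON", "DataONE"), n, replace = TRUE),
      n_uses = sample(1:50, n, replace = TRUE))
    s <- tabulate_corpus(corpus)
    expect_equal(sum(s$overlap$n_distinct), s$n_distinct)
    expect_equal(sum(s$overlap$n_instances), s$total_instances)
    expect_equal(sum(s$histogram$n_distinct), s$n_distinct)
    expect_equal(sum(s$histogram$n_instances), s$total_instances)
    expect_equal(s$total_instances, sum(corpus$n_uses))
  }
})

test_that("match summary counts are bounded and consistent", {
  corpus <- data.frame(
    raw = c(rep("g/m2", 1), "m", "martha stewart", "4a"),
    org = "EDI", n_uses = c(900L, 10L, 1L, 1L))
  s <- match_summary(corpus, fx_vocab, fx_pseudo, fx_qudt)
  expect_equal(s$match$n_distinct_matched, 2)
  expect_equal(s$match$n_instances_matched, 910)
  expect_equal(s$match$distinct_fraction_pct, 50)
  expect_equal(s$match$instance_fraction_pct, round(100 * 910 / 912, 1))
  expect_lte(s$match$n_distinct_matched, s$n_distinct)

  empty <- match_summary(data.frame(raw = "zork", org = "A", n_uses = 1L),
                         fx_vocab, fx_pseudo, fx_qudt)
  expect_equal(empty$match$n_distinct_matched, 0)
})

test_that("the synthetic generator is seed-deterministic", {
  g1 <- generate_synthetic_corpus(synthetic_spec(seed = 11), fx_vocab)
  g2 <- generate_synthetic_corpus(synthetic_spec(seed = 11), fx_vocab)
  expect_identical(g1$corpus, g2$corpus)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_synthetic_corpus(synthetic_spec(seed = 12), fx_vocab)
  expect_false(identical(g1$corpus, g3$corpus))
})

test_that("junk_fraction zero yields only true units", {
  g <- generate_synthetic_corpus(
    synthetic_spec(seed = 1, n_distinct = 40, junk_fraction = 0), fx_vocab)
  expect_false(any(g$truth$code == "JUNK"))
  expect_true(all(g$truth$code %in% fx_vocab$units$code))
})

test_that("use counts are heavy-tailed: top 10 forms dominate instances", {
  g <- generate_synthetic_corpus(
    synthetic_spec(seed = 1, n_distinct = 200, zipf_exponent = 1.5),
    fx_vocab)
  uses <- sort(tapply(g$corpus$n_uses, g$corpus$raw, sum),
               decreasing = TRUE)
  expect_gte(sum(uses[1:10]) / sum(uses), 0.5)
})

test_that("the grammar's surface forms are unique and recovery is exact", {
  gram <- variant_grammar()
  expect_false(anyDuplicated(gram$form) > 0)
  expect_true(all(gram$code %in% fx_vocab$units$code))

  g <- generate_synthetic_corpus(synthetic_spec(seed = 3), fx_vocab)
  s <- match_summary(g$corpus, fx_vocab, fx_pseudo, fx_qudt)
  truth <- stats::setNames(g$truth$code, g$truth$raw)
  mc <- s$match$matched_codes
  # zero wrong codes: everything matched maps to its generating unit
  expect_true(all(truth[mc$raw] == mc$qudt_code))
  # junk never matches
  expect_false(any(truth[mc$raw] == "JUNK"))
  # instance match fraction is at least the non-junk share
  junk_uses <- sum(truth == "JUNK")  # junk entries are singletons
  expect_gte(s$match$n_instances_matched,
             s$total_instances - junk_uses)
})

test_that("skew makes the distinct fraction lag the instance fraction", {
  g <- generate_synthetic_corpus(
    synthetic_spec(seed = 5, junk_fraction = 0.1), fx_vocab)
  s <- match_summary(g$corpus, fx_vocab, fx_pseudo, fx_qudt)
  expect_lte(s$match$distinct_fraction_pct, s$match$instance_fraction_pct)
})

test_that("corpus files round-trip through their text serialization", {
  g <- generate_synthetic_corpus(synthetic_spec(seed = 2, n_distinct = 30),
                                 fx_vocab)
  f <- tempfile(fileext = ".tsv")
  write_corpus(g, f)
  back <- read_corpus(f)
  expect_equal(nrow(back), nrow(g$corpus))
  expect_identical(back$raw, g$corpus$raw)
  expect_equal(sum(back$n_uses), sum(g$corpus$n_uses))
  expect_true(file.exists(paste0(f, ".truth.tsv")))
})
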