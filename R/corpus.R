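#' Tabulate a raw-unit corpus
#'
#' Computes the corpus-level summaries: total instances, distinct units,
#' the frequency histogram of use counts (how many distinct units — and how
#' many instances — fall in each use-count bin, the two axes of the classic
#' skew plot), and the organization-overlap partition (how many distinct
#' units are used by 3, 2, or only 1 organization, and how many instances
#' each stratum accounts for). Distinct counting is exact-string.
#'
#' @param corpus Data frame with columns \code{raw}, \code{org},
#'   \code{n_uses} (each row: uses of one raw string by one organization).
#' @return A \code{corpus_stats} list: \code{total_instances},
#'   \code{n_distinct}, \code{unit_uses} (data frame raw, n_uses, n_orgs),
#'   \code{histogram} (data frame bin, n_distinct, n_instances),
#'   \code{overlap} (data frame n_orgs, n_distinct, n_instances).
#' @export
tabulate_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus),
            all(c("raw", "org", "n_uses") %in% names(corpus)))
  if (nrow(corpus) > 0 && any(corpus$n_uses < 1)) {
    stop("n_uses must be >= 1", call. = FALSE)
  }
  if (nrow(corpus) == 0) {
    return(structure(list(
      total_instances = 0L, n_distinct = 0L,
      unit_uses = data.frame(raw = character(0), n_uses = integer(0),
                             n_orgs = integer(0)),
      histogram = use_histogram(integer(0)),
      overlap = data.frame(n_orgs = integer(0), n_distinct = integer(0),
                           n_instances = integer(0))
    ), class = "corpus_stats"))
  }
  uses <- tapply(corpus$n_uses, corpus$raw, sum)
  orgs <- tapply(corpus$org, corpus$raw, function(v) length(unique(v)))
  unit_uses <- data.frame(raw = names(uses),
                          n_uses = as.integer(uses),
                          n_orgs = as.integer(orgs[names(uses)]),
                          stringsAsFactors = FALSE)
  unit_uses <- unit_uses[order(-unit_uses$n_uses, unit_uses$raw), ,
                         drop = FALSE]
  rownames(unit_uses) <- NULL
  ov <- lapply(sort(unique(unit_uses$n_orgs), decreasing = TRUE),
               function(k) {
    sel <- unit_uses$n_orgs == k
    data.frame(n_orgs = k, n_distinct = sum(sel),
               n_instances = sum(unit_uses$n_uses[sel]))
  })
  structure(list(
    total_instances = sum(unit_uses$n_uses),
    n_distinct = nrow(unit_uses),
    unit_uses = unit_uses,
    histogram = use_histogram(unit_uses$n_uses),
    overlap = do.call(rbind, ov)
  ), class = "corpus_stats")
}

# Distinct-unit and instance counts binned by number of uses.
use_histogram <- function(n_uses) {
  breaks <- c(0, 1, 2, 5, 10, 100, 1000, Inf)
  labels <- c("1", "2", "3-5", "6-10", "11-100", "101-1000", ">1000")
  bin <- cut(n_uses, breaks = breaks, labels = labels)
  data.frame(
    bin = labels,
    n_distinct = as.integer(table(factor(bin, levels = labels))),
    n_instances = as.integer(tapply(n_uses, factor(bin, levels = labels),
                                    sum, default = 0L)),
    stringsAsFactors = FALSE)
}

#' Corpus match summary against a vocabulary
#'
#' Resolves every distinct raw unit through the full pipeline and reports
#' how many distinct units — and how many unit uses (instances) — map to a
#' vocabulary unit. With a realistically skewed corpus the two fractions
#' differ sharply: most distinct units are rare junk, while the heavily
#' used units follow conventions the rules cover, so the instance fraction
#' far exceeds the distinct fraction.
#'
#' @param corpus Data frame with columns \code{raw}, \code{org},
#'   \code{n_uses}.
#' @param vocab A \code{qudt_vocabulary}.
#' @param pseudo_rules,qudt_rules Rule sets.
#' @return A \code{corpus_stats} with an additional \code{match} element:
#'   \code{n_distinct_matched}, \code{n_instances_matched},
#'   \code{distinct_fraction_pct}, \code{instance_fraction_pct} (fractions
#'   as percentages rounded to 0.1), and \code{matched_codes}, a data frame
#'   (raw, qudt_code, n_uses) for the matched distinct units.
#' @export
match_summary <- function(corpus, vocab = qudt_fixture_vocabulary(),
                          pseudo_rules = default_rules("pseudo"),
                          qudt_rules = default_rules("qudt")) {
  stats <- tabulate_corpus(corpus)
  uu <- stats$unit_uses
  codes <- rep(NA_character_, nrow(uu))
  if (nrow(uu) > 0) {
    ps <- to_pseudounit(uu$raw, pseudo_rules)
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(uu))) {
      p <- ps[i]
      if (!nzchar(p)) next
      if (is.null(cache[[p]])) {
        m <- map_pseudounit(p, qudt_rules, vocab)
        cache[[p]] <- if (m$match_path == "unmatched") NA_character_
                      else m$matched_unit$code
      }
      codes[i] <- cache[[p]]
    }
  }
  ok <- !is.na(codes)
  total <- stats$total_instances
  stats$match <- list(
    n_distinct_matched = sum(ok),
    n_instances_matched = sum(uu$n_uses[ok]),
    distinct_fraction_pct = if (stats$n_distinct > 0)
      round(100 * sum(ok) / stats$n_distinct, 1) else NA_real_,
    instance_fraction_pct = if (total > 0)
      round(100 * sum(uu$n_uses[ok]) / total, 1) else NA_real_,
    matched_codes = data.frame(raw = uu$raw[ok], qudt_code = codes[ok],
                               n_uses = uu$n_uses[ok],
                               stringsAsFactors = FALSE)
  )
  stats
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("<corpus: ", x$total_instances, " instances, ", x$n_distinct,
      " distinct units>\n", sep = "")
  if (!is.null(x$match)) {
    cat("  matched: ", x$match$n_distinct_matched, " distinct (",
        x$match$distinct_fraction_pct, "%), ",
        x$match$n_instances_matched, " instances (",
        x$match$instance_fraction_pct, "%)\n", sep = "")
  }
  invisible(x)
}

#' The synthetic corpus variant grammar
#'
#' The explicit, versioned table of surface forms the synthetic-corpus
#' generator can emit for each vocabulary unit: symbolic (\code{g/m2}),
#' exponent-style (\code{g m-2}), spelled-out (\code{grams per square
#' meter}), camelCase (\code{gramPerMeterSquared}) and a fixed set of
#' misspellings (cenimeter, celcius, cubitmeter). Every form is covered by
#' the default rule sets; the zero-mismatch recovery guarantee of the
#' generator is checkable against this table.
#'
#' @return Data frame with columns \code{code}, \code{form}, \code{style}.
#' @export
variant_grammar <- function() {
  g <- function(code, style, ...) {
    forms <- c(...)
    data.frame(code = code, form = forms, style = style,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    g("M", "symbolic", "m"), g("M", "spelled", "meter", "meters", "metre"),
    g("CentiM", "symbolic", "cm"),
    g("CentiM", "spelled", "centimeter", "centimeters", "centimetre"),
    g("CentiM", "misspelled", "cenimeter"),
    g("MilliM", "symbolic", "mm"),
    g("MilliM", "spelled", "millimeter", "millimetre"),
    g("MicroM", "symbolic", "um", "µm"),
    g("MicroM", "spelled", "micrometer"),
    g("KiloM", "symbolic", "km"),
    g("KiloM", "spelled", "kilometer", "kilometre"),
    g("M2", "symbolic", "m2", "m^2", "m²"),
    g("M2", "spelled", "square meters", "square meter"),
    g("M2", "camel", "squareMeter"),
    g("CentiM2", "symbolic", "cm2"),
    g("CentiM2", "spelled", "square centimeters"),
    g("KiloM2", "symbolic", "km2"),
    g("KiloM2", "spelled", "square kilometers"),
    g("HA", "symbolic", "ha"), g("HA", "spelled", "hectare", "hectares"),
    g("M3", "symbolic", "m3"), g("M3", "spelled", "cubic meters"),
    g("M3", "misspelled", "cubitmeter"),
    g("L", "symbolic", "l"),
    g("L", "spelled", "liter", "liters", "litre", "litres"),
    g("MilliL", "symbolic", "ml"),
    g("MilliL", "spelled", "milliliter", "milliliters"),
    g("MicroL", "symbolic", "ul", "µl"),
    g("MicroL", "spelled", "microliter"),
    g("KiloGM", "symbolic", "kg"),
    g("KiloGM", "spelled", "kilogram", "kilograms"),
    g("GM", "symbolic", "g", "gm"), g("GM", "spelled", "gram", "grams"),
    g("MilliGM", "symbolic", "mg"),
    g("MilliGM", "spelled", "milligram", "milligrams"),
    g("MicroGM", "symbolic", "ug", "µg"),
    g("MicroGM", "spelled", "microgram", "micrograms"),
    g("SEC", "symbolic", "s", "sec"),
    g("SEC", "spelled", "second", "seconds"),
    g("MIN", "symbolic", "min"), g("MIN", "spelled", "minute", "minutes"),
    g("HR", "symbolic", "h", "hr"), g("HR", "spelled", "hour", "hours"),
    g("DAY", "symbolic", "d"), g("DAY", "spelled", "day", "days"),
    g("YR", "symbolic", "yr"), g("YR", "spelled", "year", "years"),
    g("K", "symbolic", "K"), g("K", "spelled", "kelvin"),
    g("DEG_C", "symbolic", "degC", "°C"),
    g("DEG_C", "spelled", "degrees celsius", "celsius"),
    g("DEG_C", "camel", "degreesCelsius"),
    g("DEG_C", "misspelled", "celcius"),
    g("DEG_F", "symbolic", "degF"),
    g("DEG_F", "spelled", "degrees fahrenheit", "fahrenheit"),
    g("UNITLESS", "spelled", "dimensionless", "unitless"),
    g("NUM", "symbolic", "num"),
    g("NUM", "spelled", "number", "count", "counts"),
    g("PERCENT", "symbolic", "%", "pct"),
    g("PERCENT", "spelled", "percent", "percentage"),
    g("PPM", "symbolic", "ppm"), g("PPM", "spelled", "parts per million"),
    g("PPM", "camel", "partsPerMillion"),
    g("PPTH", "symbolic", "ppt"),
    g("PPTH", "spelled", "parts per thousand", "per mil", "permille"),
    g("DEG", "symbolic", "deg"), g("DEG", "spelled", "degree", "degrees"),
    g("MOL", "symbolic", "mol"), g("MOL", "spelled", "mole", "moles"),
    g("MilliMOL", "symbolic", "mmol"),
    g("MilliMOL", "spelled", "millimole", "millimoles"),
    g("MicroMOL", "symbolic", "umol", "µmol"),
    g("MicroMOL", "spelled", "micromole", "micromoles"),
    g("PA", "symbolic", "Pa", "pa"), g("PA", "spelled", "pascal", "pascals"),
    g("KiloPA", "symbolic", "kPa", "kpa"),
    g("KiloPA", "spelled", "kilopascal", "kilopascals"),
    g("HectoPA", "symbolic", "hPa"), g("HectoPA", "spelled", "hectopascal"),
    g("J", "spelled", "joule", "joules"),
    g("W", "spelled", "watt", "watts"),
    g("GM-PER-M2", "symbolic", "g/m2", "gm/m2", "g/m^2", "g.m-2", "g m-2",
      "gm-2"),
    g("GM-PER-M2", "spelled", "grams per square meter"),
    g("GM-PER-M2", "camel", "gramPerMeterSquared", "gramsPerSquareMeter"),
    g("KiloGM-PER-HA", "symbolic", "kg/ha"),
    g("KiloGM-PER-HA", "spelled", "kilograms per hectare"),
    g("KiloGM-PER-HA", "camel", "kilogramsPerHectare"),
    g("GM-PER-CentiM2", "symbolic", "g/cm2"),
    g("GM-PER-CentiM2", "spelled", "grams per square centimeter"),
    g("GM-PER-M2-DAY", "symbolic", "g/m2/d", "g m-2 d-1"),
    g("GM-PER-M2-DAY", "spelled", "grams per square meter per day"),
    g("GM-PER-M3", "symbolic", "g/m3"),
    g("GM-PER-M3", "spelled", "grams per cubic meter"),
    g("GM-PER-L", "symbolic", "g/l", "g/L"),
    g("GM-PER-L", "spelled", "grams per liter"),
    g("MilliGM-PER-L", "symbolic", "mg/l", "mg/L"),
    g("MilliGM-PER-L", "spelled", "milligrams per liter"),
    g("MilliGM-PER-L", "camel", "milligramsPerLiter"),
    g("MicroGM-PER-L", "symbolic", "ug/l", "µg/L"),
    g("MicroGM-PER-L", "spelled", "micrograms per liter"),
    g("MilliMOL-PER-L", "symbolic", "mmol/l", "mmol/L"),
    g("MilliMOL-PER-L", "spelled", "millimoles per liter"),
    g("MilliMOL-PER-L", "camel", "millimolesPerLiter"),
    g("MicroMOL-PER-L", "symbolic", "umol/l", "µmol/L"),
    g("MicroMOL-PER-L", "spelled", "micromoles per liter"),
    g("MicroMOL-PER-L", "camel", "micromolesPerLiter"),
    g("M-PER-SEC", "symbolic", "m/s", "m s-1", "ms-1"),
    g("M-PER-SEC", "spelled", "meters per second"),
    g("M-PER-SEC", "camel", "metersPerSecond"),
    g("KiloM-PER-HR", "symbolic", "km/h", "km/hr"),
    g("KiloM-PER-HR", "spelled", "kilometers per hour"),
    g("KiloM-PER-HR", "camel", "kilometersPerHour"),
    g("PER-M2", "symbolic", "/m2"),
    g("PER-M2", "spelled", "per square meter"),
    g("MicroMOL-PER-M2-SEC", "symbolic", "umol/(m2.s)",
      "µmol m-2 s-1"),
    g("MicroMOL-PER-M2-SEC", "spelled",
      "micromoles per square meter per second")
  )
  rownames(out) <- NULL
  out
}

# Non-unit strings in the style of the junk actually found in metadata:
# numbers, missing-value codes, site labels, stray text.
junk_lexicon <- function() {
  c("4a", "atlantis/alvin", "martha stewart", "-9999", "9999", "n/a",
    "yyyy-mm-dd", "site 12", "plot7", "transect a", "unknown", "34.5",
    "station b", "see methods", "category", "flag", "qc code", "tbd",
    "river mile", "grid cell", "sample name", "latitude band", "misc",
    "level", "alvin dive", "moorings")
}

#' Specification for a synthetic raw-unit corpus
#'
#' Bundles and validates the generator's parameters. The defaults are the
#' corpus conditions used throughout the package's tests: 200 distinct raw
#' forms, a Zipf exponent of 1.5 over use counts (so a handful of units
#' dominates instance counts while most distinct forms are rare), 10% junk
#' entries concentrated in singletons, and three organizations of unequal
#' size.
#'
#' @param seed Integer RNG seed; identical seeds give identical corpora.
#' @param n_distinct Total number of distinct raw forms (unit variants plus
#'   junk).
#' @param max_variants_per_unit Upper bound on surface variants drawn per
#'   underlying unit.
#' @param zipf_exponent Exponent of the power-law use-count distribution.
#' @param junk_fraction Fraction of distinct forms that are non-units.
#' @param org_weights Named numeric vector of organization sampling weights.
#' @param top_uses Use count assigned to the most-used form (the power law
#'   is scaled from this).
#' @return A validated \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(seed = 1L, n_distinct = 200L,
                           max_variants_per_unit = 4L,
                           zipf_exponent = 1.5, junk_fraction = 0.10,
                           org_weights = c(EDI = 0.5, DataONE = 0.45,
                                           NEON = 0.05),
                           top_uses = 20000L) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_distinct >= 1, max_variants_per_unit >= 1,
            zipf_exponent >= 0, junk_fraction >= 0, junk_fraction <= 1,
            length(org_weights) >= 1, all(org_weights > 0),
            !is.null(names(org_weights)), top_uses >= 1)
  structure(list(seed = as.integer(seed),
                 n_distinct = as.integer(n_distinct),
                 max_variants_per_unit = as.integer(max_variants_per_unit),
                 zipf_exponent = zipf_exponent,
                 junk_fraction = junk_fraction,
                 org_weights = org_weights / sum(org_weights),
                 top_uses = as.integer(top_uses)),
            class = "synthetic_spec")
}

#' Generate a synthetic raw-unit corpus with ground truth
#'
#' Emulates the structure of a real multi-organization unit corpus: true
#' units drawn from the vocabulary and rendered as 1 to k surface variants
#' through the explicit [variant_grammar()]; Zipf-distributed use counts so
#' a small subset of forms dominates instances while most forms are rare;
#' junk (non-unit) strings as singleton entries; and organization labels
#' such that heavily used forms are shared across organizations while rare
#' forms belong to a single one. Junk strings are verified non-resolvable
#' at generation time. Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param vocab A \code{qudt_vocabulary} (must be nonempty).
#' @return A list with \code{corpus} (data frame raw, org, n_uses),
#'   \code{truth} (data frame raw, code — with \code{"JUNK"} for non-units)
#'   and \code{spec}.
#' @export
generate_synthetic_corpus <- function(spec = synthetic_spec(),
                                      vocab = qudt_fixture_vocabulary()) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(vocab, "qudt_vocabulary"), nrow(vocab$units) > 0)
  gram <- variant_grammar()
  gram <- gram[gram$code %in% vocab$units$code, , drop = FALSE]
  if (nrow(gram) == 0) stop("variant grammar covers no vocabulary unit",
                            call. = FALSE)

  n_junk <- min(floor(spec$junk_fraction * spec$n_distinct),
                length(junk_lexicon()))
  n_true <- spec$n_distinct - n_junk

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  # draw surface variants until n_true distinct forms are collected
  codes_pool <- sample(unique(gram$code))
  forms <- character(0); truth_codes <- character(0)
  ci <- 1L
  stalled <- 0L
  while (length(forms) < n_true && stalled < length(codes_pool)) {
    code <- codes_pool[ci]
    ci <- ci %% length(codes_pool) + 1L
    avail <- setdiff(gram$form[gram$code == code], forms)
    if (length(avail) == 0) {
      stalled <- stalled + 1L
      next
    }
    stalled <- 0L
    k <- sample.int(min(spec$max_variants_per_unit, length(avail)), 1L)
    pick <- if (length(avail) == 1L) avail else sample(avail, k)
    forms <- c(forms, pick)
    truth_codes <- c(truth_codes, rep(code, length(pick)))
  }
  if (length(forms) > n_true) {
    truth_codes <- truth_codes[seq_len(n_true)]
    forms <- forms[seq_len(n_true)]
  }
  n_true <- length(forms)

  junk <- if (n_junk > 0) sample(junk_lexicon(), n_junk) else character(0)
  # generation-time guarantee: junk must not resolve
  if (n_junk > 0) {
    vtab <- build_lookup_table(NULL, vocab)
    bad <- vapply(junk, function(j) {
      resolve(j, vtab, vocab)$match_path != "unmatched"
    }, logical(1))
    if (any(bad)) {
      stop("junk lexicon entries resolve to units: ",
           paste(junk[bad], collapse = ", "), call. = FALSE)
    }
  }

  # Zipf use counts over a random ranking of the true forms; junk entries
  # are singletons, mirroring the finding that misplaced non-units sit in
  # the long tail of the frequency distribution
  rank_of <- sample.int(n_true)
  n_uses_true <- pmax(1L, as.integer(round(
    spec$top_uses * rank_of^(-spec$zipf_exponent))))
  raws <- c(forms, junk)
  truth <- data.frame(raw = raws,
                      code = c(truth_codes, rep("JUNK", n_junk)),
                      stringsAsFactors = FALSE)
  n_uses <- c(n_uses_true, rep(1L, n_junk))

  orgs <- names(spec$org_weights)
  rows <- vector("list", length(raws))
  for (i in seq_along(raws)) {
    n <- n_uses[i]
    k <- 1L + (n > 10) + (n > 1000)       # heavy use implies shared use
    k <- min(k, length(orgs))
    which_orgs <- sample(orgs, k, prob = spec$org_weights)
    split_uses <- if (k == 1L) n else {
      s <- as.integer(stats::rmultinom(1, n - k, rep(1 / k, k))) + 1L
      s
    }
    rows[[i]] <- data.frame(raw = raws[i], org = which_orgs,
                            n_uses = split_uses, stringsAsFactors = FALSE)
  }
  corpus <- do.call(rbind, rows)
  rownames(corpus) <- NULL
  list(corpus = corpus, truth = truth, spec = spec)
}

# save/restore the global RNG state so generation is self-contained
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a corpus (and ground truth) as delimited text
#'
#' @param x A list as returned by [generate_synthetic_corpus()], or a
#'   corpus data frame.
#' @param path Output path for the corpus table; the ground truth (if
#'   present) is written next to it with suffix \code{.truth.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(x, path) {
  corpus <- if (is.data.frame(x)) x else x$corpus
  utils::write.table(corpus, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.data.frame(x) && !is.null(x$truth)) {
    utils::write.table(x$truth, paste0(path, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    encoding = "UTF-8",
                    colClasses = c(raw = "character", org = "character",
                                   n_uses = "integer"))
}
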