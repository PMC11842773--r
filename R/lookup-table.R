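#' Build the enriched unit lookup table
#'
#' Assembles the reusable lookup artifact: a table mapping any supported key
#' to a QUDT unit, enriched with label, URI, dimension vector, SI conversion
#' parameters and UCUM alias. Rows come from four sources:
#' \enumerate{
#'   \item one row per distinct raw corpus unit that the rewrite pipeline
#'     maps to a vocabulary unit, carrying its total use count;
#'   \item one row per vocabulary unit, keyed by its own code;
#'   \item one row per successfully mapped pseudounit, treated as a raw-form
#'     key in its own right;
#'   \item one row per UCUM alias strictly longer than two characters
#'     (shorter codes are excluded as ambiguous).
#' }
#' Distinct raw units that fail to map are collected on the result as the
#' \code{unmatched} sidecar (ordered by use count) — the list of candidate
#' units missing from the ontology.
#'
#' @param corpus Data frame with columns \code{raw}, \code{org},
#'   \code{n_uses}, or \code{NULL} for a vocabulary-only table.
#' @param vocab A \code{qudt_vocabulary}.
#' @param pseudo_rules,qudt_rules Rule sets for the two phases.
#' @return A \code{lookup_table}: list with \code{records} (data frame with
#'   columns key, key_kind, qudt_code, uri, label, dimension_vector,
#'   si_multiplier, si_offset, ucum, description, n_uses),
#'   \code{unmatched} (data frame key, candidate, n_uses) and \code{meta}.
#' @export
build_lookup_table <- function(corpus = NULL,
                               vocab = qudt_fixture_vocabulary(),
                               pseudo_rules = default_rules("pseudo"),
                               qudt_rules = default_rules("qudt")) {
  stopifnot(inherits(vocab, "qudt_vocabulary"))

  enrich <- function(key, key_kind, code, n_uses) {
    u <- vocab_unit(vocab, code)
    data.frame(
      key = key, key_kind = key_kind, qudt_code = u$code, uri = u$uri,
      label = u$label,
      dimension_vector = if (is.null(u$dimension_vector)) ""
                         else render_dimension_vector(u$dimension_vector),
      si_multiplier = u$si_multiplier, si_offset = u$si_offset,
      ucum = paste(u$ucum_codes, collapse = ";"),
      description = u$description, n_uses = as.integer(n_uses),
      stringsAsFactors = FALSE)
  }

  rows <- list()
  unmatched <- data.frame(key = character(0), candidate = character(0),
                          n_uses = integer(0), stringsAsFactors = FALSE)

  if (!is.null(corpus) && nrow(corpus) > 0) {
    stopifnot(all(c("raw", "org", "n_uses") %in% names(corpus)))
    uses <- tapply(corpus$n_uses, corpus$raw, sum)
    raws <- names(uses)
    ps <- to_pseudounit(raws, pseudo_rules)
    mapped_code <- character(length(raws))
    cand <- character(length(raws))
    ps_cache <- new.env(parent = emptyenv())
    for (i in seq_along(raws)) {
      p <- ps[i]
      hit <- if (nzchar(p) && !is.null(ps_cache[[p]])) ps_cache[[p]] else {
        m <- map_pseudounit(p, qudt_rules, vocab)
        v <- list(code = if (m$match_path == "unmatched") NA_character_
                         else m$matched_unit$code,
                  cand = m$candidate$finalized)
        if (nzchar(p)) ps_cache[[p]] <- v
        v
      }
      mapped_code[i] <- hit$code
      cand[i] <- hit$cand
    }
    ok <- !is.na(mapped_code)
    if (any(ok)) {
      raw_rows <- do.call(rbind, lapply(which(ok), function(i) {
        enrich(raws[i], "raw", mapped_code[i], uses[[raws[i]]])
      }))
      rows <- c(rows, list(raw_rows))
      # mapped pseudounits, treated as raw-form keys themselves
      pmap <- unique(data.frame(p = ps[ok], code = mapped_code[ok],
                                stringsAsFactors = FALSE))
      pmap <- pmap[nzchar(pmap$p), , drop = FALSE]
      conflicts <- unique(pmap$p[duplicated(pmap$p)])
      if (length(conflicts) > 0) {
        stop("conflicting enrichment: pseudounit(s) mapped to several ",
             "codes: ", paste(conflicts, collapse = ", "), call. = FALSE)
      }
      if (nrow(pmap) > 0) {
        ps_rows <- do.call(rbind, lapply(seq_len(nrow(pmap)), function(i) {
          enrich(pmap$p[i], "pseudounit", pmap$code[i], 0L)
        }))
        rows <- c(rows, list(ps_rows))
      }
    }
    if (any(!ok)) {
      unmatched <- data.frame(key = raws[!ok], candidate = cand[!ok],
                              n_uses = as.integer(uses[raws[!ok]]),
                              stringsAsFactors = FALSE)
      unmatched <- unmatched[order(-unmatched$n_uses, unmatched$key), ,
                             drop = FALSE]
      rownames(unmatched) <- NULL
    }
  }

  code_rows <- do.call(rbind, lapply(vocab$units$code, function(code) {
    enrich(code, "qudt_code", code, 0L)
  }))
  rows <- c(rows, list(code_rows))

  ucum_keys <- names(vocab$ucum_index)[nchar(names(vocab$ucum_index)) > 2]
  if (length(ucum_keys) > 0) {
    ucum_rows <- do.call(rbind, lapply(ucum_keys, function(a) {
      # an alias listed on several units would be a conflicting enrichment
      codes <- vocab$ucum_index[[a]]
      if (length(unique(codes)) > 1) {
        stop("conflicting enrichment: UCUM alias '", a,
             "' maps to several codes: ",
             paste(unique(codes), collapse = ", "), call. = FALSE)
      }
      enrich(a, "ucum", codes[1], 0L)
    }))
    rows <- c(rows, list(ucum_rows))
  }

  records <- do.call(rbind, rows)
  dupes <- duplicated(records[, c("key", "key_kind")])
  if (any(dupes)) {
    # same key+kind is only legal if it names the same unit
    kk <- paste(records$key, records$key_kind, sep = "\r")
    for (k in unique(kk[dupes])) {
      codes <- unique(records$qudt_code[kk == k])
      if (length(codes) > 1) {
        stop("conflicting enrichment for key '",
             sub("\r.*", "", k), "': ",
             paste(codes, collapse = " vs "), call. = FALSE)
      }
    }
    records <- records[!dupes, , drop = FALSE]
  }
  rownames(records) <- NULL

  structure(list(
    records = records,
    unmatched = unmatched,
    meta = list(vocabulary_version = vocab$version,
                pseudo_rules = pseudo_rules$provenance,
                qudt_rules = qudt_rules$provenance,
                n_vocab_units = nrow(vocab$units))
  ), class = "lookup_table")
}

#' Resolve a query string against the lookup table
#'
#' Lookup order: exact raw key (whitespace-trimmed, case-sensitive), then
#' exact QUDT code, then exact UCUM alias (case-sensitive), then the
#' pseudounit of the query among pseudounit keys, then the full rewrite
#' pipeline. The first hit wins and \code{match_path} records which route
#' matched. Raw-key matching is deliberately case-sensitive: case folding
#' happens only through the pseudounit route, because raw-layer folding
#' conflates case-sensitive codes (mg vs Mg).
#'
#' @param query A single unit string of any supported kind.
#' @param table A \code{lookup_table}.
#' @param vocab The vocabulary the table was built against.
#' @param pseudo_rules,qudt_rules Rule sets for the fallback rewrite.
#' @return A \code{match_result}.
#' @export
resolve <- function(query, table, vocab = qudt_fixture_vocabulary(),
                    pseudo_rules = default_rules("pseudo"),
                    qudt_rules = default_rules("qudt")) {
  stopifnot(inherits(table, "lookup_table"),
            is.character(query), length(query) == 1L)
  q <- trimws(query)
  rec <- table$records
  hit <- function(kind, key) {
    i <- which(rec$key_kind == kind & rec$key == key)
    if (length(i) > 0) rec$qudt_code[i[1]] else NULL
  }
  found <- function(code, path, p = NA_character_) {
    match_result(query = query, pseudounit = p, candidate = NULL,
                 matched_unit = vocab_unit(vocab, code), match_path = path)
  }
  code <- hit("raw", q)
  if (!is.null(code)) return(found(code, "direct_raw"))
  code <- hit("qudt_code", q)
  if (!is.null(code)) return(found(code, "direct_qudt_code"))
  code <- hit("ucum", q)
  if (!is.null(code)) return(found(code, "ucum"))
  p <- to_pseudounit(q, pseudo_rules)
  code <- if (nzchar(p)) hit("pseudounit", p) else NULL
  if (!is.null(code)) {
    res <- found(code, "rewritten")
    res$pseudounit <- p
    return(res)
  }
  map_pseudounit(p, qudt_rules, vocab, query = query)
}

#' Are two units directly inter-convertible?
#'
#' True iff the two units' dimension vectors are exactly equal — the guard
#' that (for example) refuses to convert milligrams per litre into
#' millimoles per litre, which would require knowing the substance's molar
#' mass, a property of the measurement rather than of the unit.
#'
#' @param a,b \code{qudt_unit} objects.
#' @return \code{TRUE} or \code{FALSE}; units lacking a published dimension
#'   vector raise an error rather than comparing as unequal.
#' @export
compatible <- function(a, b) {
  stopifnot(inherits(a, "qudt_unit"), inherits(b, "qudt_unit"))
  if (is.null(a$dimension_vector) || is.null(b$dimension_vector)) {
    stop("dimension vector absent for ",
         paste(c(a$code, b$code)[c(is.null(a$dimension_vector),
                                   is.null(b$dimension_vector))],
               collapse = ", "),
         "; compatibility is undefined", call. = FALSE)
  }
  dimension_vectors_equal(a$dimension_vector, b$dimension_vector)
}

#' Convert a value between compatible units
#'
#' Uses the SI multiplier and (for affine units such as Celsius) offset that
#' the ontology publishes for each unit:
#' \deqn{y = (m_{from} x + b_{from} - b_{to}) / m_{to}}
#' Round trips are identities up to floating point.
#'
#' @param x Numeric vector of values in unit \code{from}.
#' @param from,to \code{qudt_unit} objects with equal dimension vectors.
#' @return The values expressed in unit \code{to}.
#' @examples
#' v <- qudt_fixture_vocabulary()
#' convert_value(0, vocab_unit(v, "DEG_C"), vocab_unit(v, "K"))  # 273.15
#' @export
convert_value <- function(x, from, to) {
  if (!compatible(from, to)) {
    stop("cannot convert ", from$code, " to ", to$code,
         ": dimension vectors differ", call. = FALSE)
  }
  if (is.na(from$si_multiplier) || is.na(to$si_multiplier)) {
    stop("conversion parameters missing for ",
         paste(c(from$code, to$code)[c(is.na(from$si_multiplier),
                                       is.na(to$si_multiplier))],
               collapse = ", "), call. = FALSE)
  }
  (from$si_multiplier * x + from$si_offset - to$si_offset) / to$si_multiplier
}

#' Write / read a lookup table as delimited text
#'
#' The serialized table is the reusable artifact: a UTF-8 tab-delimited
#' file with one row per record and the standard column set. Serialization
#' is deterministic given the same inputs.
#'
#' @param table A \code{lookup_table}.
#' @param path Output file path.
#' @return \code{write_lookup_table}: \code{path}, invisibly.
#' @export
write_lookup_table <- function(table, path) {
  stopifnot(inherits(table, "lookup_table"))
  utils::write.table(table$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lookup_table
#' @export
read_lookup_table <- function(path) {
  rec <- utils::read.delim(path, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           colClasses = c(si_multiplier = "numeric",
                                          si_offset = "numeric",
                                          n_uses = "integer"))
  rec$key <- as.character(rec$key)
  structure(list(records = rec,
                 unmatched = data.frame(key = character(0),
                                        candidate = character(0),
                                        n_uses = integer(0)),
                 meta = list(source = path)),
            class = "lookup_table")
}

#' @export
print.lookup_table <- function(x, ...) {
  kinds <- table(x$records$key_kind)
  cat("<lookup table: ", nrow(x$records), " records (",
      paste(names(kinds), as.integer(kinds), sep = "=", collapse = ", "),
      "); ", nrow(x$unmatched), " unmatched raw unit(s)>\n", sep = "")
  invisible(x)
}
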