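#!/usr/bin/env Rscript
# Offline importer: convert an official QUDT Turtle release (VOCAB_QUDT-
# UNITS-ALL-vX.Y.Z.ttl) into the flat snapshot table load_vocabulary()
# consumes. Run once, outside the package; the core library never touches
# RDF at runtime.
#
#   Rscript scripts/import-qudt-ttl.R VOCAB_QUDT-UNITS-ALL-v2.1.25.ttl out.tsv
#
# The QUDT unit files are regular enough that a line-oriented reader
# suffices; subjects are unit:CODE blocks terminated by " ." lines.

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 2) {
  stop("usage: import-qudt-ttl.R <units.ttl> <out.tsv>", call. = FALSE)
}
ttl <- readLines(args[1], encoding = "UTF-8", warn = FALSE)

unquote <- function(x) {
  m <- regmatches(x, regexec('"((?:[^"\\\\]|\\\\.)*)"', x))[[1]]
  if (length(m) < 2) return(NA_character_)
  gsub('\\\\(.)', '\\1', m[2])
}
localname <- function(x, prefix) {
  m <- regmatches(x, regexec(paste0(prefix, ":([A-Za-z0-9_.\\-]+)"), x))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

units <- list()
cur <- NULL
flush <- function(cur) {
  if (is.null(cur) || is.null(cur$code)) return(invisible(NULL))
  units[[cur$code]] <<- cur
}
for (line in ttl) {
  t <- trimws(line)
  m <- regmatches(t, regexec("^unit:([A-Za-z0-9_.\\-]+)$", t))[[1]]
  if (length(m) == 2) {             # new subject block
    flush(cur)
    cur <- list(code = m[2], ucum = character(0), qk = character(0),
                label = NA, dv = NA, mult = NA, off = NA, desc = NA)
    next
  }
  if (is.null(cur)) next
  if (grepl("^qudt:ucumCode", t)) {
    u <- unquote(t); if (!is.na(u)) cur$ucum <- c(cur$ucum, u)
  } else if (grepl("^qudt:hasDimensionVector", t)) {
    cur$dv <- localname(t, "qkdv")
    if (!is.na(cur$dv)) cur$dv <- sub("^dim_", "", cur$dv)
  } else if (grepl("^qudt:conversionMultiplier ", t)) {
    cur$mult <- suppressWarnings(as.numeric(
      sub("^qudt:conversionMultiplier +([0-9eE.+\\-]+).*$", "\\1", t)))
  } else if (grepl("^qudt:conversionOffset ", t)) {
    cur$off <- suppressWarnings(as.numeric(
      sub("^qudt:conversionOffset +([0-9eE.+\\-]+).*$", "\\1", t)))
  } else if (grepl("^rdfs:label", t) && grepl('@en', t)) {
    if (is.na(cur$label)) cur$label <- unquote(t)
  } else if (grepl("^dcterms:description", t)) {
    if (is.na(cur$desc)) cur$desc <- unquote(t)
  } else if (grepl("^qudt:hasQuantityKind", t)) {
    q <- localname(t, "quantitykind")
    if (!is.na(q)) cur$qk <- c(cur$qk, q)
  }
}
flush(cur)

rows <- do.call(rbind, lapply(units, function(u) {
  # QUDT dimension-vector local names look like A0E0L1I0M0H0T0D0 already
  data.frame(code = u$code,
             uri = paste0("http://qudt.org/vocab/unit/", u$code),
             label = ifelse(is.na(u$label), u$code, u$label),
             dimension_vector = ifelse(is.na(u$dv), "", u$dv),
             si_multiplier = ifelse(is.na(u$mult), "", format(u$mult,
                                                              digits = 17)),
             si_offset = ifelse(is.na(u$off), "0", format(u$off,
                                                          digits = 17)),
             ucum = paste(u$ucum, collapse = ";"),
             quantity_kinds = paste(u$qk, collapse = ";"),
             description = ifelse(is.na(u$desc), "", u$desc),
             stringsAsFactors = FALSE)
}))
rows <- rows[order(rows$code), , drop = FALSE]
write.table(rows, args[2], sep = "\t", quote = FALSE, row.names = FALSE,
            fileEncoding = "UTF-8")
message("wrote ", nrow(rows), " units to ", args[2])
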