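#' Load a QUDT vocabulary snapshot
#'
#' Reads a flat snapshot table of the QUDT units vocabulary: one row per
#' unit, with its dash-delimited code, URI, label, dimension vector, SI
#' conversion parameters, UCUM aliases and quantity kinds. A snapshot of
#' this shape (rather than the RDF release itself) is the package's required
#' vocabulary input, so the core library needs neither network access nor an
#' RDF stack; a small subset transcribed from QUDT v2.1.25 ships with the
#' package (see [qudt_fixture_vocabulary()]).
#'
#' Units lacking a published dimension vector or multiplier are loaded with
#' those fields marked absent (\code{NA}); any conversion involving them is
#' an error rather than a guess.
#'
#' @param path Path to a UTF-8 tab-delimited file with a header row and
#'   columns \code{code, uri, label, dimension_vector, si_multiplier,
#'   si_offset, ucum, quantity_kinds, description}. Multi-valued cells
#'   (\code{ucum}, \code{quantity_kinds}) are semicolon-separated. Lines
#'   starting with \code{#} are comments.
#' @param version Version tag recorded on the vocabulary (default
#'   \code{"2.1.25"}, the release the bundled subset was transcribed from).
#' @return An object of class \code{qudt_vocabulary}: a list with elements
#'   \code{units} (data frame), \code{ucum_index} (named list mapping UCUM
#'   code to QUDT codes) and \code{version}.
#' @seealso [find_by_ucum()], [vocab_unit()]
#' @export
load_vocabulary <- function(path, version = "2.1.25") {
  if (!file.exists(path)) {
    stop("vocabulary snapshot not found: ", path, call. = FALSE)
  }
  units <- utils::read.delim(path, sep = "\t", comment.char = "#",
                             quote = "", stringsAsFactors = FALSE,
                             colClasses = "character", fill = TRUE,
                             encoding = "UTF-8")
  required <- c("code", "uri", "label", "dimension_vector",
                "si_multiplier", "si_offset", "ucum")
  missing_cols <- setdiff(required, names(units))
  if (length(missing_cols) > 0) {
    stop("vocabulary snapshot is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"quantity_kinds" %in% names(units)) units$quantity_kinds <- ""
  if (!"description" %in% names(units)) units$description <- ""
  units$description[is.na(units$description)] <- ""

  if (anyDuplicated(units$code)) {
    dups <- unique(units$code[duplicated(units$code)])
    stop("duplicate unit code(s) in snapshot: ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  if (any(units$code == "" | grepl("[[:space:]]", units$code))) {
    stop("unit codes must be nonempty and contain no whitespace",
         call. = FALSE)
  }
  bad_uri <- !endsWith(units$uri, units$code)
  if (any(bad_uri)) {
    stop("URI does not end with the unit code for: ",
         paste(units$code[bad_uri], collapse = ", "), call. = FALSE)
  }

  units$si_multiplier <- vapply(units$si_multiplier, function(x) {
    if (is.na(x) || x == "") return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("unparseable si_multiplier: '", x, "'", call. = FALSE)
    v
  }, numeric(1), USE.NAMES = FALSE)
  units$si_offset <- vapply(units$si_offset, function(x) {
    if (is.na(x) || x == "") return(0)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("unparseable si_offset: '", x, "'", call. = FALSE)
    v
  }, numeric(1), USE.NAMES = FALSE)
  if (any(!is.na(units$si_multiplier) & units$si_multiplier <= 0)) {
    stop("si_multiplier must be > 0", call. = FALSE)
  }
  # parse every dimension vector up front so malformed rows fail at load
  for (i in seq_len(nrow(units))) {
    dvtxt <- units$dimension_vector[i]
    if (!is.na(dvtxt) && dvtxt != "") {
      tryCatch(parse_dimension_vector(dvtxt), error = function(e) {
        stop("row for ", units$code[i], ": ", conditionMessage(e),
             call. = FALSE)
      })
    }
  }

  ucum_index <- list()
  for (i in seq_len(nrow(units))) {
    aliases <- split_multi(units$ucum[i])
    for (a in aliases) {
      ucum_index[[a]] <- c(ucum_index[[a]], units$code[i])
    }
  }

  structure(list(units = units, ucum_index = ucum_index, version = version),
            class = "qudt_vocabulary")
}

split_multi <- function(x) {
  if (is.na(x) || x == "") return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' The bundled QUDT v2.1.25 subset vocabulary
#'
#' Convenience loader for the snapshot shipped under \code{inst/extdata}.
#'
#' @return A \code{qudt_vocabulary}.
#' @export
qudt_fixture_vocabulary <- function() {
  load_vocabulary(system.file("extdata", "qudt-2.1.25-subset.tsv",
                              package = "qudtmapper", mustWork = TRUE))
}

#' Retrieve one unit record by code
#'
#' @param vocab A \code{qudt_vocabulary}.
#' @param code A QUDT unit code, e.g. \code{"GM-PER-M2"}.
#' @return A \code{qudt_unit} (list with fields code, uri, label,
#'   description, dimension_vector, si_multiplier, si_offset, ucum_codes,
#'   quantity_kinds), or \code{NULL} if the code is not in the vocabulary.
#' @export
vocab_unit <- function(vocab, code) {
  stopifnot(inherits(vocab, "qudt_vocabulary"))
  i <- match(code, vocab$units$code)
  if (is.na(i)) return(NULL)
  row <- vocab$units[i, ]
  dv <- if (is.na(row$dimension_vector) || row$dimension_vector == "") NULL
        else parse_dimension_vector(row$dimension_vector)
  structure(list(
    code = row$code,
    uri = row$uri,
    label = row$label,
    description = row$description,
    dimension_vector = dv,
    si_multiplier = row$si_multiplier,
    si_offset = row$si_offset,
    ucum_codes = split_multi(row$ucum),
    quantity_kinds = split_multi(row$quantity_kinds)
  ), class = "qudt_unit")
}

#' Find units by UCUM alias
#'
#' Exact, case-sensitive match (UCUM codes are case-sensitive: \code{mg} and
#' \code{Mg} are different units).
#'
#' @param vocab A \code{qudt_vocabulary}.
#' @param ucum A UCUM code, e.g. \code{"kPa"}.
#' @return A list of \code{qudt_unit} objects; empty if none match.
#' @export
find_by_ucum <- function(vocab, ucum) {
  stopifnot(inherits(vocab, "qudt_vocabulary"))
  if (is.null(ucum) || is.na(ucum) || ucum == "") return(list())
  codes <- vocab$ucum_index[[ucum]]
  if (is.null(codes)) return(list())
  lapply(codes, function(code) vocab_unit(vocab, code))
}

#' @export
print.qudt_vocabulary <- function(x, ...) {
  cat("<QUDT vocabulary v", x$version, ": ", nrow(x$units), " units, ",
      length(x$ucum_index), " UCUM aliases>\n", sep = "")
  invisible(x)
}

#' @export
print.qudt_unit <- function(x, ...) {
  cat("<QUDT unit ", x$code, " (", x$label, ")>\n", sep = "")
  invisible(x)
}
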