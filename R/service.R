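#' Handle one unit lookup request
#'
#' The stateless request handler behind the lookup service: resolves
#' \code{rawunit} against a built lookup table and renders the outcome in
#' the requested format. Matched responses include the QUDT code, URI,
#' label, dimension vector, SI multiplier, UCUM alias, the match path, and
#' a ready-to-paste EML \code{annotation} fragment.
#'
#' @param rawunit The query string (client error if empty).
#' @param returntype One of \code{"json"} (default), \code{"xml"},
#'   \code{"html"}; anything else is a client error listing the allowed
#'   values.
#' @param table A \code{lookup_table}.
#' @param vocab,pseudo_rules,qudt_rules Pipeline inputs for the resolve
#'   fallback.
#' @return A \code{lookup_response}: list with \code{status} (HTTP-style
#'   integer), \code{content_type}, \code{body} (single string) and
#'   \code{fields} (the named list the body renders).
#' @export
handle_lookup <- function(rawunit, returntype = "json",
                          table, vocab = qudt_fixture_vocabulary(),
                          pseudo_rules = default_rules("pseudo"),
                          qudt_rules = default_rules("qudt")) {
  if (is.null(returntype) || !returntype %in% c("json", "xml", "html")) {
    fields <- list(error = paste0("unknown returntype '", returntype,
                                  "'; allowed: json, xml, html"))
    return(structure(list(status = 400L, content_type = "application/json",
                          body = jsonlite::toJSON(fields, auto_unbox = TRUE),
                          fields = fields),
                     class = "lookup_response"))
  }
  if (is.null(rawunit) || is.na(rawunit) || !nzchar(trimws(rawunit))) {
    fields <- list(error = "rawunit parameter is required and must be non-empty")
    return(render_response(fields, returntype, 400L))
  }
  res <- resolve(rawunit, table, vocab, pseudo_rules, qudt_rules)
  fields <- if (res$match_path == "unmatched") {
    list(query = rawunit, matched = FALSE,
         candidate = if (!is.null(res$candidate)) res$candidate$finalized
                     else NA_character_)
  } else {
    u <- res$matched_unit
    list(query = rawunit, matched = TRUE, qudt_code = u$code, uri = u$uri,
         label = u$label,
         dimension_vector = if (is.null(u$dimension_vector)) NA_character_
                            else render_dimension_vector(u$dimension_vector),
         si_multiplier = u$si_multiplier,
         ucum = paste(u$ucum_codes, collapse = ";"),
         match_path = res$match_path,
         annotation = annotation_fragment(u))
  }
  render_response(fields, returntype, 200L)
}

# EML-ready <annotation> fragment for a matched unit
annotation_fragment <- function(u) {
  paste0('<annotation>\n',
         '  <propertyURI label="has unit">', QUDT_HAS_UNIT_URI,
         '</propertyURI>\n',
         '  <valueURI label="', xml_escape(u$label), '">',
         xml_escape(u$uri), '</valueURI>\n',
         '</annotation>')
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

render_response <- function(fields, returntype, status) {
  body <- switch(returntype,
    json = as.character(jsonlite::toJSON(fields, auto_unbox = TRUE,
                                         digits = NA)),
    xml = {
      doc <- xml2::xml_new_root("unitlookup")
      for (nm in names(fields)) {
        xml2::xml_add_child(doc, nm, as.character(fields[[nm]]))
      }
      as.character(doc)
    },
    html = {
      rows <- vapply(names(fields), function(nm) {
        paste0("<tr><th>", xml_escape(nm), "</th><td>",
               xml_escape(as.character(fields[[nm]])), "</td></tr>")
      }, character(1))
      paste0("<!DOCTYPE html><html><head><title>unit lookup</title></head>",
             "<body><table>", paste(rows, collapse = ""),
             "</table></body></html>")
    })
  ct <- switch(returntype, json = "application/json",
               xml = "application/xml", html = "text/html")
  structure(list(status = status, content_type = ct, body = body,
                 fields = fields), class = "lookup_response")
}

#' @export
print.lookup_response <- function(x, ...) {
  cat("<lookup response [", x$status, " ", x$content_type, "]>\n",
      x$body, "\n", sep = "")
  invisible(x)
}

# Parse the request line + query string of an HTTP GET.
# Returns list(path, params) or NULL for anything but a parseable GET.
parse_http_request <- function(request_line) {
  m <- regmatches(request_line,
                  regexec("^GET[[:space:]]+([^[:space:]]+)", request_line))[[1]]
  if (length(m) < 2) return(NULL)
  target <- m[2]
  parts <- strsplit(target, "?", fixed = TRUE)[[1]]
  path <- parts[1]
  params <- list()
  if (length(parts) > 1) {
    for (kv in strsplit(parts[2], "&", fixed = TRUE)[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(p) == 2) {
        params[[url_decode(p[1])]] <- url_decode(p[2])
      }
    }
  }
  list(path = path, params = params)
}

url_decode <- function(x) utils::URLdecode(chartr("+", " ", x))

#' Serve unit lookups over HTTP
#'
#' A minimal blocking HTTP/1.1 listener over a base-R server socket: each
#' GET with query parameters \code{rawunit} and \code{returntype} is
#' answered via [handle_lookup()]. Intended for local, interactive use.
#'
#' @param table A \code{lookup_table}.
#' @param port TCP port to listen on.
#' @param vocab,pseudo_rules,qudt_rules Pipeline inputs.
#' @param max_requests Stop after this many requests (\code{Inf} to run
#'   until interrupted); useful for scripted smoke tests.
#' @param verbose Log requests to stderr.
#' @return The number of requests served, invisibly.
#' @export
serve_units <- function(table, port = 8080L,
                        vocab = qudt_fixture_vocabulary(),
                        pseudo_rules = default_rules("pseudo"),
                        qudt_rules = default_rules("qudt"),
                        max_requests = Inf, verbose = FALSE) {
  served <- 0L
  while (served < max_requests) {
    con <- suppressWarnings(socketConnection(
      host = "127.0.0.1", port = port, server = TRUE, blocking = TRUE,
      open = "r+b", timeout = 30))
    req <- tryCatch(readLines(con, n = 1, warn = FALSE),
                    error = function(e) character(0))
    parsed <- if (length(req) > 0) parse_http_request(req[1]) else NULL
    resp <- if (is.null(parsed)) {
      render_response(list(error = "only GET requests are supported"),
                      "json", 400L)
    } else {
      handle_lookup(parsed$params[["rawunit"]],
                    if (is.null(parsed$params[["returntype"]])) "json"
                    else parsed$params[["returntype"]],
                    table, vocab, pseudo_rules, qudt_rules)
    }
    if (verbose && length(req) > 0) message("[serve_units] ", req[1])
    body <- resp$body
    writeLines(c(paste0("HTTP/1.1 ", resp$status, " ",
                        if (resp$status == 200L) "OK" else "Bad Request"),
                 paste0("Content-Type: ", resp$content_type),
                 paste0("Content-Length: ", nchar(body, type = "bytes")),
                 "Connection: close", "", body),
               con, sep = "\r\n")
    close(con)
    served <- served + 1L
  }
  invisible(served)
}
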