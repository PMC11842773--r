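#' Rewrite a pseudounit into a marked QUDT code candidate
#'
#' Applies the qudt-phase rules strictly in order, each replacing all
#' occurrences of its literal pattern. Replacement tokens are dash-delimited
#' and QUDT-cased (e.g. \code{-CentiM-}), and pseudounits cannot contain
#' dashes, so at every step the already-converted segments of the string are
#' visibly distinct from the lowercase text still awaiting conversion.
#'
#' @param pseudounit A single pseudounit string (lowercase, no dashes).
#' @param rules A qudt-phase \code{rule_set}.
#' @return A \code{candidate_code}: list with \code{marked} (the rewritten
#'   string, possibly with doubled dashes), \code{finalized} (after
#'   [finalize_candidate()]) and \code{trace}, a data frame of the rules
#'   that fired with the string state before and after each.
#' @examples
#' rewrite_to_candidate("grampermetersquaredperday")
#' @export
rewrite_to_candidate <- function(pseudounit, rules = default_rules("qudt")) {
  stopifnot(is.character(pseudounit), length(pseudounit) == 1L)
  stopifnot(inherits(rules, "rule_set"), rules$phase == "qudt")
  if (grepl("-", pseudounit, fixed = TRUE)) {
    stop("pseudounits cannot contain dashes: '", pseudounit, "'",
         call. = FALSE)
  }
  x <- pseudounit
  ord <- integer(0); before <- character(0); after <- character(0)
  for (i in seq_len(nrow(rules$rules))) {
    pat <- rules$rules$pattern[i]
    if (grepl(pat, x, fixed = TRUE)) {
      new <- gsub(pat, rules$rules$replacement[i], x, fixed = TRUE)
      ord <- c(ord, rules$rules$order[i])
      before <- c(before, x)
      after <- c(after, new)
      x <- new
    }
  }
  structure(list(
    marked = x,
    finalized = finalize_candidate(x),
    trace = data.frame(order = ord, before = before, after = after,
                       stringsAsFactors = FALSE)
  ), class = "candidate_code")
}

#' Finalize a marked candidate into a QUDT code
#'
#' Cleanup conventions for a rewritten candidate: leading and trailing
#' dashes are removed, runs of multiple dashes are reduced to single dashes,
#' and every \code{PER} token after the first is dropped (its surrounding
#' dashes merging to one), so \code{-GM--PER--M2--PER--DAY-} becomes
#' \code{GM-PER-M2-DAY}. The function is idempotent, never returns a string
#' with leading/trailing dashes or dash runs, and its output contains at
#' most one \code{PER} token.
#'
#' @param marked A marked candidate string.
#' @return The finalized dash-delimited code.
#' @examples
#' finalize_candidate("-GM--PER--M2--PER--DAY-")
#' @export
finalize_candidate <- function(marked) {
  stopifnot(is.character(marked), length(marked) == 1L)
  tokens <- strsplit(marked, "-", fixed = TRUE)[[1]]
  tokens <- tokens[tokens != ""]
  if (length(tokens) == 0) return("")
  is_per <- tokens == "PER"
  if (sum(is_per) > 1) {
    drop <- which(is_per)[-1]
    tokens <- tokens[-drop]
  }
  paste(tokens, collapse = "-")
}

#' Map a pseudounit to a QUDT unit
#'
#' Runs the qudt-phase rewrite, finalizes the candidate, and looks the
#' result up (exact, case-sensitive) among the vocabulary's codes. An
#' unmatched candidate is a value, not an error: it is retained for
#' diagnostics and for assembling lists of candidate units missing from the
#' ontology.
#'
#' @param pseudounit A single pseudounit string.
#' @param rules A qudt-phase \code{rule_set}.
#' @param vocab A \code{qudt_vocabulary}.
#' @param query The original raw query, recorded on the result (defaults to
#'   the pseudounit).
#' @return A \code{match_result}: list with \code{query},
#'   \code{pseudounit}, \code{candidate} (\code{candidate_code}),
#'   \code{matched_unit} (\code{qudt_unit} or \code{NULL}) and
#'   \code{match_path} (\code{"rewritten"} or \code{"unmatched"}).
#' @export
map_pseudounit <- function(pseudounit, rules = default_rules("qudt"),
                           vocab = qudt_fixture_vocabulary(),
                           query = pseudounit) {
  cand <- rewrite_to_candidate(pseudounit, rules)
  unit <- vocab_unit(vocab, cand$finalized)
  match_result(query = query, pseudounit = pseudounit, candidate = cand,
               matched_unit = unit,
               match_path = if (is.null(unit)) "unmatched" else "rewritten")
}

match_result <- function(query, pseudounit, candidate = NULL,
                         matched_unit = NULL, match_path) {
  stopifnot(match_path %in% c("direct_raw", "direct_qudt_code", "ucum",
                              "rewritten", "unmatched"))
  # matched_unit present iff the path is anything but unmatched
  stopifnot(is.null(matched_unit) == (match_path == "unmatched"))
  structure(list(query = query, pseudounit = pseudounit,
                 candidate = candidate, matched_unit = matched_unit,
                 match_path = match_path),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$match_path == "unmatched") {
    cand <- if (!is.null(x$candidate)) x$candidate$finalized else ""
    cat("<no match for '", x$query, "' (candidate: ", cand, ")>\n", sep = "")
  } else {
    cat("<'", x$query, "' -> ", x$matched_unit$code, " [",
        x$match_path, "]>\n", sep = "")
  }
  invisible(x)
}

#' @export
print.candidate_code <- function(x, ...) {
  cat("<candidate ", x$finalized, " (marked: ", x$marked, "; ",
      nrow(x$trace), " rules fired)>\n", sep = "")
  invisible(x)
}
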