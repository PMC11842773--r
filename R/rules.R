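#' Load an ordered substitution rule set
#'
#' Rules are literal substring substitutions applied strictly in ascending
#' \code{order}; each rule replaces every occurrence of its pattern. Two
#' phases exist: \code{pseudo} rules turn raw strings into pseudounits
#' (lowercase words, boundaries marked by spaces), \code{qudt} rules turn
#' pseudounits into dash-delimited QUDT code candidates.
#'
#' @param path UTF-8 tab-delimited file with header columns
#'   \code{order, pattern, replacement}; lines starting with \code{#} are
#'   comments. Pattern and replacement fields are taken verbatim, including
#'   any leading/trailing spaces (pseudo-phase patterns use spaces as word
#'   boundary anchors).
#' @param phase \code{"pseudo"} or \code{"qudt"}.
#' @return A \code{rule_set}: list with \code{phase}, \code{rules} (data
#'   frame with columns order, pattern, replacement, sorted by order) and
#'   \code{provenance}.
#' @export
load_rules <- function(path, phase = c("pseudo", "qudt")) {
  phase <- match.arg(phase)
  if (!file.exists(path)) {
    stop("rule file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE,
                           strip.white = FALSE, fill = TRUE,
                           colClasses = "character", encoding = "UTF-8")
  for (col in c("order", "pattern", "replacement")) {
    if (!col %in% names(raw)) {
      stop("rule file missing required column '", col, "'", call. = FALSE)
    }
  }
  ord <- suppressWarnings(as.integer(raw$order))
  if (anyNA(ord)) {
    stop("non-integer order value at line(s): ",
         paste(which(is.na(ord)), collapse = ", "), call. = FALSE)
  }
  if (any(ord <= 0)) {
    stop("order values must be positive", call. = FALSE)
  }
  if (anyDuplicated(ord)) {
    stop("duplicate order value(s): ",
         paste(unique(ord[duplicated(ord)]), collapse = ", "),
         call. = FALSE)
  }
  pat <- raw$pattern
  rep <- raw$replacement
  rep[is.na(rep)] <- ""
  empty <- which(is.na(pat) | pat == "")
  if (length(empty) > 0) {
    stop("empty pattern at rule line(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  if (phase == "pseudo") {
    bad <- which(grepl("[A-Z]", rep) | grepl("-", rep, fixed = TRUE))
    if (length(bad) > 0) {
      stop("pseudo-phase replacements may not contain uppercase letters ",
           "or dashes; offending rule line(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  rules <- data.frame(order = ord, pattern = pat, replacement = rep,
                      stringsAsFactors = FALSE)
  rules <- rules[order(rules$order), , drop = FALSE]
  rownames(rules) <- NULL
  structure(list(phase = phase, rules = rules,
                 provenance = paste0("loaded from ", basename(path))),
            class = "rule_set")
}

#' Default substitution rule sets
#'
#' The package ships reconstructed default rule sets for both phases under
#' \code{inst/extdata} (\code{rules-pseudo.tsv}, \code{rules-qudt.tsv}).
#' They cover the symbolic, spelled-out, camelCase and common-misspelling
#' surface forms of the bundled vocabulary's units. A differently sized
#' rule list (for instance one obtained from the deposited corpus archive)
#' can be used instead by passing its path to [load_rules()]; everything
#' downstream treats the rule set as data.
#'
#' @param phase \code{"pseudo"} or \code{"qudt"}.
#' @return A \code{rule_set}.
#' @export
default_rules <- function(phase = c("pseudo", "qudt")) {
  phase <- match.arg(phase)
  fname <- if (phase == "pseudo") "rules-pseudo.tsv" else "rules-qudt.tsv"
  load_rules(system.file("extdata", fname, package = "qudtmapper",
                         mustWork = TRUE), phase = phase)
}

#' @export
print.rule_set <- function(x, ...) {
  cat("<", x$phase, " rule set: ", nrow(x$rules), " ordered substitutions (",
      x$provenance, ")>\n", sep = "")
  invisible(x)
}
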