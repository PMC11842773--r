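# Pre-rule character normalization: map the Unicode symbols that appear in
# unit strings onto ASCII so that the micro sign and the Greek mu coincide,
# superscript digits become plain digits, and the degree sign becomes "deg".
unicode_premap <- function(x) {
  x <- gsub("µ", "u", x, fixed = TRUE)  # micro sign
  x <- gsub("μ", "u", x, fixed = TRUE)  # Greek small mu
  x <- gsub("¹", "1", x, fixed = TRUE)
  x <- gsub("²", "2", x, fixed = TRUE)
  x <- gsub("³", "3", x, fixed = TRUE)
  x <- gsub("°", "deg", x, fixed = TRUE)  # degree sign
  x <- gsub("‰", " permil ", x, fixed = TRUE)  # per-mille sign
  x <- gsub("·", ".", x, fixed = TRUE)  # middle dot (product)
  x <- gsub("−", "-", x, fixed = TRUE)  # minus sign
  x
}

#' Normalize a raw unit string to its pseudounit
#'
#' A pseudounit is the canonical intermediate form that groups variant
#' surface representations of the same unit: lowercase, with no spaces and
#' no symbols, e.g. \code{"grampermetersquared"} for any of
#' \code{g/m2}, \code{g m-2}, \code{grams per square meter} or
#' \code{gramPerMeterSquared}.
#'
#' Processing is a pure function of \code{(raw, rules)}: Unicode symbol
#' mapping, trim, lowercase, then each rule applied in order (replacing all
#' occurrences of its literal pattern in the string padded with one space on
#' each side, so patterns can anchor on word boundaries), then deletion of
#' any remaining whitespace and of any character outside \code{[a-z0-9]}.
#' Any input yields a (possibly empty) pseudounit; an empty result means
#' nothing unit-like survived.
#'
#' @param raw Character vector of raw unit strings.
#' @param rules A pseudo-phase \code{rule_set} (default: the bundled set).
#' @return Character vector of pseudounits, same length as \code{raw}.
#' @examples
#' to_pseudounit(c("g/m^2", "grams per square meter", "gramPerMeterSquared"))
#' @export
to_pseudounit <- function(raw, rules = default_rules("pseudo")) {
  stopifnot(inherits(rules, "rule_set"), rules$phase == "pseudo")
  vapply(raw, function(x) {
    if (is.na(x)) return("")
    x <- unicode_premap(x)
    x <- tolower(trimws(x))
    x <- paste0(" ", x, " ")
    for (i in seq_len(nrow(rules$rules))) {
      x <- gsub(rules$rules$pattern[i], rules$rules$replacement[i], x,
                fixed = TRUE)
    }
    x <- gsub("[[:space:]]+", "", x)
    gsub("[^a-z0-9]", "", x)
  }, character(1), USE.NAMES = FALSE)
}

#' Tabulate pseudounits over a set of raw units
#'
#' Groups raw unit strings by the pseudounit they normalize to and counts,
#' per pseudounit, the number of distinct raw surface forms and the total
#' number of uses. Use-count mass is conserved: the \code{total_uses}
#' column sums to the input's total.
#'
#' @param raws Data frame with columns \code{raw} (character) and
#'   \code{n_uses} (positive integer), one row per distinct raw form.
#' @param rules A pseudo-phase \code{rule_set}.
#' @return Data frame with columns \code{pseudounit},
#'   \code{n_distinct_raw_forms}, \code{total_uses}, sorted by decreasing
#'   \code{total_uses}.
#' @export
tabulate_pseudounits <- function(raws, rules = default_rules("pseudo")) {
  stopifnot(is.data.frame(raws), all(c("raw", "n_uses") %in% names(raws)))
  if (nrow(raws) == 0) {
    return(data.frame(pseudounit = character(0),
                      n_distinct_raw_forms = integer(0),
                      total_uses = integer(0)))
  }
  if (any(raws$n_uses < 1)) stop("n_uses must be >= 1", call. = FALSE)
  ps <- to_pseudounit(raws$raw, rules)
  distinct <- tapply(raws$raw, ps, function(v) length(unique(v)))
  uses <- tapply(raws$n_uses, ps, sum)
  out <- data.frame(pseudounit = names(distinct),
                    n_distinct_raw_forms = as.integer(distinct),
                    total_uses = as.integer(uses[names(distinct)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total_uses, out$pseudounit), , drop = FALSE]
  rownames(out) <- NULL
  out
}
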