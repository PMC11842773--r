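# The eight QUDT basis dimensions, in the fixed order used by the canonical
# text notation: amount of substance, electric current, length, luminous
# intensity, mass, thermodynamic temperature, time, dimensionless.
DV_LETTERS <- c("A", "E", "L", "I", "M", "H", "T", "D")

#' Parse a QUDT-style dimension vector string
#'
#' A dimension vector gives the exponent of a unit over the eight QUDT basis
#' dimensions. The canonical notation lists all eight letters in the fixed
#' order A, E, L, I, M, H, T, D, each followed by a signed rational exponent.
#' Half-integer exponents (which QUDT uses for a few units) are written with
#' "dot5", e.g. \code{"A0E0L1dot5I0M0H0T0D0"}.
#'
#' Exponents are stored as numeric values; integers and halves are exactly
#' representable, so equality of vectors (which gates unit conversion) is
#' exact.
#'
#' @param text Canonical dimension-vector notation, e.g.
#'   \code{"A0E0L1I0M0H0T-2D0"}.
#' @return A named numeric vector of length 8 with names
#'   \code{c("A","E","L","I","M","H","T","D")}, of class
#'   \code{"dimension_vector"}.
#' @examples
#' parse_dimension_vector("A0E0L1I0M0H0T-2D0")  # acceleration
#' parse_dimension_vector("A0E0L0I0M0H0T0D1")   # dimensionless
#' @export
parse_dimension_vector <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("dimension vector must be a single character string", call. = FALSE)
  }
  num <- "-?[0-9]+(dot[0-9]+)?"
  full <- paste0("^", paste0(DV_LETTERS, "(", num, ")", collapse = ""), "$")
  if (!grepl(full, text)) {
    stop("not a canonical dimension vector: '", text,
         "' (expect all of A,E,L,I,M,H,T,D in order, each with a signed ",
         "rational exponent)", call. = FALSE)
  }
  m <- regmatches(text, gregexpr(paste0("[AELIMHTD]", num), text))[[1]]
  exps <- vapply(m, function(piece) {
    val <- sub("^[AELIMHTD]", "", piece)
    as.numeric(sub("dot", ".", val, fixed = TRUE))
  }, numeric(1), USE.NAMES = FALSE)
  structure(stats::setNames(exps, DV_LETTERS), class = "dimension_vector")
}

#' Render a dimension vector back to canonical notation
#'
#' Inverse of [parse_dimension_vector()]: \code{render(parse(t)) == t} for
#' every canonical input.
#'
#' @param dv A \code{dimension_vector} (or named numeric vector of length 8).
#' @return A single string in canonical notation.
#' @export
render_dimension_vector <- function(dv) {
  stopifnot(length(dv) == 8L)
  piece <- vapply(unname(dv), function(x) {
    neg <- x < 0
    ax <- abs(x)
    ip <- floor(ax)
    frac <- ax - ip
    s <- if (frac == 0) format(ip, scientific = FALSE) else
      paste0(format(ip, scientific = FALSE), "dot",
             sub("^0\\.", "", format(frac, scientific = FALSE)))
    if (neg) paste0("-", s) else s
  }, character(1))
  paste0(DV_LETTERS, piece, collapse = "")
}

#' Test two dimension vectors for exact equality
#'
#' Equality of dimension vectors is what licenses a direct unit conversion:
#' two units are inter-convertible only when all eight exponents agree
#' exactly.
#'
#' @param a,b Dimension vectors as returned by [parse_dimension_vector()].
#' @return \code{TRUE} or \code{FALSE}.
#' @export
dimension_vectors_equal <- function(a, b) {
  stopifnot(length(a) == 8L, length(b) == 8L)
  all(unname(a) == unname(b))
}

#' @export
print.dimension_vector <- function(x, ...) {
  nz <- x[x != 0]
  if (length(nz) == 0) {
    cat("<dimension vector: all zero>\n")
  } else {
    cat("<dimension vector:",
        paste0(names(nz), "^", unname(nz), collapse = " "), ">\n")
  }
  invisible(x)
}
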