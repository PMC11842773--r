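EML_22_NS <- "https://eml.ecoinformatics.org/eml-2.2.0"

# QUDT's "has unit" predicate; the default property half of the annotation
# triple (overridable — repositories differ in their preferred predicate).
QUDT_HAS_UNIT_URI <- "http://qudt.org/schema/qudt/hasUnit"

read_eml <- function(path_or_doc) {
  doc <- if (inherits(path_or_doc, "xml_document")) path_or_doc
         else xml2::read_xml(path_or_doc)
  ns <- xml2::xml_ns(doc)
  # 2.2+ uses https://eml.ecoinformatics.org/...; 2.1 and older used the
  # eml://ecoinformatics.org/... scheme
  if (!any(grepl("ecoinformatics\\.org/eml-", unlist(ns)))) {
    stop("document does not declare an EML namespace", call. = FALSE)
  }
  if (!any(grepl("eml-2\\.2", unlist(ns)))) {
    stop("only EML 2.2 documents can be annotated (annotation elements ",
         "entered the schema at 2.2); found an older EML namespace",
         call. = FALSE)
  }
  doc
}

#' Extract unit declarations from an EML document
#'
#' Finds every attribute-level unit element (\code{standardUnit} or
#' \code{customUnit}) in document order and reports the raw unit text along
#' with the owning attribute's identifier.
#'
#' @param eml Path to an EML 2.2 XML file, or an \code{xml_document}.
#' @return Data frame with columns \code{attribute_id} (the id attribute,
#'   or \code{NA} when absent), \code{attribute_name}, \code{raw_unit},
#'   \code{unit_kind} (\code{"standardUnit"} or \code{"customUnit"}) and
#'   \code{position} (index of the attribute among all attributes, in
#'   document order).
#' @export
extract_units <- function(eml) {
  doc <- read_eml(eml)
  attrs <- xml2::xml_find_all(doc, "//*[local-name()='attribute']")
  rows <- list()
  for (i in seq_along(attrs)) {
    a <- attrs[[i]]
    unit <- xml2::xml_find_first(a, ".//*[local-name()='standardUnit' or local-name()='customUnit']")
    if (inherits(unit, "xml_missing")) next
    rows[[length(rows) + 1L]] <- data.frame(
      attribute_id = xml2::xml_attr(a, "id"),
      attribute_name = xml2::xml_text(
        xml2::xml_find_first(a, ".//*[local-name()='attributeName']")),
      raw_unit = xml2::xml_text(unit),
      unit_kind = xml2::xml_name(unit),
      position = i,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(attribute_id = character(0),
                      attribute_name = character(0),
                      raw_unit = character(0), unit_kind = character(0),
                      position = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate an EML document with QUDT unit URIs
#'
#' For every attribute whose declared unit resolves through the lookup
#' table, appends an \code{annotation} element inside the attribute: an
#' RDF-triple-style pair of \code{propertyURI} (the "has unit" predicate)
#' and \code{valueURI} (the QUDT unit URI), each carrying a human-readable
#' label. Annotation is idempotent — an identical existing annotation is
#' never duplicated — and the source document is never modified in place.
#'
#' @param eml Path to an EML 2.2 file, or an \code{xml_document}.
#' @param table A \code{lookup_table}.
#' @param vocab The vocabulary the table was built against.
#' @param pseudo_rules,qudt_rules Rule sets for the resolve fallback.
#' @param bump_revision Increment the trailing revision integer of the
#'   document's \code{packageId} (errors if the id does not end in one).
#' @param add_ids Give attributes lacking an \code{id} a deterministic
#'   generated one (\code{<prefix><position>}); attributes without an id
#'   cannot legally carry annotations and are otherwise skipped.
#' @param property_uri,property_label The predicate half of the triple.
#' @param id_prefix Prefix for generated ids.
#' @return A list with \code{doc} (the edited \code{xml_document}) and
#'   \code{report} (data frame: attribute_id, raw_unit, matched, qudt_code,
#'   value_uri, match_path, note).
#' @export
annotate_document <- function(eml, table,
                              vocab = qudt_fixture_vocabulary(),
                              pseudo_rules = default_rules("pseudo"),
                              qudt_rules = default_rules("qudt"),
                              bump_revision = FALSE, add_ids = FALSE,
                              property_uri = QUDT_HAS_UNIT_URI,
                              property_label = "has unit",
                              id_prefix = "attr") {
  src <- read_eml(eml)
  doc <- xml2::read_xml(as.character(src))  # work on a copy

  if (bump_revision) {
    pid <- xml2::xml_attr(doc, "packageId")
    if (is.na(pid) || !grepl("\\.[0-9]+$", pid)) {
      stop("packageId '", if (is.na(pid)) "" else pid,
           "' does not end in a revision integer; cannot bump revision",
           call. = FALSE)
    }
    rev <- as.integer(sub("^.*\\.([0-9]+)$", "\\1", pid))
    xml2::xml_set_attr(doc, "packageId",
                       sub("\\.[0-9]+$", paste0(".", rev + 1L), pid))
  }

  attrs <- xml2::xml_find_all(doc, "//*[local-name()='attribute']")
  report <- list()
  for (i in seq_along(attrs)) {
    a <- attrs[[i]]
    unit <- xml2::xml_find_first(a, ".//*[local-name()='standardUnit' or local-name()='customUnit']")
    if (inherits(unit, "xml_missing")) next
    raw <- xml2::xml_text(unit)
    id <- xml2::xml_attr(a, "id")
    note <- ""
    if (is.na(id)) {
      if (add_ids) {
        id <- paste0(id_prefix, i)
        xml2::xml_set_attr(a, "id", id)
        note <- "id generated"
      } else {
        report[[length(report) + 1L]] <- data.frame(
          attribute_id = NA_character_, raw_unit = raw, matched = FALSE,
          qudt_code = NA_character_, value_uri = NA_character_,
          match_path = NA_character_,
          note = "skipped: attribute has no id", stringsAsFactors = FALSE)
        next
      }
    }
    res <- resolve(raw, table, vocab, pseudo_rules, qudt_rules)
    if (res$match_path == "unmatched") {
      report[[length(report) + 1L]] <- data.frame(
        attribute_id = id, raw_unit = raw, matched = FALSE,
        qudt_code = NA_character_, value_uri = NA_character_,
        match_path = "unmatched", note = note, stringsAsFactors = FALSE)
      next
    }
    u <- res$matched_unit
    existing <- xml2::xml_find_all(a, "./*[local-name()='annotation']")
    dup <- any(vapply(existing, function(an) {
      p <- xml2::xml_text(xml2::xml_find_first(an, "./*[local-name()='propertyURI']"))
      v <- xml2::xml_text(xml2::xml_find_first(an, "./*[local-name()='valueURI']"))
      identical(p, property_uri) && identical(v, u$uri)
    }, logical(1)))
    if (!dup) {
      an <- xml2::xml_add_child(a, "annotation")
      p <- xml2::xml_add_child(an, "propertyURI", property_uri)
      xml2::xml_set_attr(p, "label", property_label)
      v <- xml2::xml_add_child(an, "valueURI", u$uri)
      xml2::xml_set_attr(v, "label", u$label)
    }
    report[[length(report) + 1L]] <- data.frame(
      attribute_id = id, raw_unit = raw, matched = TRUE,
      qudt_code = u$code, value_uri = u$uri, match_path = res$match_path,
      note = if (dup) paste(note, "already annotated") else note,
      stringsAsFactors = FALSE)
  }
  report <- if (length(report) > 0) do.call(rbind, report) else
    data.frame(attribute_id = character(0), raw_unit = character(0),
               matched = logical(0), qudt_code = character(0),
               value_uri = character(0), match_path = character(0),
               note = character(0))
  rownames(report) <- NULL
  list(doc = doc, report = report)
}

#' Validate an EML document against the bundled subset schema
#'
#' The package ships a hand-authored subset XSD (labelled synthetic)
#' covering the EML 2.2 element structure the annotator reads and writes —
#' dataset, dataTable, attributeList, attribute, measurementScale, unit and
#' annotation, including the required element order and the label
#' attributes on both URI elements.
#'
#' @param eml Path or \code{xml_document}.
#' @return \code{TRUE}/\code{FALSE} with validation errors in attribute
#'   \code{"errors"} (as [xml2::xml_validate()]).
#' @export
eml_validate_subset <- function(eml) {
  doc <- if (inherits(eml, "xml_document")) eml else xml2::read_xml(eml)
  schema <- xml2::read_xml(system.file("extdata",
                                       "eml-2.2-subset-synthetic.xsd",
                                       package = "qudtmapper",
                                       mustWork = TRUE))
  xml2::xml_validate(doc, schema)
}
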