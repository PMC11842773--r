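# Shared fixtures, loaded once per test run.
fx_vocab <- qudt_fixture_vocabulary()
fx_pseudo <- default_rules("pseudo")
fx_qudt <- default_rules("qudt")
fx_table <- build_lookup_table(NULL, fx_vocab, fx_pseudo, fx_qudt)

# The six surface variants of gram-per-square-metre used as the canonical
# equivalence-class example throughout.
gm_per_m2_variants <- c("gm/m2", "g/m2", "gm-2", "g/m^2", "g.m-2",
                        "gramPerMeterSquared")

# Write a minimal EML 2.2 document with the given unit declarations
# (named list attr name -> c(kind, unit text)); returns the file path.
write_eml_fixture <- function(units, path = tempfile(fileext = ".xml"),
                              package_id = "synth.1.1", with_ids = TRUE) {
  attrs <- character(0)
  i <- 0
  for (nm in names(units)) {
    i <- i + 1
    kind <- units[[nm]][1]
    val <- units[[nm]][2]
    id_attr <- if (with_ids) sprintf(' id="att.%d"', i) else ""
    scale <- if (is.na(val)) {
      paste0("<nominal><nonNumericDomain><textDomain><definition>x",
             "</definition></textDomain></nonNumericDomain></nominal>")
    } else {
      paste0("<ratio><unit><", kind, ">", val, "</", kind, "></unit>",
             "<numericDomain><numberType>real</numberType>",
             "</numericDomain></ratio>")
    }
    attrs <- c(attrs, paste0(
      "<attribute", id_attr, "><attributeName>", nm, "</attributeName>",
      "<attributeDefinition>def</attributeDefinition>",
      "<measurementScale>", scale, "</measurementScale></attribute>"))
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<eml:eml xmlns:eml="https://eml.ecoinformatics.org/eml-2.2.0" ',
    'packageId="', package_id, '" system="synthetic">',
    "<dataset><title>t</title>",
    "<creator><organizationName>o</organizationName></creator>",
    "<contact><organizationName>o</organizationName></contact>",
    "<dataTable><entityName>e</entityName><attributeList>",
    paste(attrs, collapse = ""),
    "</attributeList></dataTable></dataset></eml:eml>")
  writeLines(doc, path)
  path
}
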