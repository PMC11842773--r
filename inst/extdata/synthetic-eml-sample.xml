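<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic EML 2.2 sample document for exercising the unit annotator.
     Not a real data package. -->
<eml:eml xmlns:eml="https://eml.ecoinformatics.org/eml-2.2.0"
         packageId="knb-synth-example.101.4" system="synthetic">
  <dataset>
    <title>Soil pore water chemistry (synthetic sample)</title>
    <creator>
      <organizationName>Example Research Site</organizationName>
    </creator>
    <contact>
      <organizationName>Example Research Site</organizationName>
    </contact>
    <dataTable>
      <entityName>porewater_chemistry</entityName>
      <attributeList>
        <attribute id="att.depth">
          <attributeName>depth</attributeName>
          <attributeDefinition>Sampling depth below the sediment surface</attributeDefinition>
          <measurementScale>
            <ratio>
              <unit>
                <standardUnit>meter</standardUnit>
              </unit>
              <numericDomain>
                <numberType>real</numberType>
              </numericDomain>
            </ratio>
          </measurementScale>
        </attribute>
        <attribute id="att.po4">
          <attributeName>phosphate</attributeName>
          <attributeDefinition>Phosphate concentration in soil pore water</attributeDefinition>
          <measurementScale>
            <ratio>
              <unit>
                <customUnit>micromolesPerLiter</customUnit>
              </unit>
              <numericDomain>
                <numberType>real</numberType>
              </numericDomain>
            </ratio>
          </measurementScale>
        </attribute>
        <attribute id="att.site">
          <attributeName>siteCode</attributeName>
          <attributeDefinition>Site identifier</attributeDefinition>
          <measurementScale>
            <nominal>
              <nonNumericDomain>
                <textDomain>
                  <definition>alphanumeric site code</definition>
                </textDomain>
              </nonNumericDomain>
            </nominal>
          </measurementScale>
        </attribute>
      </attributeList>
    </dataTable>
  </dataset>
</eml:eml>
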