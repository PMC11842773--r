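<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic subset schema for EML 2.2, hand-authored for this package.
     It covers only the element structure the unit annotator reads and
     writes: dataset / dataTable / attributeList / attribute with
     measurementScale (ratio | interval | nominal), unit declarations and
     annotation elements (propertyURI + valueURI, both with a required
     label attribute and both constrained to absolute URIs). It is NOT the
     official EML schema; it mirrors EML's qualified root element with
     unqualified local elements. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           xmlns:eml="https://eml.ecoinformatics.org/eml-2.2.0"
           targetNamespace="https://eml.ecoinformatics.org/eml-2.2.0"
           elementFormDefault="unqualified">

  <xs:element name="eml">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="dataset" type="eml:DatasetType"/>
      </xs:sequence>
      <xs:attribute name="packageId" type="xs:string" use="required"/>
      <xs:attribute name="system" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>

  <xs:complexType name="DatasetType">
    <xs:sequence>
      <xs:element name="title" type="xs:string"/>
      <xs:element name="creator" type="eml:PartyType" maxOccurs="unbounded"/>
      <xs:element name="contact" type="eml:PartyType" maxOccurs="unbounded"/>
      <xs:element name="dataTable" type="eml:DataTableType"
                  minOccurs="0" maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="PartyType">
    <xs:sequence>
      <xs:element name="organizationName" type="xs:string"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="DataTableType">
    <xs:sequence>
      <xs:element name="entityName" type="xs:string"/>
      <xs:element name="attributeList">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="attribute" type="eml:AttributeType"
                        maxOccurs="unbounded"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
    <xs:attribute name="id" type="xs:string"/>
  </xs:complexType>

  <xs:complexType name="AttributeType">
    <xs:sequence>
      <xs:element name="attributeName" type="xs:string"/>
      <xs:element name="attributeDefinition" type="xs:string"/>
      <xs:element name="storageType" type="xs:string" minOccurs="0"/>
      <xs:element name="measurementScale" type="eml:MeasurementScaleType"/>
      <xs:element name="missingValueCode" type="xs:string"
                  minOccurs="0" maxOccurs="unbounded"/>
      <xs:element name="annotation" type="eml:AnnotationType"
                  minOccurs="0" maxOccurs="unbounded"/>
    </xs:sequence>
    <xs:attribute name="id" type="xs:string"/>
  </xs:complexType>

  <xs:complexType name="MeasurementScaleType">
    <xs:choice>
      <xs:element name="ratio" type="eml:NumericScaleType"/>
      <xs:element name="interval" type="eml:NumericScaleType"/>
      <xs:element name="nominal" type="eml:NominalScaleType"/>
    </xs:choice>
  </xs:complexType>

  <xs:complexType name="NumericScaleType">
    <xs:sequence>
      <xs:element name="unit">
        <xs:complexType>
          <xs:choice>
            <xs:element name="standardUnit" type="xs:string"/>
            <xs:element name="customUnit" type="xs:string"/>
          </xs:choice>
        </xs:complexType>
      </xs:element>
      <xs:element name="numericDomain">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="numberType" type="xs:string"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="NominalScaleType">
    <xs:sequence>
      <xs:element name="nonNumericDomain">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="textDomain">
              <xs:complexType>
                <xs:sequence>
                  <xs:element name="definition" type="xs:string"/>
                </xs:sequence>
              </xs:complexType>
            </xs:element>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="AnnotationType">
    <xs:sequence>
      <xs:element name="propertyURI" type="eml:LabelledUriType"/>
      <xs:element name="valueURI" type="eml:LabelledUriType"/>
    </xs:sequence>
  </xs:complexType>

  <xs:simpleType name="AbsoluteUriType">
    <xs:restriction base="xs:anyURI">
      <xs:pattern value="https?://.+"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:complexType name="LabelledUriType">
    <xs:simpleContent>
      <xs:extension base="eml:AbsoluteUriType">
        <xs:attribute name="label" use="required">
          <xs:simpleType>
            <xs:restriction base="xs:string">
              <xs:minLength value="1"/>
            </xs:restriction>
          </xs:simpleType>
        </xs:attribute>
      </xs:extension>
    </xs:simpleContent>
  </xs:complexType>

</xs:schema>
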