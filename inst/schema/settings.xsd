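<?xml version="1.0" encoding="UTF-8"?>
<!-- Normative schema for the run-settings XML read by parse_settings().
     The tag vocabulary is defined by this package. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:element name="sensitivitySettings">
    <xs:complexType>
      <xs:all>
        <xs:element name="technique">
          <xs:simpleType>
            <xs:restriction base="xs:string">
              <xs:enumeration value="LOCAL"/>
              <xs:enumeration value="LHS"/>
              <xs:enumeration value="EFAST"/>
              <xs:enumeration value="SNAPSHOT"/>
              <xs:enumeration value="INTERVENTION"/>
            </xs:restriction>
          </xs:simpleType>
        </xs:element>
        <xs:element name="modelPath" type="xs:string"/>
        <xs:element name="outputDir" type="xs:string" minOccurs="0"/>
        <xs:element name="solver" minOccurs="0">
          <xs:complexType>
            <xs:attribute name="tEnd" type="xs:double"/>  <!-- default 144 -->
            <xs:attribute name="step" type="xs:double"/>  <!-- default 0.12 -->
          </xs:complexType>
        </xs:element>
        <xs:element name="lhs" minOccurs="0">
          <xs:complexType>
            <xs:attribute name="samples" type="xs:positiveInteger"
                          use="required"/> <!-- >= 2 -->
          </xs:complexType>
        </xs:element>
        <xs:element name="efast" minOccurs="0">
          <xs:complexType>
            <!-- samplesPerCurve must be odd and >= 65; curves default 3 -->
            <xs:attribute name="curves" type="xs:positiveInteger"/>
            <xs:attribute name="samplesPerCurve" type="xs:positiveInteger"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="local" minOccurs="0">
          <xs:complexType>
            <xs:attribute name="increments" type="xs:positiveInteger"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="ranges" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="range" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="target" type="xs:string"
                                use="required"/>
                  <xs:attribute name="kind" default="parameter">
                    <xs:simpleType>
                      <xs:restriction base="xs:string">
                        <xs:enumeration value="parameter"/>
                        <xs:enumeration value="species_initial"/>
                      </xs:restriction>
                    </xs:simpleType>
                  </xs:attribute>
                  <xs:attribute name="min" type="xs:double" use="required"/>
                  <xs:attribute name="max" type="xs:double" use="required"/>
                  <xs:attribute name="baseline" type="xs:double"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="interventions" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="intervention" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="target" type="xs:string"
                                use="required"/>
                  <xs:attribute name="kind" default="species_initial">
                    <xs:simpleType>
                      <xs:restriction base="xs:string">
                        <xs:enumeration value="parameter"/>
                        <xs:enumeration value="species_initial"/>
                      </xs:restriction>
                    </xs:simpleType>
                  </xs:attribute>
                  <xs:attribute name="mode" default="SET">
                    <xs:simpleType>
                      <xs:restriction base="xs:string">
                        <xs:enumeration value="SET"/>
                        <xs:enumeration value="SCALE"/>
                      </xs:restriction>
                    </xs:simpleType>
                  </xs:attribute>
                  <xs:attribute name="magnitude" type="xs:double"
                                use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:all>
    </xs:complexType>
  </xs:element>
</xs:schema>
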