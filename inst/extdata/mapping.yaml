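# Declarative table -> graph mapping for the synthetic study bundle.
# Dates arrive as dd-MM-yyyy and are normalized to xsd:date (yyyy-MM-dd);
# coded fields are decoded via the codebooks below (Gender 0 = Female).
codebooks:
  gender:
    "0": Female
    "1": Male
  comorbidity:
    "0": absent
    "1": present
mappings:
  - source: patients
    subject: "http://data.avert.ie/patient/{PatientID}"
    types: [avert:Patient, geo:Feature]
    predicate_objects:
      - predicate: rdfs:label
        template: "{PatientID}"
      - predicate: foaf:gender
        template: "{Gender}"
        transform: {kind: decode, codebook: gender}
      - predicate: avert:comorbidity
        template: "{Comorbidity}"
        transform: {kind: decode, codebook: comorbidity}
      - predicate: avert:dateOfBirth
        template: "{DOB}"
        transform: {kind: date, pattern: dd-MM-yyyy}
      - predicate: avert:diagnosisDate
        template: "{DiagnosisDate}"
        transform: {kind: date, pattern: dd-MM-yyyy}
      - predicate: geo:hasGeometry
        template: "http://data.avert.ie/patient/{PatientID}/geom"
        kind: iri
  - source: patients
    subject: "http://data.avert.ie/patient/{PatientID}/geom"
    types: [geo:Geometry]
    predicate_objects:
      - predicate: geo:asWKT
        template: "POINT ({Lon} {Lat})"
        datatype: geo:wktLiteral
  - source: stations
    subject: "http://data.avert.ie/weather_station/{name}"
    types: [avert:WeatherStation, geo:Feature]
    predicate_objects:
      - predicate: rdfs:label
        template: "{name}"
      - predicate: geo:hasGeometry
        template: "http://data.avert.ie/weather_station/{name}/geom"
        kind: iri
  - source: stations
    subject: "http://data.avert.ie/weather_station/{name}/geom"
    types: [geo:Geometry]
    predicate_objects:
      - predicate: geo:asWKT
        template: "POINT ({lon} {lat})"
        datatype: geo:wktLiteral
  - source: regions
    subject: "http://data.avert.ie/region/{RegionID}"
    types: [avert:Region, geo:Feature]
    predicate_objects:
      - predicate: rdfs:label
        template: "{Label}"
      - predicate: avert:level
        template: "{Level}"
      - predicate: geo:hasGeometry
        template: "http://data.avert.ie/region/{RegionID}/geom"
        kind: iri
  - source: regions
    subject: "http://data.avert.ie/region/{RegionID}/geom"
    types: [geo:Geometry]
    predicate_objects:
      - predicate: geo:asWKT
        template: "{WKT}"
        datatype: geo:wktLiteral
  - source: observations
    subject: "http://data.avert.ie/observation/{Station}/{Date}"
    types: [avert:Observation]
    predicate_objects:
      - predicate: avert:atStation
        template: "http://data.avert.ie/weather_station/{Station}"
        kind: iri
      - predicate: avert:onDate
        template: "{Date}"
        transform: {kind: date, pattern: dd-MM-yyyy}
      - predicate: avert:temperatureC
        template: "{TemperatureC}"
        datatype: xsd:double
      - predicate: avert:rainfallMm
        template: "{RainfallMm}"
        datatype: xsd:double
  - source: weekly_counts
    subject: "http://data.avert.ie/weekly_count/{RegionID}/{ISOWeek}"
    types: [avert:WeeklyCount]
    predicate_objects:
      - predicate: avert:region
        template: "http://data.avert.ie/region/{RegionID}"
        kind: iri
      - predicate: avert:isoWeek
        template: "{ISOWeek}"
      - predicate: avert:count
        template: "{Count}"
        datatype: xsd:integer
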