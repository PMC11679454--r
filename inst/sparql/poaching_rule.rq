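# Buffer-zone poaching rule: bind a binary poaching indicator on every GPS
# observation from its haversine distance to the oil-palm plantation node.
PREFIX xsd: <http://www.w3.org/2001/XMLSchema#>
INSERT { ?observation <https://w3id.org/def/foo#poaching> ?poaching }
WHERE {
  ?observation a <https://w3id.org/def/foo#gPSObservation> ;
      <http://www.w3.org/2003/01/geo/wgs84_pos#latitude>  ?lat ;
      <http://www.w3.org/2003/01/geo/wgs84_pos#longitude> ?long .
  <https://w3id.org/def/foo#plantation> a <https://w3id.org/def/foo#OilPalmPlantation> ;
      <http://www.w3.org/2003/01/geo/wgs84_pos#latitude>  ?plantationLat ;
      <http://www.w3.org/2003/01/geo/wgs84_pos#longitude> ?plantationLong .
  # Convert coordinates to float (if stored as literals)
  BIND(xsd:float(?lat) AS ?latitude)
  BIND(xsd:float(?long) AS ?longitude)
  BIND(xsd:float(?plantationLat) AS ?oilpalmLat)
  BIND(xsd:float(?plantationLong) AS ?oilpalmLong)
  # Calculate distance using the haversine formula
  BIND(6371 * 2 * ASIN(SQRT(
    POW(SIN((?latitude - ?oilpalmLat) * PI() / 180 / 2), 2) +
    COS(?oilpalmLat * PI() / 180) * COS(?latitude * PI() / 180) *
    POW(SIN((?longitude - ?oilpalmLong) * PI() / 180 / 2), 2)
  )) AS ?distance)
  # Determine poaching based on the calculated distance
  BIND(IF(?distance <= 5, 1, 0) AS ?poaching)
}
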