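# Retrieve poaching status as a Turtle subgraph with the geo-location
# coordinates, local date and poaching likelihood.
CONSTRUCT WHERE {
  ?Observation a <https://w3id.org/def/foo#gPSObservation> ;
      <https://w3id.org/def/foo#localDate> ?LocalDate ;
      <http://www.w3.org/2003/01/geo/wgs84_pos#latitude>  ?lat ;
      <http://www.w3.org/2003/01/geo/wgs84_pos#longitude> ?long ;
      <https://w3id.org/def/foo#poaching> ?poaching .
}
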