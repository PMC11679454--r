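# Extract per-observation geo-location rows: latitude, longitude,
# local date and local time of every GPS observation.
SELECT *
WHERE {
  ?observation a <https://w3id.org/def/foo#gPSObservation> ;
      <http://www.w3.org/2003/01/geo/wgs84_pos#latitude>  ?lat ;
      <http://www.w3.org/2003/01/geo/wgs84_pos#longitude> ?long ;
      <https://w3id.org/def/foo#localDate> ?localDate ;
      <https://w3id.org/def/foo#localTime> ?localTime .
}
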