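population,state,latitude,elevation_m,migration_km
Coleman,CA,40.398,123,441
Elk River,OR,42.740,35,22
Feather River,CA,39.519,41,233
Priest Rapids,WA,46.630,125,631
Trask River,OR,45.433,17,28
Trinity River,CA,40.727,562,250
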