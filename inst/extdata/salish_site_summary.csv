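site_id,n_samples,p95_ear_mix,pct_male_vtg,pct_female_altered_timing
Port Susan,6,1338,6.8,8
Port Gardner,38,3119,18.8,9
Hood Canal,33,548,5.7,6
Eagle Harbor,20,436,0,4
Myrtle Edwards,15,2913,46.9,81
Bell Harbor,57,32346,37.5,65
Duwamish Waterway,47,831,17.6,0
Bremerton,29,830,5.9,6
Commencement Bay-Thea Foss Waterway,25,505,21.7,2
Nisqually,13,6345,0,5
Strait of Georgia,12,1831,,
Vendovi Island,8,1848,,
Port Madison,9,1273,,
West Point North,10,1436,,
West Point South,7,546,,
Commencement Bay-Hylebos Waterway,9,2466,,
Commencement Bay-Blair Waterway,10,1901,,
Carr Inlet,6,49519,,
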