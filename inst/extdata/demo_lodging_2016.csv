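cultivar,year,level_speed,lodged_count
CVA,2016,20,50
CVB,2016,>Smax,50
CVC,2016,12,30
CVC,2016,24,20
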