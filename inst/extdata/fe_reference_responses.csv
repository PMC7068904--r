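run_id,combination,varus_deg,slope_deg,rotation_deg,peak_pressure_mpa
1,A1B1C1,0,1,3,18.99
2,A1B2C2,0,2,4,17.10
3,A1B3C3,0,3,5,20.46
4,A2B1C2,3,1,4,22.18
5,A2B2C3,3,2,5,24.10
6,A2B3C1,3,3,3,21.26
7,A3B1C3,-3,1,5,22.68
8,A3B2C1,-3,2,3,29.73
9,A3B3C2,-3,3,4,24.25
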