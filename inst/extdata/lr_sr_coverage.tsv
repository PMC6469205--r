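bin	lr_coverage	sr_coverage
B1	57.3	117.5
B2	384.2	707.8
B3	48.8	107.6
B4	25.1	56.2
B5	52.1	109.9
B6	29.5	56.1
B7	38.7	90.2
B8	32.7	60.5
B9	10.2	23.2
B10	14.1	27.7
B11	15.4	22.3
B12	37.1	66.0
B13	17.6	28.7
B14	13.3	18.9
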