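# Toy TATA-box-like matrix for tests and examples (synthetic counts,
# not derived from any curated database).
NA TATA_toy
P0  A   C   G   T
01  0   1   1  18
02 18   1   0   1
03  1   0   1  18
04 18   1   1   0
05 12   0   0   8
06 17   1   1   1
07 11   1   1   7
//
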