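# Toy GCC-box-like (AGCCGCC) matrix for tests and examples (synthetic
# counts, not derived from any curated database).
NA GCC_toy
P0  A   C   G   T
01 16   2   1   1
02  1   1  17   1
03  1  17   1   1
04  1  17   1   1
05  1   1  17   1
06  1  17   1   1
07  1  17   1   1
//
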