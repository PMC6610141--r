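qualification	years
None	15
CSE/O level/GCSE	16
NVQ/HND/HNC	18
A level	18
Other professional qualification	20
College or University degree	21
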