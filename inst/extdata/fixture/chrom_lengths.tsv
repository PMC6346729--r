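chrom	length
SSC1	5e+05
SSC2	5e+05
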