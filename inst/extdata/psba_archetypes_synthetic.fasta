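>long species=synthetic_archetype region=psbA-trnH source=synthetic_long_stem
GGCAGGGGCAGGAAACCTGCCCCTGCC
>short species=synthetic_archetype region=psbA-trnH source=synthetic_short_stem_deletion
GGCAGGAAACCTGCC
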