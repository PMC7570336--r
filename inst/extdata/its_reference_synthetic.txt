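# Synthetic two-segment ITS reference barcode (case-encoded):
# lowercase = essential base (exact, ambiguity-aware match required),
# uppercase = context (counts toward the 95% overall identity threshold).
# The base string is synthetic reference data, not a published sequence.
>its-reference-v1 segment=ITS1 threshold=0.95 species=H._perforatum
ATTCACGTCGCcgTATCGGYCGTTGAGCCGCTTATTCCGrttGGCCGCCCAGTAAAATCAAACCCTgCTAGTCAGCCGGA
>its-reference-v1 segment=ITS2 threshold=0.95 species=H._perforatum
TGCTGATacTCACTAAGCAAGCTTACATCcgGTAGTACCACAAACGCTGCGCGTttCCCTGCCTATAATWCTGGCGCAAggGATCTCGGTGGACAAATTA
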