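# GA-rich exonic splicing enhancer hexamers (consensus-derived starter set).
GAAGAA
AAGAAG
AGAAGA
GAAGAG
GAGGAA
AAGGAA
GAAGGA
UGAAGA
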