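# UAG-core exonic splicing silencer hexamers (consensus-derived starter set).
UAGGGU
UAGGGA
GUAGGU
UUAGGG
UAGAGU
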