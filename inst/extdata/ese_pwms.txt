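# Consensus-derived splicing-regulatory PWMs (log-odds per position).
# Format: ">name kind threshold" then four tab-delimited rows A/C/G/U x width.
# GA-ESE: purine-rich GA(A/G)-type exonic splicing enhancer consensus of the
#   kind bound by SR proteins (GAAGAA core).
# UAG-ESS: UAG-core exonic splicing silencer consensus of the kind bound by
#   hnRNP A1 (UAGGGU core).
# These matrices are consensus-derived approximations shipped as a starter
# library; replace the file to use a different motif collection.
>GA-ESE ESE 4.5
A	-0.5	1.0	1.0	-0.5	1.0	1.0
C	-1.0	-1.0	-1.0	-1.0	-1.0	-1.0
G	1.0	0.5	0.0	1.0	0.5	0.5
U	-1.0	-1.0	-1.0	-1.0	-1.0	-1.0
>UAG-ESS ESS 5.0
A	-1.0	1.0	-1.0	-1.0	0.5	0.5
C	-1.0	-1.0	-1.0	-1.0	-1.0	-1.0
G	-1.0	-1.0	1.0	1.0	1.0	-1.0
U	1.0	-1.0	-1.0	-1.0	-1.0	1.0
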