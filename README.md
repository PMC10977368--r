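# aondesign

Design and in-silico validation of splice-switching antisense
oligonucleotides (AONs) that knock a gene down by forcing skipping of an
out-of-frame internal exon.

When an AON hybridizes over an exon's recognition elements, the spliceosome
drops that exon from the mature mRNA. If the exon length *L* satisfies
*L* mod 3 ≠ 0, the downstream reading frame shifts, a premature termination
codon (PTC) appears, and the gene is effectively knocked down — via
nonsense-mediated decay (predicted here with the 50-nt junction rule)
and/or a truncated protein. The motivating use case is knockdown of mouse
IGF-binding proteins (*Igfbp1*/*Igfbp3*, both with an out-of-frame exon 2)
to enhance IGF-1 signaling; the machinery is generic.

The package covers the full in-silico workflow:

| stage | functions |
|---|---|
| gene models: GFF3/GTF + FASTA parsing, frame classification, exon-skip simulation (frameshift, PTC, NMD) | `parse_annotation()`, `classify_exon_frame()`, `simulate_exon_skip()`, `extract_target_region()` |
| accessibility: stacking-weighted nested-structure fold, ss-count openness profile over a suboptimal ensemble | `fold_mfe()`, `ss_count_profile()` |
| splice signals: ESE/ESS PWM + hexamer scanning, window densities | `scan_motifs()`, `ese_density()`, `default_motif_library()` |
| hybridization: GC%, nearest-neighbor Tm, binding ΔG, self/cross-dimer screens (Xia et al. 1998 RNA/RNA table) | `gc_content()`, `tm_nearest_neighbor()`, `duplex_score()` |
| design: window enumeration, hard filters, composite ranking | `design_config()`, `enumerate_candidates()`, `score_and_rank()`, `design_aons()` |
| in-silico assay: nested RT-PCR product sizes, virtual gel, relative qPCR | `pcr_products()`, `virtual_gel()`, `qpcr_relative()` |
| expression counts: CPM filtering ahead of differential expression | `cpm_filter()` |
| synthetic data: seeded toy genes with planted truth, paper-like fixtures, NB count matrices | `make_toy_gene()`, `make_paperlike_fixture()`, `make_count_matrix()` |

The candidate score is an explicit weighted sum of min-max-normalized
metrics — mean window openness and net ESE density rewarded (weights 0.3 +
0.3), thermodynamics (binding stability rewarded; self/cross-dimer
stability and GC/Tm deviation penalized) at weight 0.4 — over all windows
of 18–30 nt passing hard filters. See the methods vignette
(`vignettes/aon-design-methods.Rmd`) for the model details and every
default.

## Worked example

An Igfbp1-like synthetic fixture: a 185-nt out-of-frame exon 2, the
published nested-PCR primers planted in the flanking exons, and the
published AON's 20-nt target window planted inside exon 2.

```r
library(aondesign)

fx <- make_paperlike_fixture("igfbp1", seed = 7)
fx$transcript
#> transcript igfbp1_like.t1 (igfbp1_like+), 3 exon(s), spliced length 545 nt
#>   exon lengths: 170, 185, 190
#>   CDS (spliced offsets): [9, 528)

rep <- simulate_exon_skip(fx$transcript, 2, fx$genome)
rep
#> exon-skip report: igfbp1_like.t1, exon 2
#>   skipped mRNA: 360 nt (wild type 545 nt)
#>   frameshift: TRUE (exon length mod 3 = 2)
#>   PTC at spliced offset 198; NMD predicted: FALSE
```

Exon 2 is out of frame (185 mod 3 = 2): the skip shifts the frame and a
PTC appears 28 nt past the junction. Nested RT-PCR on both templates
reproduces the diagnostic band pattern — wild-type and skipped inner
products differ by exactly the exon length:

```r
wt <- spliced_sequence(fx$transcript, fx$genome)
prods <- rbind(
  pcr_products(wt,       fx$primers$outer, fx$primers$inner, "wildtype"),
  pcr_products(rep$mrna, fx$primers$outer, fx$primers$inner, "skipped"))
virtual_gel(prods)
#> virtual gel (largest first)
#>     480 bp  wildtype     outer      outer_pair
#>     425 bp  wildtype     inner      inner_pair
#>     295 bp  skipped      outer      outer_pair
#>     240 bp  skipped      inner      inner_pair
```

The full design pipeline (fold → motif scan → enumerate → filter → rank)
on the same exon:

```r
des <- design_aons(fx$transcript, 2, fx$genome)
des
#> design report: 3406 candidate(s), 831 passing hard filters
#>   failures per criterion:
#>     gc_ok            2575
#>     tm_ok            53
#>     self_dimer_ok    0
#>     cross_dimer_ok   0
#>     openness_ok      0
#>     ese_ok           0
#>   top candidate: [113, 143) 30 nt  UUCUUGAGGUCGGGUGUGUGUGUGGUUUUG  (score 0.731)

to_2omeps(des$candidates$aon[1])
#> 5'-UUCUUGAGGUCGGGUGUGUGUGUGGUUUUG-3' (2OMePS)
```

The top-ranked 30-mer overlaps the planted target window: its 5' half
`UUCUUGAGGUCGG` is the 3' half of the published Igfbp1 oligo
(`CUUCCAUUUCUUGAGGUCGG`), recovered from sequence alone.

A command-line wrapper over the same functions ships in
`inst/cli/aondesign.R` (subcommands `skip-simulate`, `fold`, `scan-ese`,
`oligo-thermo`, `design`, `ispcr`, `make-fixture`).

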