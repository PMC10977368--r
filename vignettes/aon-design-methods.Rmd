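---
title: "Designing exon-skipping antisense oligonucleotides in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing exon-skipping antisense oligonucleotides in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aondesign)
```

## The knockdown strategy

Splice-switching antisense oligonucleotides (AONs) are short (18--30 nt)
single-stranded nucleic-acid analogues that hybridize to a pre-mRNA and
sterically block the splicing machinery from recognizing an exon. When the
blocked exon is *out of frame* -- its length is not a multiple of 3 -- its
exclusion from the mature mRNA shifts the downstream reading frame, usually
creating a premature termination codon (PTC). The result is a truncated,
nonfunctional protein and often degradation of the transcript by
nonsense-mediated decay (NMD): exon skipping becomes a gene *knockdown*
tool. The motivating application is knockdown of IGF-binding proteins
(mouse *Igfbp1* and *Igfbp3*, whose exon 2 is out of frame in both genes)
to raise free IGF-1 levels; the package, however, is written for any
multi-exon gene.

This package implements the complete in-silico arm of that strategy:

1. **Gene model** -- parse GFF3/GTF + FASTA, classify exon frames, and
   simulate the skip (`simulate_exon_skip()`): new mRNA, frameshift flag,
   PTC position, NMD call.
2. **Accessibility** -- fold the target exon with 50-nt intronic flanks
   and derive a per-base openness ("ss-count") profile
   (`ss_count_profile()`).
3. **Splice signals** -- scan for exonic splicing enhancers/silencers
   (`scan_motifs()`); AONs placed over ESE-rich windows block exon
   recognition most effectively.
4. **Hybridization thermodynamics** -- GC%, nearest-neighbor Tm, binding
   free energy, and self/cross-dimer screens (`tm_nearest_neighbor()`,
   `duplex_score()`).
5. **Candidate ranking** -- enumerate all windows, filter hard
   constraints, rank by a composite score (`design_aons()`).
6. **In-silico validation** -- nested RT-PCR product sizes on wild-type
   and skipped templates (`pcr_products()`), reference-gene-normalized
   qPCR ratios (`qpcr_relative()`), and the CPM pre-filter used ahead of
   differential-expression analysis (`cpm_filter()`).

A synthetic-data module (`make_toy_gene()`, `make_paperlike_fixture()`,
`make_count_matrix()`) generates fully specified fixtures so that every
stage is testable without downloads.

## Coordinate and translation conventions

All internal coordinates are 0-based half-open; GFF3/GTF input (1-based
inclusive) is converted at the parsing boundary. This removes off-by-one
ambiguity from splicing arithmetic: the length of any feature is always
`end - start`.

Only internal exons are skippable -- a terminal exon has just one splice
site, so there is nothing for a splice-switching oligo to redirect.
Translation after a skip restarts nowhere: it proceeds from the annotated
start codon of the wild-type CDS and scans codons for the first in-frame
stop at or past the skip junction. Without CDS annotation the longest open
reading frame is used and the report flags the fallback. Codons containing
`N` are treated as unknown and never count as stops. The NMD call uses the
standard 50-nt heuristic: a PTC at least 50 nt upstream of the final
exon-exon junction of the *skipped* transcript predicts decay. Note a
structural consequence: skipping the middle exon of a three-exon gene
always leaves the PTC downstream of the only remaining junction, so such
transcripts are predicted NMD-escaping; knockdown then relies on the
truncated protein rather than transcript degradation.

## The folding model and its scope

The packaged fold is a stacking-weighted Nussinov-style dynamic program:
nested structures over Watson-Crick plus G:U pairs, hairpin loops of at
least 3 nt, and a score that counts only *stacked* adjacent pairs (a stack
scores the sum of its two pair strengths: G:C 1.5, A:U 1.0, G:U 0.5).
Isolated pairs score nothing and the tie-breaks drop them, so predicted
helices are at least two stacks deep. This is deliberately not a
thermodynamic nearest-neighbor loop model: it is a transparent,
desk-checkable stand-in whose optimum is verified exactly against
exhaustive enumeration of all nested structures (sequences up to 12 nt in
the test suite). Any engine producing sets of nested pairs can be swapped
in behind `ss_count_profile()`.

The openness profile is computed over an ensemble: the optimal structure
plus up to `ensemble_size - 1` (default 10 total) suboptimal structures
obtained by *pair-exclusion re-folds* -- refolding once with each optimal
pair banned -- and retained when they score at least
`suboptimal_tolerance` (default 0.95) of the optimum. `openness[i]` is the
fraction of ensemble structures in which base `i` is unpaired; with
ensemble size 1 it degenerates to the unpaired indicator of the optimum.
The whole procedure is deterministic. The defaults mimic the breadth of a
typical suboptimal-folding ensemble while staying fast; both are explicit
knobs, not inferred from any reference tool.

## Motif library

The ESE/ESS library shipped under `inst/extdata/` is consensus-derived: a
GA-rich (GAAGAA-core) enhancer PWM and hexamer set of the kind bound by SR
proteins, and a UAG-core silencer PWM and hexamer set of the hnRNP
A1-recognized kind. PWMs are scored as summed per-position log-odds
against a per-motif threshold; hexamers match exactly, overlapping matches
included. The PWM's G positions penalize A (`-0.5`) so that A-rich
sequence cannot drift over the reporting threshold without its G anchors.
The library is a starter set, not a reconstruction of any web server's
proprietary matrices; the plain-text format (`>name kind threshold` plus
four A/C/G/U rows) makes it fully user-replaceable. Scanning is on the
sense strand only, since enhancers act on the pre-mRNA. Densities count
hit *starts* per nucleotide, which keeps the measure shift-equivariant and
independent of overlap conventions.

## Thermodynamics

Duplex stability uses the published RNA/RNA Watson-Crick nearest-neighbor
parameters of Xia et al. (1998), read from a provenance-tagged text file
and swappable wholesale. This is a first approximation for the 2'-O-methyl
phosphorothioate chemistry of splice-switching oligos (no
backbone-specific corrections are applied; the provenance tag keeps the
choice auditable). Conditions default to 1 µM total strand concentration
and 100 mM monovalent salt, with the entropic salt correction
`dS + 0.368 (n-1) ln[Na+]`; self-complementary duplexes receive the
symmetry correction and `x = 1` in `Tm = dH / (dS + R ln(C/x)) - 273.15`.

The dimer screen (`duplex_score()`) finds the best contiguous
Watson-Crick-complementary stretch over all ungapped antiparallel
alignments and sums stack free energies at 37 °C. Helix initiation is
deliberately excluded: the score is then a pure stability sum, exactly
reproducible by hand, strictly negative whenever a duplex of at least two
stacks exists, and exactly zero otherwise. The same scan yields the
AON:target binding energy (a perfect-complement window) and self/cross
dimerization scores.

## Candidate scoring

`design_config()` holds every tunable with its default:

| parameter | default | unit | rationale |
|---|---|---|---|
| length range | 18--30 | nt | conventional AON lengths; override requires an explicit flag |
| GC bounds | 0.40--0.60 | fraction | synthesis and specificity window |
| Tm bounds | 45--90 | °C | duplex stable at 37 °C without being intractable |
| max self/cross dimer | 8 | kcal/mol | stronger dimers compete with target binding |
| min mean openness | 0.5 | fraction | operationalizes "partly open" |
| min ESE density | 0 | hits/nt | ESE content is rewarded, not gated |
| weights | 0.3 / 0.3 / 0.4 | -- | openness / ESE / thermodynamics |

Hard filters remove candidates outside these bands (failures stay in the
report with flags). Passing candidates are ranked by a weighted sum of
min-max-normalized metrics: openness and net ESE density (ESE minus ESS)
are rewarded; binding stability is rewarded; self/cross-dimer stability
and deviation of GC and Tm from the centre of their allowed bands are
penalized, with the thermodynamic weight split evenly across its
sub-metrics. Two numerical choices matter:

* **Spread floors.** A metric whose range across the passing set is below
  a small floor (0.1 on fractions, 2 kcal/mol on free energies, 2 °C on
  Tm) is mapped to a neutral constant instead of being rescaled to
  [0, 1]. Without this, a metric that is effectively constant -- for
  example openness when every surviving window is essentially unpaired --
  would have its numerical noise amplified to full weight.
* **Tie-break.** Equal scores rank the 5'-most window start first, making
  the ranking deterministic and invariant to candidate input order.

The published selections this pipeline mirrors were qualitative ("partly
open and ESE-rich"); the weights and floors above are this package's
explicit operationalization, not values taken from any reference.

## In-silico RT-PCR

`pcr_products()` matches primers exactly (the printed assay primers are
exact designs); an optional mismatch allowance exists but the 3'-terminal
base must always match. Product length includes both primer footprints, so
predicted sizes compare directly to gel band sizes. Nested semantics
search the inner pair within each outer product. On the packaged
Igfbp1-like and Igfbp3-like fixtures the inner products are 425/240 bp and
422/195 bp on wild-type/skipped templates -- the size difference equals
the skipped exon length (185 and 227 nt) whenever both primers anneal
outside the skipped exon, which the tests assert as a property.

`qpcr_relative()` implements efficiency-corrected relative expression
`E_t^(-Cq_t)` over the geometric mean of the reference genes'
`E_r^(-Cq_r)`, with an optional calibrator sample. Amplification
efficiencies are inputs in (1, 2]; estimating them from raw fluorescence
is out of scope.

## CPM filtering

`cpm_filter()` computes `count / library size x 1e6` and keeps genes whose
mean CPM strictly exceeds the threshold (default 5) -- "above" is strict,
so a gene sitting exactly at the threshold is dropped. log2-CPM uses a 0.5
pseudo-count. Averaging is across all samples by default with a per-group
option, since either convention is defensible. Model fitting, PCA and
enrichment are deliberately out of scope: the module ends at the filtered
matrix that downstream differential-expression tools consume.

## What the synthetic fixtures do and do not emulate

`make_toy_gene()` builds a chromosome holding one gene to exact
specification, with a truth record listing every planted feature:

* exon lengths and frames (default 160/100/180 with an out-of-frame
  middle exon);
* an ESE-rich design window in the target exon: tandem copies of the
  planted hexamer joined by a short `CCA` spacer. The spacer keeps the
  window's GC fraction near 0.44 (inside the designable band) and is
  chosen so the antisense sequence of the window contains no
  self-complementary run -- its alphabet is G/C/U, and the reverse
  complement of any U-containing segment needs an A;
* one hairpin stem planted in each intronic flank (8-bp G/C arms, 4-nt
  loop) as the only genuine structure;
* primer landing sites in the flanking exons placed from an intended
  wild-type product size plus its upstream-exon portion -- the skipped
  product is then smaller by exactly the exon length, and contradictory
  placements (a primer that would have to sit inside the skipped exon)
  are refused with an explanation;
* a clean wild-type ORF (ATG, no premature in-frame stop, terminal TAA)
  and a guaranteed stop in the shifted frame downstream of the skip
  junction.

The background outside planted features is drawn from an A/C-only
alphabet (75/25). This is the load-bearing construction: with a fold that
scores only stacked pairs, an A/C background offers no two consecutive
base pairs anywhere outside the planted stems (G occurs only inside
planted features, and there is no U for A to pair with), so the design
window is open *by construction* and structure contrast comes only from
the stems. Planted primer sites, oligo sites and CDS anchors reintroduce
G/T locally where the assays need them. A bounded repair loop scrubs
stray in-frame stops and stray copies of the planted hexamer, never
touching planted (protected) bases; random primers are resampled until
their sites hold no stop triplet in the wild-type frame.

Consequently the fixtures are *not* realistic genomic sequence: real exons
have ~40--60% GC, diffuse structure, many weak ESE/ESS motifs, and no
hard guarantee that the best window is unique. Passing the
plant-and-recover suite shows the pipeline correctly integrates its
signals and recovers a window that is verifiably best under the model's
own assumptions -- it does not show that the model's assumptions hold for
real pre-mRNAs, where accessibility and motif predictions are far noisier.
The `igfbp1`/`igfbp3` "paper-like" fixtures similarly emulate only the
assay geometry -- the published primer sequences planted so the inner
nested products are 425/240 bp and 422/195 bp, and the published AONs'
target windows planted in exon 2 -- with no attempt to reproduce the real
genomic sequences. The per-gene CDS offsets (9 and 10) and oligo-site
offsets (80 and 81) are chosen so that stop triplets occurring inside the
planted, protected sites lie out of the wild-type frame.

`make_count_matrix()` draws two groups of 3 replicates from
gene-wise negative-binomial distributions (log-normal baseline means,
dispersion 0.1, 10% of genes shifted by a configurable log2 fold change,
default 1 -- matching the effect-size cutoff conventionally used
downstream). It emulates a small filtered RNA-seq comparison, not read
counting: no length bias, no library-composition effects.

## Problem sizes and runtime choices

The test suite folds regions of ~200 nt (100-nt exon plus 50-nt flanks)
with 10-structure ensembles, checks the folding optimum against exhaustive
enumeration on 1000 random sequences of up to 12 nt, screens ~2300
candidates per region, and runs the 20-fixture recovery study; the whole
suite completes in about a minute on one core. These sizes were chosen to
exercise every code path at full fidelity -- the dynamic programs are
exact at any length, so small oracle lengths lose no generality.

## Known limitations

* The fold ignores loop entropies and pseudoknots; openness is a rank
  signal, not a probability from a thermodynamic partition function.
* The nearest-neighbor table is unmodified RNA/RNA; 2'-O-methyl and
  phosphorothioate corrections are not applied.
* The motif library is a small consensus-derived starter set; users with
  access to a curated matrix collection should supply it.
* No transcriptome-wide off-target search and no synthesis-feasibility
  scoring; both are natural extensions behind the existing report format.
* Percent exon skipping on a gel is a densitometry measurement and is not
  predicted -- the assay engine predicts which bands can occur and their
  sizes, not their intensities.
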