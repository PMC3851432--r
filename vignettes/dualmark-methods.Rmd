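---
title: "Marker discovery between two cultivars: models, thresholds and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker discovery between two cultivars: models, thresholds and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dualmark re-implements, as a reusable and fully tested pipeline, the
classic two-cultivar marker-discovery workflow: resequence two cultivars
against a common reference, extract high-confidence SNPs, classify
cross-genotype InDel and SSR length polymorphisms, annotate everything
against gene models, summarize genome-wide patterns, and measure the
diversity a selected SNP panel captures across a germplasm collection.
This vignette explains the models and conventions the package commits to,
why each tunable has the default it has, and what the synthetic-data
module does and does not emulate.

## The discovery model

The pipeline consumes three kinds of evidence, all anchored to one
reference assembly:

* per-cultivar **variant call tables** (SNPs and 1–6 bp InDels) carrying
  depth, a phred-like quality, and per-allele read counts;
* per-cultivar **consensus sequences**, which are scanned for perfect
  microsatellites;
* **gene models** (GFF3) and an optional gene-to-GO mapping.

A marker is always a *difference between the two cultivars*: a SNP site
where the filtered alleles differ (an absent call means the reference
allele; two distinct non-reference alleles are kept but flagged
multiallelic rather than silently resolved), an InDel locus whose signed
motif lengths differ, or an SSR locus whose tract lengths differ. Mapping
and genotype-likelihood computation are out of scope — the pipeline starts
from call tables and applies the confidence rules below.

## Thresholds

All thresholds live in one place (`run_config()`), are echoed into the
run manifest and output headers, and default to:

| parameter | default | units | reading |
|---|---|---|---|
| SNP depth | > 8 | reads | strict: a depth of exactly 8 fails |
| SNP quality | > 30 | phred-like | strict |
| reads per allele | ≥ 4 | reads | inclusive, applied to every *observed* allele |
| panel depth | > 15 | reads | strict; capture genotyping is deeper than WGS |
| InDel size | 1–6 | bp | longer events are a different marker class |
| InDel polymorphism | Δ ≥ 1 | bp | signed lengths; identical events cancel |
| SSR polymorphism | Δ ≥ 2 | bp | a one-unit mononucleotide slip is not called |
| SSR minima | 12/12/12/16/20/24 | bp | per motif length 1–6 |
| class I boundary | ≥ 20 | bp | class II is 12–19 bp |
| SSR flank | 180 | bp | locus identity / primer context |
| InDel flank | up to 195 | bp | truncated at contig ends |
| window | 100 | kb | density track tiling |

The strict/inclusive boundary readings are deliberate and tested
(`depth = 8` rejected, `reads = 4` accepted), so the filter's edge
behavior is part of the package contract rather than an accident of
implementation.

## SSR mining conventions

The detector reports **maximal perfect tandem runs** of primitive (non-
periodic) 1–6 bp motifs, truncated to whole repeat units. Three
conventions need stating because mining tools genuinely differ:

* **Shortest period wins.** A poly-A tract is a mononucleotide locus,
  never a dinucleotide `AA` locus; a locus whose span lies inside a
  shorter-period locus's span is suppressed. Partial overlaps between
  different-period runs are legitimate and both loci are kept.
* **N breaks runs.** Consensus sequences contain no-call positions; no
  reported locus contains an N.
* **Perfect repeats only.** Compound and interrupted SSRs are not
  modelled; the class spectrum this package reproduces is defined over
  perfect tracts.

Equivalent motifs are pooled by the canonical representative: the
lexicographically smallest rotation of the motif or of its reverse
complement, rendered `AG/CT`-style. The whole detector is validated
against an independent brute-force enumerator (character-by-character
scanning with explicit divisor-based primitivity checks) on more than a
thousand random and adversarial sequences per test run.

## Cross-genome SSR matching

Upstream InDels shift coordinates between consensus sequences, so SSR
loci are **matched by flank anchoring**, not by position: each locus's
30 bp left flank is located in the reference (exact, unique match), and
two loci pair when chromosome, canonical motif and reference anchors
(± 10 bp) agree. Ambiguous many-to-many matches are dropped with a
warning — never mispaired. A locus detected in only one cultivar (the
other allele having eroded below its detection minimum) is compared to
the reference's own run length at the anchor; each such case is reported.

## Annotation

Feature labels follow the precedence CDS > UTR > intron > intergenic;
every position gets exactly one label, and the per-chromosome label
lengths partition the chromosome (tested). InDel and SSR markers take the
label of their reference anchor base; spans are not split. Coding effects
are computed on the spliced CDS of the annotated strand, so codons that
straddle splice junctions are handled, minus-strand alternates are
complemented, and genes whose CDS length is not a multiple of 3 are
flagged and refused rather than guessed at. The classifier is checked two
independent ways: whole-protein re-translation of mutated CDS, and a
reverse-complement-the-world invariance test. The translation of the
initial codon is literal (an ATG→TTG change is nonsynonymous), not
initiator-aware. GO "assignment" means ≥ 1 term in any of the three
top-level ontologies, and category tallies count term–gene pairs.

## Summaries and printed precision

Report tables round through one helper (`round_half_up()`): densities to
whole markers/Mb, percentages to one decimal, ratios to two decimals,
fold differences to one decimal. Half-way cases round away from zero —
base R's round-half-even would make printed tables platform-honest but
hand-arithmetic-unfriendly. The totals row of the per-chromosome table
divides summed counts by summed sizes rather than averaging the rounded
per-chromosome densities. The "0.1 Mb sliding window" track is
implemented as non-overlapping 100 kb tiles (step = width), matching how
such tracks are drawn; window counts must sum to chromosome totals
(tested), and the density flags translate the >1000/Mb and <500/Mb rules
to per-window counts.

## Diversity statistics

`PIC = 1 − Σpᵢ²` is used verbatim — this is the form under which the
biallelic maximum is exactly 0.50, attained at equal allele frequencies,
which is also what the acceptance script recomputes. Expected
heterozygosity uses Nei's unbiased small-sample correction
`He = (2n/(2n−1))(1 − Σpᵢ²)` with `n` the number of called individuals;
this is the standard population-genetics convention and is why observed
He can slightly exceed the 0.50 biallelic ceiling while PIC cannot.
Both are reported.

The similarity coefficient on the binary allele-presence matrix defaults
to **simple matching** (with Jaccard and Dice as options) with pairwise
deletion of masked cells: the choice of coefficient is genuinely open in
this workflow's tradition, and simple matching treats shared absence as
information, which is appropriate for co-dominant markers scored as
presence/absence per allele. A pair of samples with no comparable cells
is an error naming the pair, not a silent NA.

Neighbor joining is implemented in the package because the contract
demands properties library implementations do not promise: deterministic
lowest-index tie-breaking, clamping of negative branch lengths to zero
with the clamped deficit recorded on the tree, and exactness on additive
matrices to ≤ 1e-9 (branch lengths are serialized at full double
precision internally). `ape::nj()` serves as an independent cross-check
in the tests, and trees are ordinary `ape::phylo` objects, so the whole
ape/phangorn toolbox applies downstream. The dendrogram is unrooted; any
rooting for display is cosmetic.

## The synthetic-data module

The generator is the package's study system, not a fixture. Defaults
describe a desk-scale version of a two-cultivar resequencing experiment:
two 500 kb chromosomes, GC 0.38, one SNP per kilobase at a 2:1
transition:transversion target, one 1–6 bp InDel per 10 kb with lengths
weighted toward mononucleotides (51.4%, 21.8%, 9.9%, then a tapering
tail), 50 seeded SSR arrays with motif lengths weighted like an observed
polymorphic-SSR spectrum (43.7% mono, 40.1% di, 11.8% tri, …), of which
60% differ in repeat count between cultivars, and ~20-fold simulated
coverage (capture-style; the filter thresholds sit comfortably below it)
with clipped-Gaussian qualities around 40. One master seed drives every
stage through deterministic sub-seeds: identical configs give
byte-identical FASTA/GFF3/TSV outputs, which the manifest hashes verify.

Deliberate simplifications, and hence what passing tests do and do not
show about real data:

* **Planted events never overlap** and keep 40 bp clear of SSR arrays;
  real cultivar pairs have no such guarantee. Truth-based recovery can
  therefore be exact (100% precision and recall), which tests the
  classification logic, not the robustness to entangled variation.
* **No read-level simulation.** Depth is Poisson, quality clipped
  Gaussian, errors a 1% binomial — enough to straddle the filters, not a
  sequencing-error model. Mapping artifacts (the known mismatch-instead-
  of-gap InDel underestimation of short-read aligners) are outside the
  model.
* **Seeded SSRs are forced detectable** (at or above their class
  minimum, with repeat-breaking boundary bases), so detector recall on
  truth is exactly testable; proto-microsatellites below the minima are
  simply absent.
* **Gene models are clean**: two exons, one intron, both UTRs, CDS a
  multiple of 3 translating without internal stops, genes non-
  overlapping, SSR seeds intergenic. Overlapping genes exercise only the
  precedence rule, not biological ambiguity.
* The genotype panel draws Hardy–Weinberg genotypes within
  subpopulations from known frequency vectors; there is no linkage,
  inbreeding or admixture.

## Coordinates and other numerical choices

* All coordinates are **1-based inclusive** end to end — the native
  R/Bioconductor (IRanges/GFF3) convention. Keeping a single convention
  removes the off-by-one surface entirely; the trade-off (length =
  end − start + 1 arithmetic) is idiomatic in this ecosystem.
* SSR anchor matching tolerance is ± 10 bp after reference projection;
  flank anchors use 30 bp of left flank (collision probability of a
  specific 30-mer in a megabase-scale genome is negligible).
* Degenerate inputs are defined, not accidental: monomorphic loci return
  `Na = 1, Ho = He = PIC = 0`; a zero-transversion SNP set reports an
  undefined ratio as `NA`; empty marker sets produce zero-filled tables;
  unextractable flanks are flagged, not errors.
* Test problem sizes: the detector-oracle suite runs ~1,200 sequences of
  300 bp; planted-marker recovery uses the default 2 × 500 kb study
  (~1,000 SNPs, ~100 InDels, 50 SSRs); NJ exactness uses 20 random
  additive matrices of 5–12 taxa; panel recovery uses 24 samples × 599
  loci. These sizes were chosen so the whole suite exercises every
  contract in well under a minute of simulation time.

## Known limitations

Beyond the simulator simplifications above: compound/interrupted SSRs
and InDels longer than 6 bp are out of scope; multiallelic SNP sites are
flagged rather than decomposed; per-chromosome densities computed from
rounded (1-decimal) chromosome sizes can differ by a few markers/Mb from
densities computed on exact sizes, so only totals-row densities are
treated as exactly reproducible; and no bootstrap support, LD, or
population-structure inference is attempted on the dendrogram.
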