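---
title: "Verifying CRISPR/Cas9 knock-in clones from read depth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying CRISPR/Cas9 knock-in clones from read depth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(knockin)
```

This vignette is the package's account of its science: the cloning grammar
it simulates, the coverage statistic it implements, what the synthetic data
generator does and does not emulate, and the numerical and design choices
made where the problem left them open.

## The system being modelled

Markerless integration in *Komagataella phaffii* proceeds in two stages.
First, a donor helper plasmid is built by hierarchical Golden Gate
assembly: promoter, gene and terminator modules carry outward-facing type
IIS sites (BsaI `GGTCTC` N1, BpiI `GAAGAC` N2) whose staggered cuts expose
designer 4-nt overhangs — the *fusion sites* Fs1 `GGAG`, Fs2 `CATG`, Fs3
`GCTT`, Fs4 `CGCT` within one transcription unit, FsA `GATC`, FsB `CCGG`,
FsC `AATT` between units, and FsX `AGCT` for in-frame fusion of a
secretion leader. Because the recognition sites cut outside themselves,
ligation of matching overhangs consumes the sites and the reaction funnels
toward the single product whose cycle of fusion sites closes. The
assembled cassette sits between 500-bp homology regions matching the
sequence immediately upstream and downstream of an sgRNA-guided Cas9 cut.
The plasmid is opened with EcoRI and co-transformed; homology-directed
repair exchanges the cassette into the locus.

Second, the outcome is verified from whole-genome sequencing. Three
signatures matter:

1. **Copy number.** Reads are mapped, per-position depth is normalized by
   the genome-wide mean, and region means on the donor-plasmid reference
   are expressed relative to the mean normalized eGFP coverage of a
   verified single-copy clone for the same locus (the *calibrator*). A
   clone with *k* cassette copies shows ~*k* relative eGFP coverage;
   promoter and terminator, which are native (TDH3-derived), show *k + 1*.
2. **Junction architecture.** EcoRI linearization leaves AATT cohesive
   ends that the cell can re-ligate before or during integration,
   regenerating `GAATTC` at each fusion. Contigs spanning such junctions
   reveal whether fragments joined head-to-tail (tandem), head-to-head or
   tail-to-tail, and whether plasmid-backbone fragments (cat, ori) were
   co-integrated.
3. **Terminal loss.** A Cas9 break near a chromosome end can cost the cell
   everything distal to the repair point: a terminal run of zero coverage
   on the wild-type reference.

## Cohesive-end semantics

A digestion product is a linear molecule whose ends carry 4-nt labels: the
top-strand 4-mer spanning the staggered cut. Two ends ligate iff one is a
right end and the other a left end with the identical label. Fragment
strings own the junction 4-mer at their left end, so fragment lengths sum
to the parent length; the "filled" duplex form (label appended on the
right) is used where strand symmetry matters. Coordinates are 0-based,
half-open, top strand, everywhere. Circular molecules are scanned across
the origin via the doubled string and compared by lexicographically
minimal rotation.

Assembly is deterministic: the ligation graph (right label to equal left
label) must contain exactly one closed cycle through the vector backbone
that uses every insert payload once. Multiple cycles raise an
ambiguous-assembly error rather than sampling an outcome — the wet-lab
reaction is stochastic, the simulator is not.

## The synthetic study system

`make_toy_genome()` builds a four-chromosome genome whose default (`full`)
geometry matches the study system at the numbers that matter:

| quantity | default | why |
|---|---|---|
| chromosome lengths | 2.85, 2.40, 2.25, 1.65 Mb (9.15 Mb) | four-chromosome, ~9.2-Mb yeast genome; a 36.6-kb terminal loss is 1.5% of chr2 and exactly 0.4% of the genome |
| landing loci | PFK1-like and ROX1-like on chr2, 04576-like on chr4 | chromosome assignment of the real loci |
| ROX1-like cut | 36,600 nt from the chr2 distal end | the distance at which terminal loss was observed |
| homology arms | 500 nt | donor design |
| promoter / terminator | 493 / 202 nt, implanted once at a native chr3 locus | native TDH3 elements present once in the wild type; 493 > 300-nt reads (not spannable), 202 < 300 (spannable) |
| eGFP / cat / ori | 720 / 660 / 589 nt | typical ORF and backbone element sizes |
| distal chr2 annotation | ROX1 + 14 protein-coding genes + 2 rRNA genes | the feature content of the lost segment |
| reads | 2x300 bp pairs, insert 650, uniform starts | MiSeq-style paired-end sequencing |
| default depth | 50x | median genome depth of the sequenced panel (19-79x) |

Clone genomes are declarative: a `clone_structure()` lists the chain of
EcoRI fragments (cassette or backbone, `+`/`-`) ligated into the locus;
every junction regenerates `GAATTC`. The builder records ground truth
(copy counts per element, junction classes, lost features) and a
block-level projection from clone coordinates onto the mapping references
(wild-type chromosomes and the linearized donor-plasmid reference).
Cassette-borne homology-arm/promoter/terminator blocks project onto both
the plasmid reference and their genomic spans, and the native
promoter/terminator locus also projects onto the plasmid — reads from
identical sequence accumulate on every homologous reference region, which
is what makes the single-copy promoter read ~2x the eGFP coverage on the
plasmid reference.

Depth is computed from this projection without an aligner: `"reads"` mode
places read pairs uniformly and counts true-origin overlap; `"analytic"`
mode uses the exact expectation (constant depth with linear edge ramps of
read length minus one). FASTQ export exists for integration tests against
external mappers, but nothing in the package requires one.

What the generator deliberately does **not** emulate: GC or mappability
bias (on real data, uneven coverage typically inflates a single-copy
calibrator's relative eGFP value to 1.4-1.5x), indels and quality scores (substitution-only errors),
low-complexity slippage artifacts, and real assembly behaviour (contig
lengths are not modelled, only junction content). Passing tests therefore
demonstrate the correctness of the statistics on ideal uniform data, not
robustness to mapping bias; on real data the calibrator ratio absorbs a
locus-independent part of that bias, which is exactly why the statistic is
defined relative to a calibrator rather than in absolute normalized units.

## The copy-number statistic

Normalization divides every position by the mean depth over the genome
references only; plasmid references are excluded from the mean (they carry
concentrated cassette homology). Region means are computed on unsmoothed
normalized depth — the 35-nt centred moving average exists for track
export and plots only, because smoothing biases means of regions
comparable to the window. Copy calls are
`round(relative x calibrator_true_copies)` with round-half-away-from-zero
(a fixed tie rule; ties essentially never occur), minus the native
multiplicity for cassette-borne counts, floored at zero. Calls of eight or
more genome copies carry a low-confidence flag.

The calibrator is explicit user input, never inferred: in practice
calibrator clones are chosen by fluorescence phenotype, which the
pipeline cannot see. The
calibrator is one fixed measurement per locus — sequence it deeply (its
relative error multiplies every copy call linearly; at 600x truth-based
depth its eGFP mean has ~2% error, contributing ~0.3 copies of
uncertainty at k = 14).

Sampling noise of a region mean is dominated by read-placement
granularity: for a 720-nt region under 2x300-bp pairs the standard
deviation is roughly 0.15 copies per sqrt(copy) at 30x and shrinks with
the square root of depth. This is a property of depth statistics, not of
the implementation; it is why copy calls become progressively less precise
at high copy number, and why the recovery suite runs at a depth of 50x (the middle of the 19-79x range typical of such panels)
rather than the 30x floor.

## Terminal-loss detection

The detector takes the longest terminal run (either end) of positions with
normalized depth at or below `zero_eps = 0.02` and reports it when at
least `min_run = 1000` nt. The tolerance exists because sampled or
mismapped reads can dust a truly absent region; the run length makes a
1-kb gap the smallest reportable event, far above noise at any realistic
depth. Interior gaps are ignored — they are a different phenomenon.
Features entirely inside the lost span are reported as lost. In the
simulated deletion clone the integrated chain retains its final
downstream-homology copy, so the zero run begins at the arm's end and the
reported loss is 36,100 nt (1.50% of chr2, 0.39% of the genome) — the
detector reports what the data shows.

## Junction classification

Exact terminal k-mer anchoring (k = 40) replaces alignment: each catalog
fragment (cassette, backbone, in their filled duplex form) contributes
head and tail 40-mers on both strands; unique occurrence in a contig is
required (duplicates raise an ambiguity error), and adjacent anchored ends
within a small tolerance (the 4-nt cohesive overlap) yield one call.
"Head" is a fragment's 5' end on its catalog strand; tail-head meetings
(in either strand sense) are head-to-tail, head-head and tail-tail are the
two inversions. k = 40 is long enough that random 40-mers essentially
never collide in a 10-Mb genome and short enough to sit inside any real
contig. The loop-back property — scanning error-free junction windows of a
simulated clone recovers exactly the truth junction multiset — is the
module's acceptance bar; an adapter for external BLAST tabular output can
feed real contigs into the same call type.

Off-target scanning flags contigs that anchor one end in donor sequence
and the other in genomic sequence outside the target locus plus arms and
margin. Spannability (`read_len > region_len`, strict) annotates which
single-crossover events short reads can even in principle detect — 300-bp
reads cannot bridge the 493-bp promoter, but can bridge the 202-bp
terminator.

## Plate analytics

Endpoint screening calls a clone fluorescent when RFU strictly exceeds
600 (a negative-control threshold at gain 50; no blank subtraction — the
threshold is defined on raw readings). Normalized fluorescence (RFU/OD600)
includes only clones with OD600 strictly above 1.0. Transformation
efficiency divides colonies by the plated fraction (explicit input,
default 1, made explicit rather than guessed) and by
micrograms of donor DNA; integrations per microgram is its product with
the fluorescent fraction. Specific growth rate is the least-squares slope
of ln(OD600) over an explicit window (typical choices: 9-11 h, 11-13 h,
or onset-to-7.5 h post inoculation); window choice is the user's, with an optional
maximal-slope 2-h helper. The simulated fixtures are logistic curves, so
windows early in exponential phase (biomass well below capacity) recover
the generating rate within 0.01 /h under 1% multiplicative noise.

## Numerical and design choices

* **Cas9 cut offset**: blunt cut 3 nt 5' of the PAM (standard SpCas9),
  configurable — the source protocol does not state it. Integration
  replaces the inter-arm segment (double-crossover exchange); other
  architectures are expressed through `clone_structure()`.
* **Site scrubbing**: outside coding sequence, the third base of the
  occupied site is substituted with the smallest base that clears it
  (deterministic, one edit per site); in frame, codons overlapping the
  site are swapped to synonyms left to right. Unremovable sites raise an
  error rather than silently degrading.
* **Hairpin insulator**: sequence unspecified in the source system; a
  configurable 20-nt-stem/8-nt-loop inverted repeat placeholder is used
  and recorded as such.
* **Element termini**: generated elements are pinned to `CC` dinucleotide
  ends. Every recognition site handled here contains a G in any window
  spanning a CC|CC junction, so concatenating elements cannot create a new
  site — this makes donor validation deterministic across seeds.
* **Codon usage**: the bundled *K. phaffii*-style table is approximate
  (preferred codon per residue with geometrically decaying alternatives);
  it makes reverse translation deterministic and testable. Supply a real
  usage table for production designs.
* **Ambiguity is an error**: ambiguous assemblies, ambiguous junction
  anchors, and double normalization all stop with messages instead of
  guessing.

## Problem sizes used by the test and acceptance suites

The geometry of the statistics is local (arm lengths, region sizes, read
length, depth), so replicate-heavy suites run on scaled genomes: the
terminal-loss worked example runs at full 9.15-Mb scale; the copy-number
recovery sweep (k in {1, 2, 3, 5, 8, 14}, 20 replicates each, 50x target
depth, one 600x calibrator) runs at 1/3 scale, the smallest at which the
genome is still large against the cassette homology footprint (at 1/10
scale the k = 14 chain's homology copies inflate the whole-genome
normalization mean by ~2%, a real but study-scale-negligible effect);
structural-ratio and junction checks run at 1/10 scale. The demonstration
pipeline (`run_pipeline()`) verifies a nine-clone panel — three loci times
low/medium/strong architectures with copy numbers 1/2/3, 1/5/14 and
1/2(+terminal loss)/8, backbone inclusions in all three orientations —
and is deterministic per seed.

## Known limitations

* The depth model has no coverage bias; real calibrator ratios sit above 1
  (1.4-1.5x in the study) for reasons the simulator does not reproduce.
  The relative statistic is designed to cancel exactly this class of
  effect, but the cancellation is only as good as the bias's locus
  independence.
* Copy calls at k >= 8 are point estimates with ~0.5-copy noise even at
  50x; the low-confidence flag is a reminder, not a confidence interval.
* Junction detection requires junction-spanning contigs; single-crossover
  insertions into regions longer than the read length are structurally
  invisible, which `spannable()` makes explicit.
* BB2-level multi-unit assembly is supported by the grammar (FsA-FsC); the
  shipped constants stop at the two-unit case.
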