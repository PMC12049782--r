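# knockin

Design and whole-genome-sequencing verification of markerless CRISPR/Cas9
knock-ins in *Komagataella phaffii*.

## The problem

Markerless cassette integration in *K. phaffii* combines hierarchical
Golden Gate cloning with CRISPR/Cas9-stimulated homology-directed repair: a
donor helper plasmid carries the expression cassette between 500-bp
homology regions matching the sequence around the sgRNA-guided Cas9 cut,
is linearized with EcoRI, and is co-transformed with a Cas9/sgRNA plasmid.
The outcome at the locus is not guaranteed to be a single clean copy —
in vivo ligation of the EcoRI cohesive ends can stitch multiple donor
cassettes and even plasmid-backbone fragments into the target site, and
the double-strand break can occasionally cost the cell the distal end of
the chromosome. Verifying what actually integrated, from short-read WGS
alone, is the job of this package.

`knockin` provides, as tested R functions:

* **Construct design** — type IIS digestion (BsaI/BpiI), fusion-site
  ligation-graph assembly (Fs1 `GGAG`, Fs2 `CATG`, Fs3 `GCTT`, Fs4 `CGCT`,
  FsA/FsB/FsC, FsX `AGCT`), restriction-site scrubbing by synonymous point
  mutation, codon optimization, homology-arm extraction around a PAM-anchored
  cut site, and donor-helper plasmid assembly and validation.
* **A synthetic study system** — a toy 4-chromosome, 9.15-Mb genome with
  three landing loci (PFK1- and ROX1-like on chr2, 04576-like on chr4; the
  ROX1-like cut 36.6 kb from the chr2 end), clone genomes for any
  integration architecture (tandem head-to-tail, head-to-head/tail-to-tail
  inversions, backbone inclusions, terminal deletion), and uniform 2x300-bp
  paired reads with known truth, so every statistic is testable without an
  aligner or download.
* **Copy-number estimation from depth** — per-position normalization by the
  genome-wide mean, region means, coverage relative to a single-copy
  calibrator clone, and integer copy calls with native-multiplicity
  correction.
* **Junction classification** — head-to-tail / head-to-head / tail-to-tail
  calls at regenerated `GAATTC` sites by exact terminal k-mer anchoring of
  assembled contigs, plus backbone detection and off-target (chimeric
  junction) scanning.
* **Terminal-loss detection** — longest terminal run of (near-)zero
  normalized depth, with the annotation features lost.
* **Plate analytics** — fluorescent-clone calling (RFU > 600), RFU/OD600
  normalization (OD600 > 1), transformation efficiency (cfu per ug donor
  DNA), and specific growth rate from ln(OD600) regression.

## The statistic

For a clone with per-position read depth *d(x)*, the normalized depth is
*d(x) / mean(d over the genome references)* (plasmid references are
excluded from the mean). The mean normalized coverage of a region *R* on
the donor-plasmid reference is compared with the mean normalized eGFP
coverage *c* of the verified single-copy, low-fluorescence clone for the
same target locus:

```
relative_to_eGFP(R) = mean_norm_cov(R) / c
copies_genome(R)    = round(relative_to_eGFP(R))
copies_cassette(R)  = max(0, copies_genome(R) - native_multiplicity(R))
```

where `native_multiplicity` counts wild-type copies of the sequence (1 for
the TDH3-derived promoter/terminator and the homology arms, 0 for eGFP and
the backbone `cat`/`ori`). Calls of 8 or more genome copies carry a
low-confidence flag: the depth ratio's precision degrades with copy
number.

## Worked example

Verify a simulated tandem double integration at the PFK1-like locus:

```r
library(knockin)
g     <- make_toy_genome(toy_genome_config("mini"), seed = 1)
donor <- design_donor(g, "PFK1")    # arms + Golden Gate assembly + validation

## single-copy calibrator clone, sequenced deeply once
calib        <- apply_structure(g, donor, single_copy_structure("PFK1"))
calib_tracks <- normalize_tracks(
  exact_depth(calib, reads = simulate_reads(calib, depth = 600, seed = 11)),
  calib$genome_refs)
regions    <- donor_regions(donor$ref)
calib_egfp <- region_mean(calib_tracks$plasmid, regions$egfp)

## clone under verification
clone  <- apply_structure(g, donor, tandem_structure("PFK1", 2))
tracks <- normalize_tracks(
  exact_depth(clone, reads = simulate_reads(clone, depth = 300, seed = 12)),
  clone$genome_refs)
copy_number_report(tracks, regions, calib_egfp, clone_id = "PFK1_66-like")
scan_contigs(truth_contigs(clone), donor_catalog(donor$ref))
```

prints

```
Copy-number report for PFK1_66-like (calibrator eGFP mean 0.991)
        clone     region mean_normalized_coverage relative_to_egfp copies_genome copies_cassette
 PFK1_66-like   promoter                    3.036            3.063             3               2
 PFK1_66-like       egfp                    1.981            1.999             2               2
 PFK1_66-like terminator                    2.926            2.953             3               2
 PFK1_66-like        cat                    0.000            0.000             0               0
 PFK1_66-like        ori                    0.000            0.000             0               0
 PFK1_66-like        uHR                    2.085            2.104             2               1
 PFK1_66-like        dHR                    2.006            2.024             2               1

  left_fragment left_end right_fragment right_end        class junction_seq
1      cassette     tail       cassette      head head-to-tail       GAATTC
```

Read it as: two cassette-borne eGFP copies; promoter and terminator at
three genome copies each (two cassette + one native); two copies of each
homology region; no plasmid backbone; and one head-to-tail cassette fusion
at a regenerated EcoRI site — the signature of a tandem double insertion.
`run_pipeline(run_config())` runs the same verification over a nine-clone
panel (three loci x low/medium/strong architectures, including a
terminal-deletion clone) and writes TSV/JSON reports.

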