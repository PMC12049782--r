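## Shared fixtures, built once per test run and memoized. The mini preset
## keeps the local geometry of the study system (500-nt arms, ROX1-like
## locus 36.6 kb from the chr2 end) at 1/10 chromosome scale.

.fixtures <- new.env()

mini_genome <- function() {
  if (is.null(.fixtures$genome))
    .fixtures$genome <- make_toy_genome(toy_genome_config("mini"), seed = 42L)
  .fixtures$genome
}

midi_genome <- function() {
  if (is.null(.fixtures$midi))
    .fixtures$midi <- make_toy_genome(toy_genome_config("midi"), seed = 42L)
  .fixtures$midi
}

midi_donor <- function(locus = "PFK1") {
  key <- paste0("midi_donor_", locus)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- design_donor(midi_genome(), locus)
  .fixtures[[key]]
}

midi_regions <- function(locus = "PFK1") donor_regions(midi_donor(locus)$ref)

mini_donor <- function(locus = "PFK1") {
  key <- paste0("donor_", locus)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- design_donor(mini_genome(), locus)
  .fixtures[[key]]
}

mini_regions <- function(locus = "PFK1") donor_regions(mini_donor(locus)$ref)

## depth tracks for a clone at given depth, via truth-based read placement
clone_tracks <- function(clone, depth, seed, normalized = TRUE) {
  rs <- simulate_reads(clone, depth = depth, seed = seed)
  tr <- exact_depth(clone, reads = rs, mode = "reads")
  if (normalized) normalize_tracks(tr, clone$genome_refs) else tr
}

## small clone panel (single locus) for fast pipeline tests
default_panel_subset <- function() list(
  list(id = "PFK1_21", locus = "PFK1",
       segments = data.frame(kind = "cassette", orientation = "+"),
       distal_loss = FALSE),
  list(id = "PFK1_66", locus = "PFK1",
       segments = data.frame(kind = rep("cassette", 2),
                             orientation = rep("+", 2)),
       distal_loss = FALSE))

## eGFP relative coverage of a clone against a calibrator mean
egfp_relative <- function(clone, depth, seed, calibrator_mean, locus = "PFK1") {
  ntr <- clone_tracks(clone, depth, seed)
  region_mean(ntr$plasmid, mini_regions(locus)$egfp) / calibrator_mean
}
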