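test_that("scrub_sites removes sites with minimal deterministic edits", {
  out <- scrub_sites("AAGAATTCAA", "EcoRI")
  expect_equal(nrow(find_sites(out, "EcoRI")), 0L)
  ## exactly one substitution
  expect_equal(sum(strsplit(out, "")[[1]] != strsplit("AAGAATTCAA", "")[[1]]), 1)
  ## identity on clean input
  expect_identical(scrub_sites("AAATTTCCC", "EcoRI"), "AAATTTCCC")
})

test_that("coding scrub is synonymous", {
  ## GGT CTC = Gly-Leu carries a BsaI site across the codon boundary
  cds <- "GGTCTCAAA"  # Gly-Leu-Lys
  out <- scrub_sites(cds, "BsaI", frame = 0)
  expect_equal(nrow(find_sites(out, "BsaI")), 0L)
  expect_equal(translate_cds(out), translate_cds(cds))
  expect_error(scrub_sites("GGTCTCA", "BsaI", frame = 0), "multiple of 3")
})

test_that("Cas9 cut coordinates follow the blunt-cut offset on both strands", {
  gplus <- guide_target(strrep("A", 20), "TGG", "+", start = 100L)
  expect_equal(cut_site(gplus), 117L)   # blunt cut between 116 and 117
  gminus <- guide_target(strrep("A", 20), "TGG", "-", start = 100L)
  expect_equal(cut_site(gminus), 103L)  # mirror case
  expect_equal(cut_site(gplus, offset = 4L), 116L)
  expect_error(guide_target(strrep("A", 20), "TGA", "+", 0), "PAM")
  expect_error(guide_target(strrep("A", 19), "TGG", "+", 0), "20 nt")
})

test_that("homology arms are exact flanking slices around the cut", {
  chrom <- paste(rep(c("ACGTT"), 400), collapse = "")  # 2000 nt
  arms <- extract_homology_arms(chrom, 1000L, arm_len = 10L, scrub = NULL)
  expect_equal(arms$uHR, substr(chrom, 991, 1000))
  expect_equal(arms$dHR, substr(chrom, 1001, 1010))
  expect_error(extract_homology_arms(chrom, 300L, arm_len = 500L), "out of range")
  ## default arms are 500 nt and free of the forbidden sites
  g <- mini_genome()
  arms <- extract_homology_arms(g$chromosomes[["chr2"]], g$loci$PFK1$cut)
  expect_equal(nchar(arms$uHR), 500L)
  expect_equal(nchar(arms$dHR), 500L)
  for (e in c("BpiI", "BsaI", "EcoRI"))
    expect_equal(nrow(find_sites(arms$uHR, e)) + nrow(find_sites(arms$dHR, e)), 0L)
})

test_that("codon_optimize obeys usage and avoids forbidden sites", {
  toy <- c(ATG = 1, AAG = 0.6, AAA = 0.4)
  expect_equal(codon_optimize("MK", usage = toy, forbidden = character(0))$bases,
               "ATGAAG")
  ## naive argmax for E-F would be GAATTC (EcoRI) under this usage table
  usage <- c(GAA = 0.9, GAG = 0.1, TTC = 0.9, TTT = 0.1, ATG = 1)
  naive <- codon_optimize("MEF", usage = usage, forbidden = character(0))
  expect_equal(naive$bases, "ATGGAATTC")
  fixed <- codon_optimize("MEF", usage = usage, forbidden = "EcoRI")
  expect_equal(nrow(find_sites(fixed, "EcoRI")), 0L)
  expect_equal(translate_cds(fixed), "MEF")
  ## bundled usage table: translation round-trips, no forbidden sites
  prot <- "MSKGEELFTGVVPILVELDGDVNGHKFSVSGEGEGDATYGKLTLKFICTTGKLPVPWPTLVTTF"
  cds <- codon_optimize(prot)
  expect_equal(translate_cds(cds), prot)
  for (e in c("BpiI", "BsaI", "EcoRI", "XhoI", "BamHI", "NotI"))
    expect_equal(nrow(find_sites(cds, e)), 0L)
})

test_that("linearize opens a single-cutter plasmid with AATT ends", {
  plas <- nucleic_seq(paste0("CCAAACCC", "GAATTC", "CCTTTCC"),
                      topology = "circular")
  lin <- linearize(plas, "EcoRI")
  expect_equal(lin$topology, "linear")
  expect_equal(lin$left_end, "AATT")
  expect_equal(lin$right_end, "AATT")
  expect_error(linearize(nucleic_seq("CCAAACCC", topology = "circular"), "EcoRI"),
               "cannot linearize")
  two <- nucleic_seq(paste0("CCGAATTCCC", "AA", "CCGAATTCCC"),
                     topology = "circular")
  expect_warning(res <- linearize(two, "EcoRI"), "2")
  expect_true(isTRUE(attr(res, "multi_fragment")))
})

test_that("designed donors carry the expected architecture", {
  d <- mini_donor("PFK1")
  ## exactly two EcoRI sites; cassette fragment holds uHR..dHR in order
  expect_equal(nrow(find_sites(d$plasmid, "EcoRI")), 2L)
  reg <- d$ref$regions
  ord <- reg$name[order(reg$start)]
  expect_equal(ord[ord %in% c("uHR", "promoter", "egfp", "terminator", "dHR")],
               c("uHR", "promoter", "egfp", "terminator", "dHR"))
  expect_true(all(reg$start[reg$name %in% c("cat", "ori")] >= d$ref$cassette_end))
  ## no residual assembly-enzyme sites anywhere on the donor
  expect_equal(nrow(validate_part(d$plasmid)), 0L)
})
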