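## fixed payloads free of BpiI/BsaI sites
PROM <- "CCAAATTTACCACTTACTACCAATCATCACC"
CDS  <- "CCATGTTTAAACCTTGGTATCATTCTTAACC"
TERM <- "CCTTTATTATTCACCAATCAACAACTTCACC"

test_that("three-part Golden Gate assembly yields one clean circular product", {
  g <- mini_genome()
  vec <- crbb3_vector(strrep("CCAAT", 100), strrep("CCTAG", 100), g$elements)
  parts <- list(gg_part(PROM, "Fs1", "Fs2", role = "promoter"),
                gg_part(CDS, "Fs2", "Fs3", role = "cds"),
                gg_part(TERM, "Fs3", "Fs4", role = "terminator"))
  prod <- assemble_golden_gate(vec, parts, "BpiI")
  expect_equal(prod$topology, "circular")
  ## payload order promoter-cds-terminator between the fusion sites
  expect_true(grepl(paste0("GGAG", PROM, "CATG", CDS, "GCTT", TERM, "CGCT"),
                    paste0(prod$bases, prod$bases), fixed = TRUE))
  ## re-digestion with the assembly enzyme is a no-op
  expect_equal(nrow(find_sites(prod, "BpiI")), 0L)
  ## every insert payload appears exactly once
  expect_equal(knockin:::count_both_strands(prod$bases, CDS), 1)
})

test_that("missing fusion-site partners and internal sites are errors", {
  g <- mini_genome()
  vec <- crbb3_vector(strrep("CCAAT", 100), strrep("CCTAG", 100), g$elements)
  expect_error(
    assemble_golden_gate(vec, list(gg_part(CDS, "Fs2", "Fs3")), "BpiI"),
    "incompatible fusion sites")
  expect_error(gg_part(paste0("CCA", "GAAGAC", "ACC"), "Fs1", "Fs2"),
               "invalid part")
  dirty <- nucleic_seq(paste0("ATATA", CDS, "TATAT"))  # zero BpiI sites
  expect_error(assemble_golden_gate(vec, list(dirty), "BpiI"), "invalid part")
})

test_that("a secretion-leader part can be fused in frame at the FsX (AGCT) site", {
  g <- mini_genome()
  vec <- crbb3_vector(strrep("CCAAT", 100), strrep("CCTAG", 100), g$elements)
  leader <- "CCATGAGATTTCCTTCAATTTTTACC"    # alpha-MF-like leader payload
  ova <- "CCAAAGCACTTATTCTTAATCTTCACC"
  prod <- assemble_golden_gate(vec, list(
    gg_part(PROM, "Fs1", "Fs2", role = "promoter"),
    gg_part(leader, "Fs2", "FsX", role = "signal"),
    gg_part(ova, "FsX", "Fs3", role = "cds"),
    gg_part(TERM, "Fs3", "Fs4", role = "terminator")), "BpiI")
  ## the leader-gene junction reads AGCT
  expect_true(grepl(paste0(leader, "AGCT", ova),
                    paste0(prod$bases, prod$bases), fixed = TRUE))
})

test_that("fusion-site constants match the cloning grammar", {
  expect_equal(unname(fusion_sites()[c("Fs1", "Fs2", "Fs3", "Fs4")]),
               c("GGAG", "CATG", "GCTT", "CGCT"))
  expect_equal(unname(fusion_sites()[c("FsA", "FsB", "FsC", "FsX")]),
               c("GATC", "CCGG", "AATT", "AGCT"))
  expect_error(fusion_site("Fs9"), "unknown")
})

test_that("validate_part reports forbidden sites and the linearization rule", {
  v <- validate_part("CCGAAGACCC")
  expect_equal(v$enzyme, "BpiI")
  expect_equal(v$type, "assembly_site")
  expect_equal(nrow(validate_part("CCAATTTACCCAATCAAC")), 0L)
  ## all four linearization sites present -> rule violation
  allsites <- paste0("CCAA", "GAATTC", "AA", "CTCGAG", "AA", "GGATCC",
                     "AA", "GCGGCCGC", "AACC")
  v <- validate_part(allsites)
  expect_true("linearization_rule" %in% v$type)
})

test_that("ligating all digestion fragments of a plasmid reconstitutes it", {
  g <- mini_genome()
  vec <- crbb3_vector(strrep("CCAAT", 100), strrep("CCTAG", 100), g$elements)
  frags <- digest(vec, "EcoRI")
  expect_length(frags, 2)
  rejoined <- nucleic_seq(paste(vapply(frags, function(f) f$bases, character(1)),
                                collapse = ""), topology = "circular")
  expect_true(seq_identical(rejoined, nucleic_seq(vec$bases, topology = "circular")))
})
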