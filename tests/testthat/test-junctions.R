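test_that("fragment catalogs enforce unique terminal k-mers", {
  expect_error(fragment_catalog(c(a = strrep("ACGT", 20),
                                  b = strrep("ACGT", 30))),
               "ambiguous catalog")
  cat <- donor_catalog(mini_donor("PFK1")$ref)
  expect_equal(cat$k, 40L)
  expect_length(cat$anchors, 8L)
})

test_that("junction classification recovers every simulated orientation class", {
  g <- mini_genome()
  d <- mini_donor("PFK1")
  catalog <- donor_catalog(d$ref)
  structures <- list(
    tandem_structure("PFK1", 2),
    clone_structure("PFK1", data.frame(kind = c("cassette", "backbone"),
                                       orientation = c("+", "-"))),
    clone_structure("PFK1", data.frame(kind = c("cassette", "cassette"),
                                       orientation = c("-", "+"))),
    clone_structure("PFK1", data.frame(
      kind = c("cassette", "cassette", "backbone", "backbone", "cassette"),
      orientation = c("+", "+", "+", "-", "-"))))
  for (st in structures) {
    cl <- apply_structure(g, d, st)
    calls <- scan_contigs(truth_contigs(cl), catalog)
    truth <- cl$truth$junctions
    expect_equal(nrow(calls), nrow(truth))
    expect_equal(sort(calls$class), sort(truth$class))
    expect_true(all(calls$junction_seq == "GAATTC"))
    ## fragment identities line up junction by junction
    expect_equal(calls$left_fragment, truth$left_kind)
    expect_equal(calls$right_fragment, truth$right_kind)
  }
})

test_that("tandem head-to-tail junction reads dHR|GAATTC|uHR", {
  g <- mini_genome()
  d <- mini_donor("PFK1")
  cl <- apply_structure(g, d, tandem_structure("PFK1", 2))
  ctg <- truth_contigs(cl, flank = 150)
  calls <- scan_contigs(ctg, donor_catalog(d$ref))
  expect_equal(calls$class, "head-to-tail")
  expect_equal(calls$left_end, "tail")
  expect_equal(calls$right_end, "head")
  ## the contig covers the end of dHR, the regenerated EcoRI site, and the
  ## start of uHR
  reg <- d$ref$regions
  dHR <- substr(d$ref$ref, reg$start[reg$name == "dHR"] + 1,
                reg$end[reg$name == "dHR"])
  uHR <- substr(d$ref$ref, reg$start[reg$name == "uHR"] + 1,
                reg$end[reg$name == "uHR"])
  expect_true(grepl(paste0(substr(dHR, 401, 500), "GAATTC",
                           substr(uHR, 1, 100)), ctg[[1]], fixed = TRUE))
})

test_that("scanning reverse-complemented contigs yields mirrored calls", {
  g <- mini_genome()
  d <- mini_donor("PFK1")
  catalog <- donor_catalog(d$ref)
  cl <- apply_structure(g, d, clone_structure(
    "PFK1", data.frame(kind = c("cassette", "backbone"),
                       orientation = c("+", "-"))))
  fwd <- scan_contigs(truth_contigs(cl), catalog)
  rev <- scan_contigs(revcomp_chr(truth_contigs(cl)), catalog)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(fwd$class), sort(rev$class))
  expect_equal(fwd$left_fragment, rev$right_fragment)
  expect_equal(fwd$right_fragment, rev$left_fragment)
})

test_that("contigs inside one fragment produce no calls", {
  d <- mini_donor("PFK1")
  catalog <- donor_catalog(d$ref)
  inner <- substr(d$ref$ref, 200, 800)  # inside the cassette fragment
  expect_equal(nrow(scan_contigs(c(x = inner), catalog)), 0L)
})

test_that("backbone presence combines copy calls and junction evidence", {
  expect_false(detect_backbone()$present)
  rep0 <- data.frame(region = c("cat", "ori"), copies_cassette = c(0L, 0L))
  expect_false(detect_backbone(rep0)$present)
  rep1 <- data.frame(region = c("cat", "ori"), copies_cassette = c(2L, 2L))
  expect_true(detect_backbone(rep1)$present)
  jc <- data.frame(left_fragment = "backbone", right_fragment = "backbone",
                   class = "head-to-tail", contig = "c1")
  expect_true(detect_backbone(junction_calls = jc)$present)
})

test_that("off-target scan flags cassette-genome chimeras only", {
  g <- mini_genome()
  d <- mini_donor("PFK1")
  catalog <- donor_catalog(d$ref)
  ## clean single-copy clone junction contigs: nothing off target
  cl <- apply_structure(g, d, tandem_structure("PFK1", 2))
  expect_equal(nrow(off_target_scan(truth_contigs(cl), g, catalog,
                                    target_locus = "PFK1")), 0L)
  ## fixture: cassette end fused to a random chr3 locus
  chimera <- paste0(substr(d$ref$ref, d$ref$cassette_end - 200,
                           d$ref$cassette_end),
                    substr(g$chromosomes[["chr3"]], 50001, 50200))
  hits <- off_target_scan(c(chimera = chimera), g, catalog,
                          target_locus = "PFK1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$genomic_chrom, "chr3")
  ## pure genomic contig: no call
  pure <- substr(g$chromosomes[["chr1"]], 1001, 1600)
  expect_equal(nrow(off_target_scan(c(p = pure), g, catalog,
                                    target_locus = "PFK1")), 0L)
})

test_that("spannability is a strict read-length comparison", {
  expect_false(spannable(300, 493))   # reads cannot bridge the promoter
  expect_true(spannable(300, 202))    # but can bridge the terminator
  expect_false(spannable(300, 300))
  expect_error(spannable(0, 10))
})
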