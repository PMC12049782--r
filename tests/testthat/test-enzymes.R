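test_that("find_sites locates recognition sites on both strands", {
  expect_equal(find_sites("GGTCTCAAAAA", "BsaI"),
               data.frame(position = 0L, strand = "+"))
  expect_equal(nrow(find_sites("AAAAA", "BsaI")), 0L)
  ## reverse-strand site: revcomp of GGTCTC
  hits <- find_sites(paste0("TT", revcomp_chr("GGTCTC"), "TT"), "BsaI")
  expect_equal(hits$position, 2L)
  expect_equal(hits$strand, "-")
  ## site spanning the origin of a circular molecule
  hits <- find_sites(nucleic_seq("TCAAAAGGTC", topology = "circular"), "BsaI")
  expect_equal(hits$position, 6L)
})

test_that("find_sites agrees with a Biostrings brute-force oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(50:2000, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    for (ez in c("BsaI", "BpiI", "EcoRI")) {
      rec <- enzyme(ez)$recognition
      fwd <- Biostrings::start(Biostrings::matchPattern(rec, Biostrings::DNAString(s))) - 1L
      rev <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::reverseComplement(Biostrings::DNAString(rec)),
        Biostrings::DNAString(s))) - 1L
      hits <- find_sites(s, ez)
      expect_setequal(hits$position[hits$strand == "+"], fwd)
      if (revcomp_chr(rec) != rec)
        expect_setequal(hits$position[hits$strand == "-"], rev)
    }
  }
})

test_that("type IIS digestion labels junctions with the staggered-cut 4-mer", {
  ## GGTCTC N1 | GGAG ... : single circular cut opens to one linear fragment
  f <- digest(nucleic_seq("GGTCTCAGGAGTTTTTTTTC", topology = "circular"), "BsaI")
  expect_length(f, 1)
  expect_equal(f[[1]]$left_end, "GGAG")
  expect_equal(f[[1]]$right_end, "GGAG")
  expect_equal(length(f[[1]]), 20L)
})

test_that("palindromic digestion of a two-site circle yields two AATT fragments", {
  f <- digest(nucleic_seq("AAGAATTCTTAAGAATTCTT", topology = "circular"), "EcoRI")
  expect_length(f, 2)
  for (fr in f) {
    expect_equal(fr$left_end, "AATT")
    expect_equal(fr$right_end, "AATT")
  }
  expect_equal(sum(vapply(f, length, integer(1))), 20L)
})

test_that("digestion is conservative and strand-symmetric; no sites = identity", {
  s <- nucleic_seq("TTGGTCTCAGGAGAAACCCTTTGGGAAGAATTCAA")
  f <- digest(s, "BsaI")
  expect_equal(sum(vapply(f, length, integer(1))), length(s))
  ## digest(revcomp(s)) == revcomp of digest(s), reversed order; fragments
  ## compared as filled duplexes (the staggered-cut 4-mer appended to the
  ## right of every interior junction) since the flattened top strand
  ## assigns each overhang to the fragment on its right
  filled <- function(frags) vapply(seq_along(frags), function(i)
    if (i == length(frags)) frags[[i]]$bases
    else paste0(frags[[i]]$bases, frags[[i]]$right_end), character(1))
  fr <- digest(revcomp(s), "BsaI")
  expect_equal(length(fr), length(f))
  expect_equal(filled(fr), rev(revcomp_chr(filled(f))))
  ## identity on site-free molecules
  clean <- nucleic_seq("AAATTTCCCGGG")
  expect_identical(digest(clean, "BsaI")[[1]]$bases, clean$bases)
})

test_that("a type IIS cut falling outside a linear molecule is an error", {
  ## recognition at the very end: cut coordinate beyond the molecule
  expect_error(digest(nucleic_seq("AAAAGGTCTCA"), "BsaI"), "degenerate cut")
})
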