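test_that("toy genome generation is seed-deterministic with fixed geometry", {
  cfg <- toy_genome_config("mini")
  g1 <- make_toy_genome(cfg, seed = 5L)
  g2 <- make_toy_genome(cfg, seed = 5L)
  expect_identical(g1$chromosomes, g2$chromosomes)
  g3 <- make_toy_genome(cfg, seed = 6L)
  expect_false(identical(g1$chromosomes[["chr1"]], g3$chromosomes[["chr1"]]))
  expect_identical(g1$loci, g3$loci)  # geometry is config, not noise
  ## ROX1-like locus sits rox_distance from the chr2 distal end
  expect_equal(nchar(g1$chromosomes[["chr2"]]) - g1$loci$ROX1$cut, 36600L)
  ## distal annotation: >= 15 protein-coding + 2 rRNA beyond the cut
  a <- g1$annotation
  distal <- a[a$chrom == "chr2" & a$start >= g1$loci$ROX1$cut, ]
  expect_gte(sum(distal$type == "protein_coding"), 15L)
  expect_equal(sum(distal$type == "rRNA"), 2L)
  expect_true("ROX1" %in% distal$gene_id)
})

test_that("full preset realizes the study-scale geometry", {
  cfg <- toy_genome_config("full")
  expect_equal(unname(cfg$chrom_lengths["chr2"]), 2400000)
  expect_equal(sum(cfg$chrom_lengths), 9150000)
  expect_equal(cfg$chrom_lengths[["chr2"]] - cfg$loci$ROX1$cut, 36600)
})

test_that("native promoter/terminator are implanted once in the wild type", {
  g <- mini_genome()
  n_prom <- sum(vapply(g$chromosomes, knockin:::count_both_strands,
                       numeric(1), g$elements$promoter))
  n_term <- sum(vapply(g$chromosomes, knockin:::count_both_strands,
                       numeric(1), g$elements$terminator))
  expect_equal(n_prom, 1)
  expect_equal(n_term, 1)
})

test_that("applied structures match literal substring truth counts", {
  g <- mini_genome()
  d <- mini_donor("PFK1")
  for (segs in list("cassette",
                    rep("cassette", 2),
                    data.frame(kind = c("cassette", "backbone", "cassette"),
                               orientation = c("+", "-", "+")))) {
    st <- clone_structure("PFK1", segs)
    cl <- apply_structure(g, d, st)
    reg <- d$ref$regions
    getel <- function(nm) substr(d$ref$ref, reg$start[reg$name == nm] + 1L,
                                 reg$end[reg$name == nm])
    counts <- vapply(c("egfp", "uHR", "dHR", "cat", "ori"), function(nm)
      sum(vapply(cl$chromosomes, knockin:::count_both_strands, numeric(1),
                 getel(nm))), numeric(1))
    expect_equal(unname(counts["egfp"]), unname(cl$truth$counts["egfp"]))
    expect_equal(unname(counts["uHR"]), unname(cl$truth$counts["uHR"]))
    expect_equal(unname(counts["cat"]), unname(cl$truth$counts["cat"]))
    n_prom <- sum(vapply(cl$chromosomes, knockin:::count_both_strands,
                         numeric(1), g$elements$promoter))
    expect_equal(n_prom, unname(cl$truth$counts["promoter"]))
    ## clone equals wild type outside the modified locus
    expect_identical(cl$chromosomes[["chr1"]], g$chromosomes[["chr1"]])
    lc <- g$loci$PFK1
    expect_identical(substr(cl$chromosomes[["chr2"]], 1, lc$uHR_span[1]),
                     substr(g$chromosomes[["chr2"]], 1, lc$uHR_span[1]))
  }
})

test_that("single-copy integration regenerates no junction and keeps flanks", {
  g <- mini_genome()
  cl <- apply_structure(g, mini_donor("PFK1"), single_copy_structure("PFK1"))
  expect_null(cl$truth$junctions)
  expect_equal(truth_contigs(cl), character(0))
  ## locus now reads uHR + cassette + dHR between the genomic flanks
  lc <- g$loci$PFK1
  reg <- mini_donor("PFK1")$ref$regions
  uHR <- substr(mini_donor("PFK1")$ref$ref, reg$start[reg$name == "uHR"] + 1L,
                reg$end[reg$name == "uHR"])
  expect_equal(substr(cl$chromosomes[["chr2"]], lc$uHR_span[1] + 1L,
                      lc$uHR_span[1] + 500L), uHR)
})

test_that("terminal-deletion structures truncate the chromosome", {
  g <- mini_genome()
  cl <- apply_structure(g, mini_donor("ROX1"),
                        tandem_structure("ROX1", 2, distal_loss = TRUE))
  expect_equal(cl$truth$lost_span, c(g$loci$ROX1$dHR_span[2],
                                     nchar(g$chromosomes[["chr2"]])))
  expect_equal(length(cl$truth$lost_genes), 17L)
  expect_lt(nchar(cl$chromosomes[["chr2"]]), nchar(g$chromosomes[["chr2"]]))
})

test_that("simulated reads are exact substrings at zero error rate", {
  g <- mini_genome()
  cl <- apply_structure(g, mini_donor("PFK1"), single_copy_structure("PFK1"))
  rs <- simulate_reads(cl, depth = 0.5, seed = 7L, with_sequences = TRUE)
  idx <- sample.int(nrow(rs$pairs), 25)
  for (i in idx) {
    chrom <- cl$chromosomes[[rs$pairs$chrom[i]]]
    expect_identical(rs$mate1[i], substr(chrom, rs$pairs$start1[i] + 1L,
                                         rs$pairs$end1[i]))
    expect_identical(rs$mate2[i],
                     revcomp_chr(substr(chrom, rs$pairs$start2[i] + 1L,
                                        rs$pairs$end2[i])))
  }
  ## determinism
  rs2 <- simulate_reads(cl, depth = 0.5, seed = 7L, with_sequences = TRUE)
  expect_identical(rs, rs2)
  ## error rate injects substitutions but preserves length
  rse <- simulate_reads(cl, depth = 0.5, seed = 7L, error_rate = 0.01,
                        with_sequences = TRUE)
  expect_true(any(rse$mate1 != rs$mate1))
  expect_equal(unique(nchar(rse$mate1)), 300L)
})

test_that("mean read depth concentrates on the target", {
  g <- mini_genome()
  cl <- apply_structure(g, mini_donor("PFK1"), single_copy_structure("PFK1"))
  tr <- clone_tracks(cl, depth = 50, seed = 3L, normalized = FALSE)
  interior <- tr$chr1$depth[1000:(length(tr$chr1$depth) - 1000)]
  expect_lt(abs(mean(interior) - 50), 1)
})

test_that("analytic depth is the exact expected profile", {
  g <- mini_genome()
  cl <- apply_structure(g, mini_donor("PFK1"), single_copy_structure("PFK1"))
  tr <- exact_depth(cl, target = 40, read_len = 300, mode = "analytic")
  d <- tr$chr1$depth
  expect_equal(d[500], 40)                      # interior plateau
  expect_equal(d[1], 40 / 300)                  # edge ramp start
  expect_equal(d[150], 40 * 150 / 300)
  ## plasmid eGFP region sees exactly one cassette copy
  reg <- mini_regions("PFK1")
  expect_equal(mean(tr$plasmid$depth[(reg$egfp$start + 1):reg$egfp$end]), 40)
})

test_that("hand-placed reads give hand-countable depth", {
  g <- mini_genome()
  cl <- apply_structure(g, mini_donor("PFK1"), single_copy_structure("PFK1"))
  pairs <- data.frame(chrom = "chr1",
                      start1 = c(0L, 10L), end1 = c(5L, 15L),
                      start2 = c(20L, 30L), end2 = c(25L, 35L))
  rs <- structure(list(pairs = pairs, depth = NA, read_len = 5L,
                       insert_size = NA, error_rate = 0, seed = 0L),
                  class = "read_set")
  d <- exact_depth(cl, reads = rs, mode = "reads")$chr1$depth
  expect_equal(d[1:5], rep(1, 5))
  expect_equal(d[11:15], rep(1, 5))
  expect_equal(d[6:10], rep(0, 5))
  expect_equal(sum(d), 20)
})

test_that("clone genomes and reads round-trip through FASTA/FASTQ", {
  g <- mini_genome()
  cl <- apply_structure(g, mini_donor("PFK1"), single_copy_structure("PFK1"))
  dir <- withr::local_tempdir()
  write_clone(cl, dir)
  back <- read_fasta(file.path(dir, "clone_genome.fasta"))
  expect_identical(unname(back[["chr2"]]), cl$chromosomes[["chr2"]])
  rs <- simulate_reads(cl, depth = 0.2, seed = 1L, with_sequences = TRUE)
  paths <- write_fastq(rs, file.path(dir, "reads"))
  r1 <- readLines(paths[1])
  expect_equal(length(r1), 4L * nrow(rs$pairs))
  expect_identical(r1[2], rs$mate1[1])
})
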