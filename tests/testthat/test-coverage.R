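toy_tracks <- function() {
  list(chrA = depth_track("chrA", rep(40, 1000)),
       plasmid = depth_track("plasmid", rep(80, 200)))
}

test_that("normalization divides by the genome-only mean and guards state", {
  ntr <- normalize_tracks(toy_tracks(), "chrA")
  expect_equal(unique(ntr$chrA$depth), 1.0)
  expect_equal(unique(ntr$plasmid$depth), 2.0)  # plasmid excluded from mean
  expect_equal(ntr$chrA$genome_mean, 40)
  expect_lt(abs(mean(ntr$chrA$depth) - 1), 1e-9)
  expect_error(normalize_tracks(ntr, "chrA"), "already normalized")
  expect_error(normalize_tracks(list(z = depth_track("z", rep(0, 10))), "z"),
               "zero")
})

test_that("moving average is a truncated centred window", {
  tr <- depth_track("c", rep(3, 100))
  expect_equal(moving_average(tr, 35)$depth, rep(3, 100))
  ## unit impulse spreads to a 35-wide plateau of 1/35
  imp <- depth_track("c", c(rep(0, 60), 1, rep(0, 60)))
  sm <- moving_average(imp, 35)$depth
  expect_equal(sm[61], 1 / 35)
  expect_equal(sum(sm[44:78] > 0), 35)
  expect_equal(moving_average(imp, 1)$depth, imp$depth)
  expect_error(moving_average(imp, 34), "odd")
  ## truncated edge window: first position averages over h+1 points
  edge <- depth_track("c", c(1, rep(0, 99)))
  expect_equal(moving_average(edge, 35)$depth[1], 1 / 18)
})

test_that("region means and calibrator ratios are plain arithmetic", {
  tr <- normalize_tracks(toy_tracks(), "chrA")$chrA
  expect_equal(region_mean(tr, region("r", "chrA", 100, 200)), 1.0)
  half <- depth_track("c", c(rep(0, 50), rep(2, 50)), state = "normalized")
  expect_equal(region_mean(half, region("r", "c", 0, 100)), 1.0)
  expect_error(region_mean(toy_tracks()$chrA, region("r", "chrA", 0, 10)),
               "normalized")
  expect_error(region_mean(half, region("r", "c", 50, 200)), "outside")
  expect_equal(relative_to_calibrator(2.8, 1.4), 2.0)
  expect_equal(relative_to_calibrator(1.45, 1.45), 1.0)
  expect_equal(relative_to_calibrator(4.35, 1.45), 3.0)
  expect_error(relative_to_calibrator(1, 0), "positive")
})

test_that("copy calls subtract native multiplicity and flag high copies", {
  expect_equal(as.integer(call_copies(1.05, 0)), 1L)
  cc <- call_copies(3.0, 1)          # promoter: 3 genome copies, 2 cassette
  expect_equal(as.integer(cc), 2L)
  expect_equal(attr(cc, "copies_genome"), 3L)
  expect_equal(as.integer(call_copies(0.02, 0)), 0L)  # absent backbone
  expect_true(attr(call_copies(8.2, 0), "low_confidence"))
  expect_false(attr(call_copies(5.1, 0), "low_confidence"))
  ## round-half-away-from-zero is the fixed tie rule
  expect_equal(attr(call_copies(2.5, 0), "copies_genome"), 3L)
})

test_that("qc metrics aggregate depth and zero positions", {
  q <- qc_metrics(list(a = depth_track("a", rep(0, 7)),
                       b = depth_track("b", c(50, 50, 0, 50))))
  expect_equal(q$zero_depth_positions, c(7L, 1L))
  expect_equal(q$mean_depth[1], 0)
  expect_equal(q$mean_depth[2], 37.5)
  hand <- depth_track("h", c(0, 1, 2, 3, 0, 0, 4, 5, 6, 0))
  qh <- qc_metrics(list(h = hand))
  expect_equal(qh$positions, 10L)
  expect_equal(qh$mean_depth, 2.1)
  expect_equal(qh$zero_depth_positions, 4L)
})

test_that("depth TSV, BEDGRAPH and BED region files round-trip", {
  dir <- withr::local_tempdir()
  tracks <- list(chrA = depth_track("chrA", c(1, 2, 2, 0, 5)),
                 chrB = depth_track("chrB", c(3, 3)))
  p <- file.path(dir, "depth.tsv")
  write_depth_tsv(tracks, p)
  back <- read_depth_tsv(p)
  expect_equal(names(back), c("chrA", "chrB"))
  expect_equal(back$chrA$depth, tracks$chrA$depth)
  ## bedgraph merges equal-valued runs
  bg <- file.path(dir, "t.bedgraph")
  write_bedgraph(tracks$chrA, bg)
  df <- utils::read.table(bg)
  expect_equal(nrow(df), 4L)         # 1 | 2,2 | 0 | 5
  expect_equal(df$V2[2], 1L)
  expect_equal(df$V3[2], 3L)
  ## BED with native multiplicity in the name column
  regs <- list(region("promoter", "plasmid", 10, 110, 1),
               region("egfp", "plasmid", 120, 840, 0))
  bp <- file.path(dir, "regions.bed")
  write_regions_bed(regs, bp)
  back <- read_regions_bed(bp)
  expect_equal(back[[1]]$name, "promoter")
  expect_equal(back[[1]]$start, 10L)
  expect_equal(back[[1]]$end, 110L)
  expect_equal(back[[1]]$native_multiplicity, 1L)
  expect_equal(back[[2]]$native_multiplicity, 0L)
})

test_that("annotation survives a GFF3 round-trip", {
  g <- mini_genome()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ann.gff3")
  write_annotation_gff3(g, p)
  back <- read_annotation(p)
  expect_setequal(back$gene_id, g$annotation$gene_id)
  m <- match(g$annotation$gene_id, back$gene_id)
  expect_equal(back$start[m], g$annotation$start)
  expect_equal(back$end[m], g$annotation$end)
})
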