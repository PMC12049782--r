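#' Per-position depth track
#'
#' Depth of coverage over one named reference sequence, with an explicit
#' normalization state: raw tracks hold counts, normalized tracks hold
#' depth divided by the clone's mean depth over the genome references.
#'
#' @param reference reference name.
#' @param depth numeric vector of per-position depth (position 1 = first
#'   base).
#' @param state `"raw"` or `"normalized"`.
#' @param genome_mean the genome-wide mean depth used for normalization
#'   (set by [normalize_tracks()]).
#' @return object of class `depth_track`.
#' @export
depth_track <- function(reference, depth, state = "raw", genome_mean = NA_real_) {
  if (any(depth < 0)) stop("depth must be non-negative")
  structure(list(reference = reference, depth = as.numeric(depth),
                 state = state, genome_mean = genome_mean),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track %s: %d positions, %s, mean %.3f>\n",
              x$reference, length(x$depth), x$state, mean(x$depth)))
  invisible(x)
}

#' Normalize a clone's depth tracks
#'
#' Divides every position of every track by the mean depth over the
#' *genome* references only — plasmid or other episomal references do not
#' enter the mean. After normalization the depth averaged over the genome
#' references equals 1.
#'
#' @param tracks named list of raw [depth_track()]s (one clone).
#' @param genome_refs names of the references that constitute the genome.
#' @return named list of normalized tracks.
#' @export
normalize_tracks <- function(tracks, genome_refs) {
  if (any(vapply(tracks, function(t) t$state, character(1)) == "normalized"))
    stop("tracks are already normalized")
  gr <- intersect(genome_refs, names(tracks))
  if (length(gr) == 0) stop("no genome references among the tracks")
  tot <- sum(vapply(tracks[gr], function(t) sum(t$depth), numeric(1)))
  n <- sum(vapply(tracks[gr], function(t) length(t$depth), numeric(1)))
  gm <- tot / n
  if (gm <= 0) stop("empty input: genome mean depth is zero")
  lapply(tracks, function(t)
    depth_track(t$reference, t$depth / gm, state = "normalized",
                genome_mean = gm))
}

#' Centred moving average of a track
#'
#' Presentation-only smoothing (default 35-nt window) used for track
#' export and plots; region means are always computed on unsmoothed depth.
#' Windows are truncated at the sequence ends.
#'
#' @param track a [depth_track()].
#' @param window odd window size, default 35.
#' @return a smoothed `depth_track`.
#' @export
moving_average <- function(track, window = 35L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1")
  x <- track$depth
  n <- length(x)
  h <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out <- track
  out$depth <- sm
  out
}

#' Genomic region with native multiplicity
#'
#' @param name region name (e.g. `"egfp"`).
#' @param reference reference the span lives on.
#' @param start,end 0-based half-open span.
#' @param native_multiplicity copies of this sequence present in the
#'   wild-type genome (eGFP/cat/ori: 0; promoter/terminator/uHR/dHR: 1).
#' @return object of class `region`.
#' @export
region <- function(name, reference, start, end, native_multiplicity = 0L) {
  stopifnot(end > start, start >= 0)
  structure(list(name = name, reference = reference, start = as.integer(start),
                 end = as.integer(end),
                 native_multiplicity = as.integer(native_multiplicity)),
            class = "region")
}

#' Mean normalized coverage over a region
#'
#' @param track a normalized [depth_track()].
#' @param reg a [region()] on that track's reference.
#' @return arithmetic mean of the normalized depth over the span.
#' @export
region_mean <- function(track, reg) {
  if (track$state != "normalized") stop("region_mean requires a normalized track")
  if (reg$reference != track$reference)
    stop("region reference does not match the track")
  if (reg$end > length(track$depth)) stop("region span outside the reference")
  mean(track$depth[(reg$start + 1L):reg$end])
}

#' Coverage relative to the single-copy calibrator
#'
#' Divides a mean normalized coverage by the mean normalized eGFP coverage
#' of the verified single-copy (low-fluorescence) clone for the same
#' target locus, so the calibrator's eGFP value is 1 by construction.
#'
#' @param value mean normalized coverage of the region of interest.
#' @param calibrator_egfp_mean the calibrator clone's eGFP mean normalized
#'   coverage.
#' @return the ratio.
#' @export
relative_to_calibrator <- function(value, calibrator_egfp_mean) {
  if (calibrator_egfp_mean <= 0) stop("calibrator mean must be positive")
  value / calibrator_egfp_mean
}

## round half away from zero (deterministic integer calls)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Integer copy call from relative coverage
#'
#' Genome-wide copies are `round(relative x calibrator_true_copies)`
#' (half away from zero); cassette-borne copies subtract the native
#' multiplicity, floored at zero. Calls of 8 or more genome-wide copies
#' carry a low-confidence flag, reflecting the decreasing precision of
#' depth ratios at high copy number.
#'
#' @param relative coverage relative to the calibrator (>= 0).
#' @param native_multiplicity wild-type copies of the region.
#' @param calibrator_true_copies cassette copies in the calibrator clone,
#'   default 1.
#' @return integer cassette-borne copy call with attributes
#'   `copies_genome` and `low_confidence`.
#' @export
call_copies <- function(relative, native_multiplicity = 0L,
                        calibrator_true_copies = 1L) {
  if (relative < 0) stop("relative coverage must be >= 0")
  genome_copies <- as.integer(round_half_away(relative * calibrator_true_copies))
  cassette <- max(0L, genome_copies - as.integer(native_multiplicity))
  structure(cassette, copies_genome = genome_copies,
            low_confidence = genome_copies >= 8L)
}

#' Per-clone copy-number report
#'
#' Computes, for each region, the mean normalized coverage, the coverage
#' relative to the calibrator's eGFP mean, and integer copy calls.
#'
#' @param tracks named list of normalized tracks for the clone.
#' @param regions list of [region()]s.
#' @param calibrator_egfp_mean calibrator eGFP mean normalized coverage
#'   (use the clone's own eGFP mean for the calibrator itself).
#' @param clone_id clone label.
#' @param calibrator_true_copies see [call_copies()].
#' @return data.frame of class `copy_number_report`.
#' @export
copy_number_report <- function(tracks, regions, calibrator_egfp_mean,
                               clone_id = "clone",
                               calibrator_true_copies = 1L) {
  rows <- lapply(regions, function(rg) {
    m <- region_mean(tracks[[rg$reference]], rg)
    rel <- relative_to_calibrator(m, calibrator_egfp_mean)
    cc <- call_copies(rel, rg$native_multiplicity, calibrator_true_copies)
    data.frame(clone = clone_id, region = rg$name,
               mean_normalized_coverage = m, relative_to_egfp = rel,
               copies_genome = attr(cc, "copies_genome"),
               copies_cassette = as.integer(cc),
               low_confidence = attr(cc, "low_confidence"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("copy_number_report", "data.frame")
  attr(out, "calibrator_egfp_mean") <- calibrator_egfp_mean
  out
}

#' @export
print.copy_number_report <- function(x, digits = 3, ...) {
  cat(sprintf("Copy-number report for %s (calibrator eGFP mean %.3f)\n",
              x$clone[1], attr(x, "calibrator_egfp_mean")))
  df <- as.data.frame(x)
  df$mean_normalized_coverage <- round(df$mean_normalized_coverage, digits)
  df$relative_to_egfp <- round(df$relative_to_egfp, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Sequencing / mapping QC metrics
#'
#' Per-reference mean raw depth and count of zero-depth positions, plus
#' optional mapped-read percentages.
#'
#' @param tracks named list of raw tracks.
#' @param mapped_pct optional named numeric (percent mapped per reference
#'   group).
#' @return data.frame with one row per reference.
#' @export
qc_metrics <- function(tracks, mapped_pct = NULL) {
  out <- do.call(rbind, lapply(tracks, function(t) data.frame(
    reference = t$reference, positions = length(t$depth),
    mean_depth = mean(t$depth), zero_depth_positions = sum(t$depth == 0),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (!is.null(mapped_pct))
    out$mapped_pct <- mapped_pct[out$reference]
  out
}
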