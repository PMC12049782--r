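## Format adapters for depth tracks and region files. The depth dialect is
## the 3-column TSV of `samtools depth -a`: reference, 1-based position,
## depth, with every position present including zeros.

#' Read / write per-position depth TSV
#'
#' @param path depth TSV (reference, 1-based position, depth; no header).
#' @param tracks named list of [depth_track()]s.
#' @return `read_depth_tsv` returns a named list of raw `depth_track`s.
#' @export
read_depth_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("reference", "pos", "depth"),
                          colClasses = c("character", "integer", "numeric"))
  out <- lapply(split(df, df$reference), function(d) {
    d <- d[order(d$pos), ]
    if (!identical(d$pos, seq_len(nrow(d))))
      stop("depth TSV must list every 1-based position (samtools depth -a dialect)")
    depth_track(d$reference[1], d$depth)
  })
  out[unique(df$reference)]
}

#' @rdname read_depth_tsv
#' @export
write_depth_tsv <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in tracks) {
    utils::write.table(
      data.frame(t$reference, seq_along(t$depth), t$depth),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Export a (smoothed) track as BEDGRAPH
#'
#' Adjacent positions with equal value are merged into one interval.
#'
#' @param track a [depth_track()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  d <- track$depth
  chg <- c(TRUE, d[-1] != d[-length(d)])
  starts <- which(chg) - 1L                 # 0-based
  ends <- c(starts[-1], length(d))
  utils::write.table(
    data.frame(track$reference, starts, ends, signif(d[chg], 6)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read regions from BED
#'
#' BED is 0-based half-open; the 4th (name) column may carry
#' `name:native_multiplicity` (e.g. `promoter:1`), otherwise multiplicity
#' defaults to 0.
#'
#' @param path BED file.
#' @return list of [region()]s.
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lapply(seq_along(gr), function(i) {
    nm <- gr$name[i]
    if (is.null(nm) || is.na(nm)) nm <- sprintf("region%03d", i)
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    mult <- if (length(parts) > 1) as.integer(parts[2]) else 0L
    region(parts[1], as.character(GenomicRanges::seqnames(gr)[i]),
           GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i],
           native_multiplicity = mult)
  })
}

#' @rdname read_regions_bed
#' @param regions list of [region()]s.
#' @export
write_regions_bed <- function(regions, path) {
  df <- do.call(rbind, lapply(regions, function(r) data.frame(
    chrom = r$reference, start = r$start, end = r$end,
    name = paste0(r$name, ":", r$native_multiplicity),
    stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Regions of a donor reference as a named list
#'
#' Converts the element table of a [donor_reference()] into [region()]
#' objects on the `"plasmid"` reference, ready for
#' [copy_number_report()].
#'
#' @param donor_ref a `donor_reference` (e.g. `design_donor(...)$ref`).
#' @return named list of [region()]s.
#' @export
donor_regions <- function(donor_ref) {
  out <- lapply(seq_len(nrow(donor_ref$regions)), function(i) {
    r <- donor_ref$regions[i, ]
    region(r$name, "plasmid", r$start, r$end, r$native_multiplicity)
  })
  names(out) <- donor_ref$regions$name
  out
}
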