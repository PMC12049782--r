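#' Write a molecule as a GenBank flat file
#'
#' Minimal GenBank export for construct provenance: LOCUS, FEATURES (one
#' `misc_feature` per annotated element) and ORIGIN. Feature spans are
#' taken from `features` or, when absent, from the molecule's `features`
#' attribute (set by [crbb3_vector()]); a [donor_reference()] can be
#' written by passing its `regions` table. No installed package writes
#' GenBank, so this exporter is implemented here.
#'
#' @param seq a [nucleic_seq()].
#' @param path output file.
#' @param features optional data.frame with `name`, `start`, `end`
#'   (0-based half-open).
#' @return the path, invisibly.
#' @export
write_genbank <- function(seq, path, features = NULL) {
  seq <- as_nucleic_seq(seq)
  if (is.null(features)) features <- attr(seq, "features")
  n <- nchar(seq$bases)
  lines <- c(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN %s",
                     substr(seq$id, 1, 16), n,
                     if (seq$topology == "circular") "circular" else "linear",
                     format(Sys.Date(), "%d-%b-%Y")),
             sprintf("DEFINITION  %s.", seq$id),
             "FEATURES             Location/Qualifiers")
  if (!is.null(features) && nrow(features)) {
    for (i in seq_len(nrow(features)))
      lines <- c(lines,
                 sprintf("     misc_feature    %d..%d",
                         features$start[i] + 1L, features$end[i]),
                 sprintf("                     /label=\"%s\"", features$name[i]))
  }
  lines <- c(lines, "ORIGIN")
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(seq$bases, off, min(off + 59L, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(tolower(tens), collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' Parses LOCUS topology, `misc_feature` spans and the ORIGIN sequence.
#'
#' @param path GenBank file.
#' @return a [nucleic_seq()] with a `features` attribute.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  id <- locus[2]
  topo <- if (any(grepl("circular", lines[1]))) "circular" else "linear"
  feat_i <- grep("^\\s+misc_feature\\s+", lines)
  features <- NULL
  if (length(feat_i)) {
    spans <- regmatches(lines[feat_i],
                        regexec("(\\d+)\\.\\.(\\d+)", lines[feat_i]))
    labs <- sub(".*?/label=\"([^\"]+)\".*", "\\1", lines[feat_i + 1L])
    features <- data.frame(
      name = labs,
      start = vapply(spans, function(m) as.integer(m[2]), integer(1)) - 1L,
      end = vapply(spans, function(m) as.integer(m[3]), integer(1)),
      stringsAsFactors = FALSE)
  }
  o <- grep("^ORIGIN", lines)
  seq_lines <- lines[(o + 1L):(length(lines) - 1L)]
  bases <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
  out <- nucleic_seq(bases, id = id, topology = topo)
  attr(out, "features") <- features
  out
}
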