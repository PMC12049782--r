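#' Fragment catalog for junction scanning
#'
#' Named reference fragments (cassette, backbone, genomic flanks) indexed
#' by their terminal k-mers. "head" is a fragment's 5' end on its catalog
#' strand, "tail" its 3' end. Terminal k-mers (and their reverse
#' complements) must be unique within the catalog.
#'
#' @param fragments named character vector of fragment sequences.
#' @param k anchor k-mer length, default 40.
#' @return object of class `fragment_catalog`.
#' @export
fragment_catalog <- function(fragments, k = 40L) {
  k <- as.integer(k)
  stopifnot(length(fragments) >= 1, !is.null(names(fragments)))
  if (any(nchar(fragments) < k))
    stop("all fragments must be at least k nt long")
  anchors <- list()
  for (nm in names(fragments)) {
    s <- fragments[[nm]]
    head_k <- substr(s, 1L, k)
    tail_k <- substr(s, nchar(s) - k + 1L, nchar(s))
    anchors[[paste0(nm, ".head.+")]] <- head_k
    anchors[[paste0(nm, ".tail.+")]] <- tail_k
    anchors[[paste0(nm, ".head.-")]] <- revcomp_chr(head_k)
    anchors[[paste0(nm, ".tail.-")]] <- revcomp_chr(tail_k)
  }
  kmers <- unlist(anchors)
  if (anyDuplicated(kmers))
    stop("ambiguous catalog: terminal k-mers are not unique (",
         paste(unique(kmers[duplicated(kmers)]), collapse = ", "), ")")
  structure(list(fragments = fragments, k = k, anchors = anchors),
            class = "fragment_catalog")
}

## all anchor matches of the catalog inside one contig, as a data.frame:
## fragment, end (head/tail), orient (+/-), start/stop of the k-mer match
anchor_matches <- function(contig, catalog) {
  rows <- list()
  for (key in names(catalog$anchors)) {
    p <- str_find_all(contig, catalog$anchors[[key]])
    if (length(p) > 1)
      stop("ambiguous anchor: k-mer of ", key, " occurs ", length(p),
           " times in the contig")
    if (length(p) == 1) {
      info <- strsplit(key, ".", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        fragment = info[1], end = info[2], orient = info[3],
        start = p, stop = p + catalog$k, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Scan contigs for fragment-fusion junctions
#'
#' Anchors each catalog fragment's terminal k-mers (both strands) in each
#' contig and emits one junction call per adjacent pair of anchored
#' fragment ends. Along a contig, a plus-orientation fragment runs
#' head-to-tail; a minus-orientation fragment presents its ends reverse
#' complemented. The junction class follows from which ends meet:
#' tail-head (either strand sense) is head-to-tail, head-head and
#' tail-tail are the two inverted classes.
#'
#' @param contigs named character vector of contig sequences (or a FASTA
#'   path).
#' @param catalog a [fragment_catalog()].
#' @return data.frame of junction calls: left/right fragment, end and
#'   orientation, `class`, `junction_seq` (the 6-mer spanning the fusion,
#'   e.g. a regenerated GAATTC), `contig` and `offset`.
#' @export
scan_contigs <- function(contigs, catalog) {
  if (length(contigs) == 1 && file.exists(contigs)) contigs <- read_fasta(contigs)
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("contig%03d", seq_along(contigs))
  calls <- list()
  for (cn in names(contigs)) {
    contig <- contigs[[cn]]
    if (nchar(contig) < 2L * catalog$k) next
    m <- anchor_matches(contig, catalog)
    if (is.null(m) || nrow(m) < 2) next
    ## the contig-facing side of each anchored fragment: an incoming
    ## fragment ends with its tail (+) / head (-); an outgoing one starts
    ## with its head (+) / tail (-)
    for (i in seq_len(nrow(m) - 1L)) {
      a <- m[i, ]; b <- m[i + 1L, ]
      if (a$fragment == b$fragment && a$orient == b$orient &&
          a$end != b$end) {
        ## two ends of the same fragment occurrence, not a fusion
        inner <- if (a$orient == "+") a$end == "head" else a$end == "tail"
        if (inner) next
      }
      gap <- b$start - a$stop
      if (gap < -6L || gap > 2L) next   # anchors must abut (4-nt overlap typical)
      left_is_end <- (a$orient == "+" && a$end == "tail") ||
                     (a$orient == "-" && a$end == "head")
      right_is_start <- (b$orient == "+" && b$end == "head") ||
                        (b$orient == "-" && b$end == "tail")
      if (!left_is_end || !right_is_start) next
      meet_left <- a$end            # end of fragment A at the junction
      meet_right <- if (b$orient == "+") "head" else "tail"
      cls <- if (meet_left == "tail" && meet_right == "head") "head-to-tail"
        else if (meet_left == "head" && meet_right == "tail") "head-to-tail"
        else if (meet_left == "tail") "tail-to-tail" else "head-to-head"
      jseq <- substr(contig, max(1L, a$stop - 4L), min(nchar(contig), a$stop + 1L))
      calls[[length(calls) + 1L]] <- data.frame(
        left_fragment = a$fragment, left_end = a$end,
        left_orientation = a$orient,
        right_fragment = b$fragment, right_end = meet_right,
        right_orientation = b$orient,
        class = cls, junction_seq = jseq, contig = cn,
        offset = a$stop, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(left_fragment = character(0), left_end = character(0),
                      left_orientation = character(0),
                      right_fragment = character(0), right_end = character(0),
                      right_orientation = character(0), class = character(0),
                      junction_seq = character(0), contig = character(0),
                      offset = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, calls)
}

#' Import junction calls from BLAST tabular output
#'
#' Adapter for external contig alignments: reads BLAST `-outfmt 6` hits of
#' contigs (queries) against the catalog fragments (subjects) and emits
#' the same call table as [scan_contigs()]. A hit anchors a fragment end
#' when it reaches within `tol` nt of the fragment terminus; adjacent
#' anchored ends along a contig yield one junction call. The junction
#' sequence itself is not recoverable from tabular output and is reported
#' as `NA`.
#'
#' @param path BLAST outfmt-6 file (qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore).
#' @param catalog a [fragment_catalog()] whose fragment names match the
#'   subject ids.
#' @param tol terminus tolerance in nt, default 5.
#' @return junction call data.frame (see [scan_contigs()]).
#' @export
read_blast_junctions <- function(path, catalog, tol = 5L) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(path, sep = "\t", col.names = cols,
                          stringsAsFactors = FALSE)
  flen <- vapply(catalog$fragments, nchar, integer(1))
  empty <- scan_contigs(character(0), catalog)
  calls <- list()
  for (cn in unique(df$qseqid)) {
    h <- df[df$qseqid == cn, , drop = FALSE]
    h <- h[order(pmin(h$qstart, h$qend)), , drop = FALSE]
    if (nrow(h) < 2) next
    for (i in seq_len(nrow(h) - 1L)) {
      a <- h[i, ]; b <- h[i + 1L, ]
      if (!(a$sseqid %in% names(flen)) || !(b$sseqid %in% names(flen))) next
      gap <- b$qstart - a$qend
      if (gap < -6L || gap > tol + 2L) next
      ao <- if (a$sstart <= a$send) "+" else "-"
      bo <- if (b$sstart <= b$send) "+" else "-"
      ## the left hit must end at a fragment terminus, the right one start
      ## at a terminus
      meet_left <- if (ao == "+") {
        if (a$send >= flen[[a$sseqid]] - tol) "tail" else NA
      } else if (a$send <= 1L + tol) "head" else NA
      meet_right <- if (bo == "+") {
        if (b$sstart <= 1L + tol) "head" else NA
      } else if (b$sstart >= flen[[b$sseqid]] - tol) "tail" else NA
      if (is.na(meet_left) || is.na(meet_right)) next
      cls <- if (meet_left == "tail" && meet_right == "head") "head-to-tail"
        else if (meet_left == "head" && meet_right == "tail") "head-to-tail"
        else if (meet_left == "tail") "tail-to-tail" else "head-to-head"
      calls[[length(calls) + 1L]] <- data.frame(
        left_fragment = a$sseqid, left_end = meet_left,
        left_orientation = ao, right_fragment = b$sseqid,
        right_end = meet_right, right_orientation = bo, class = cls,
        junction_seq = NA_character_, contig = cn, offset = a$qend,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty)
  do.call(rbind, calls)
}

#' Backbone presence call
#'
#' The plasmid backbone is present iff its marker/origin copy calls reach 1
#' or any junction call involves a backbone fragment.
#'
#' @param copy_report optional [copy_number_report()] containing `cat` /
#'   `ori` rows.
#' @param junction_calls optional [scan_contigs()] output.
#' @return list with `present` (logical) and `notes` (character).
#' @export
detect_backbone <- function(copy_report = NULL, junction_calls = NULL) {
  notes <- character(0)
  present <- FALSE
  if (!is.null(copy_report)) {
    bb <- copy_report[copy_report$region %in% c("cat", "ori"), , drop = FALSE]
    if (nrow(bb) && any(bb$copies_cassette >= 1)) {
      present <- TRUE
      notes <- c(notes, sprintf("%s copy call %d", bb$region, bb$copies_cassette))
    }
  }
  if (!is.null(junction_calls) && nrow(junction_calls)) {
    hit <- junction_calls$left_fragment == "backbone" |
      junction_calls$right_fragment == "backbone"
    if (any(hit)) {
      present <- TRUE
      notes <- c(notes, sprintf("%s backbone junction in %s",
                                junction_calls$class[hit],
                                junction_calls$contig[hit]))
    }
  }
  list(present = present, notes = notes)
}

#' Scan for off-target (chimeric) integrations
#'
#' Flags contigs that anchor one end in a cassette/backbone fragment and
#' the other end in genomic sequence outside the target locus and its
#' homology arms.
#'
#' @param contigs named character vector (or FASTA path).
#' @param genome a [make_toy_genome()] object (or named character vector of
#'   chromosomes).
#' @param catalog a [fragment_catalog()] of donor-derived fragments.
#' @param target_locus name of the intended locus (its cut +/- one arm
#'   length, plus margin, is excluded); `NULL` to flag every genomic join.
#' @param margin extra exclusion margin around the target locus, default
#'   1000 nt.
#' @return data.frame of chimeric joins (possibly empty).
#' @export
off_target_scan <- function(contigs, genome, catalog, target_locus = NULL,
                            margin = 1000L) {
  if (length(contigs) == 1 && file.exists(contigs)) contigs <- read_fasta(contigs)
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("contig%03d", seq_along(contigs))
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes else genome
  excl <- NULL
  if (!is.null(target_locus) && inherits(genome, "toy_genome")) {
    lc <- genome$loci[[target_locus]]
    arm <- genome$config$arm_len
    excl <- list(chrom = lc$chrom, span = c(lc$cut - arm - margin,
                                            lc$cut + arm + margin))
  }
  k <- catalog$k
  locate_genomic <- function(kmer) {
    for (nm in names(chroms)) {
      for (pat in c(kmer, revcomp_chr(kmer))) {
        p <- str_find_all(chroms[[nm]], pat)
        if (length(p)) return(list(chrom = nm, pos = p[1]))
      }
    }
    NULL
  }
  in_catalog <- function(kmer)
    any(vapply(catalog$anchors, function(a) a == kmer, logical(1))) ||
    any(vapply(names(catalog$fragments), function(nm) {
      s <- catalog$fragments[[nm]]
      length(str_find_all(s, kmer)) > 0 ||
        length(str_find_all(s, revcomp_chr(kmer))) > 0
    }, logical(1)))
  hits <- list()
  for (cn in names(contigs)) {
    contig <- contigs[[cn]]
    if (nchar(contig) < 2L * k) next
    ends <- c(left = substr(contig, 1L, k),
              right = substr(contig, nchar(contig) - k + 1L, nchar(contig)))
    donor_side <- vapply(ends, in_catalog, logical(1))
    genomic <- lapply(ends, locate_genomic)
    for (side in c("left", "right")) {
      other <- setdiff(c("left", "right"), side)
      g <- genomic[[other]]
      if (!donor_side[[side]] || is.null(g)) next
      if (donor_side[[other]]) next            # donor-donor join, not chimeric
      if (!is.null(excl) && g$chrom == excl$chrom &&
          g$pos >= excl$span[1] && g$pos < excl$span[2]) next
      hits[[length(hits) + 1L]] <- data.frame(
        contig = cn, donor_end = side, genomic_chrom = g$chrom,
        genomic_pos = g$pos, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(contig = character(0), donor_end = character(0),
                      genomic_chrom = character(0), genomic_pos = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Can a single read bridge a region?
#'
#' A region is spannable when a read is strictly longer than it, so one
#' read can anchor unique sequence on both sides; used to annotate which
#' single-crossover events are detectable at a given read length (a
#' 300-bp read cannot bridge a 493-bp promoter, but can bridge a 202-bp
#' terminator).
#'
#' @param read_len read length (nt).
#' @param region_len region length (nt).
#' @return logical.
#' @export
spannable <- function(read_len, region_len) {
  stopifnot(read_len > 0, region_len > 0)
  read_len > region_len
}

#' Fragment catalog for a designed donor
#'
#' Convenience: builds the cassette/backbone [fragment_catalog()] from a
#' [donor_reference()], using the filled (blunt) fragment sequences.
#'
#' @param donor_ref a `donor_reference`.
#' @param k anchor k-mer length.
#' @return a `fragment_catalog`.
#' @export
donor_catalog <- function(donor_ref, k = 40L) {
  c_end <- donor_ref$cassette_end
  ref <- donor_ref$ref
  fragment_catalog(c(
    cassette = substr0(ref, 0L, c_end + 4L),
    backbone = substr0(ref, c_end, donor_ref$length)), k = k)
}
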