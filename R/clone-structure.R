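#' Declarative description of an integration event
#'
#' A `clone_structure` states what sits at a landing locus: an ordered chain
#' of EcoRI fragments from the linearized donor (cassette and/or plasmid
#' backbone), each in `+` or `-` orientation, joined in vivo at their AATT
#' cohesive ends (regenerating GAATTC at every junction), plus an optional
#' terminal deletion of everything distal to the integrated chain.
#'
#' @param locus landing-locus name.
#' @param segments data.frame with columns `kind` (`"cassette"` or
#'   `"backbone"`) and `orientation` (`"+"`/`"-"`), one row per fragment in
#'   chain order; or a character vector of kinds (all `+`).
#' @param distal_loss if `TRUE`, the chromosome is truncated right after the
#'   integrated chain (terminal-deletion clone).
#' @param id clone identifier.
#' @return object of class `clone_structure`.
#' @export
#' @examples
#' tandem_structure("PFK1", 2)
clone_structure <- function(locus, segments, distal_loss = FALSE,
                            id = paste0(locus, "_clone")) {
  if (is.character(segments))
    segments <- data.frame(kind = segments,
                           orientation = rep("+", length(segments)),
                           stringsAsFactors = FALSE)
  stopifnot(all(segments$kind %in% c("cassette", "backbone")),
            all(segments$orientation %in% c("+", "-")),
            nrow(segments) >= 1)
  structure(list(locus = locus, segments = segments,
                 distal_loss = isTRUE(distal_loss), id = id),
            class = "clone_structure")
}

#' @rdname clone_structure
#' @param n number of tandem cassette copies (head-to-tail).
#' @export
single_copy_structure <- function(locus, id = paste0(locus, "_single"))
  clone_structure(locus, "cassette", id = id)

#' @rdname clone_structure
#' @export
tandem_structure <- function(locus, n, distal_loss = FALSE,
                             id = sprintf("%s_tandem%d", locus, n))
  clone_structure(locus, rep("cassette", n), distal_loss = distal_loss, id = id)

#' @export
print.clone_structure <- function(x, ...) {
  cat(sprintf("<clone_structure %s @ %s: %s%s>\n", x$id, x$locus,
              paste0(x$segments$orientation, x$segments$kind, collapse = " | "),
              if (x$distal_loss) " + distal loss" else ""))
  invisible(x)
}

## classify the junction where the right side of fragment a (orientation oa)
## meets the left side of fragment b (orientation ob)
junction_class <- function(oa, ob) {
  right_end <- if (oa == "+") "tail" else "head"
  left_end <- if (ob == "+") "head" else "tail"
  if (right_end == "tail" && left_end == "head") "head-to-tail"
  else if (right_end == "head" && left_end == "tail") "head-to-tail"
  else if (right_end == "tail" && left_end == "tail") "tail-to-tail"
  else "head-to-head"
}

## EcoRI fragment span on the donor reference: cassette = [0, c),
## backbone = [c, Lp) with the reference carrying a 4-nt filled AATT tail
fragment_span <- function(donor_ref, kind) {
  if (kind == "cassette") c(0L, donor_ref$cassette_end)
  else c(donor_ref$cassette_end, donor_ref$length - 4L)
}

## one chain fragment: clone-string + projection blocks relative to the
## fragment's own start. "+": ref[f0, f1); "-": revcomp(ref[f0+4, f1+4)).
chain_fragment <- function(donor_ref, genome, locus_name, kind, orient) {
  sp <- fragment_span(donor_ref, kind)
  f0 <- sp[1]; f1 <- sp[2]
  ref <- donor_ref$ref
  lc <- genome$loci[[locus_name]]
  if (orient == "+") {
    str <- substr0(ref, f0, f1)
    plasmid_block <- data.frame(rel = 0L, len = f1 - f0, ref = "plasmid",
                                src = f0, strand = "+", stringsAsFactors = FALSE)
    extra <- genomic_projections(donor_ref, genome, lc, kind,
                                 frag0 = f0, frag1 = f1, orient = "+")
  } else {
    str <- revcomp_chr(substr0(ref, f0 + 4L, f1 + 4L))
    plasmid_block <- data.frame(rel = 0L, len = f1 - f0, ref = "plasmid",
                                src = f0 + 4L, strand = "-", stringsAsFactors = FALSE)
    extra <- genomic_projections(donor_ref, genome, lc, kind,
                                 frag0 = f0 + 4L, frag1 = f1 + 4L, orient = "-")
  }
  list(str = str, blocks = rbind(plasmid_block, extra))
}

## genomic projections of cassette elements (uHR/dHR to the landing locus,
## promoter/terminator to the native locus) for one chain fragment
genomic_projections <- function(donor_ref, genome, lc, kind, frag0, frag1,
                                orient) {
  if (kind != "cassette") return(NULL)
  reg <- donor_ref$regions
  nl <- genome$native_locus
  targets <- list(
    uHR = c(list(ref = lc$chrom), list(src = lc$uHR_span[1])),
    dHR = c(list(ref = lc$chrom), list(src = lc$dHR_span[1])),
    promoter = list(ref = nl$chrom, src = nl$promoter_span[1]),
    terminator = list(ref = nl$chrom, src = nl$terminator_span[1]))
  out <- NULL
  for (nm in names(targets)) {
    r <- reg[reg$name == nm, ]
    if (nrow(r) != 1) next
    a <- r$start; b <- r$end           # element span on the plasmid ref
    if (a < frag0 || b > frag1) next
    len <- b - a
    rel <- if (orient == "+") a - frag0 else frag1 - b
    out <- rbind(out, data.frame(rel = rel, len = len,
                                 ref = targets[[nm]]$ref,
                                 src = targets[[nm]]$src,
                                 strand = orient, stringsAsFactors = FALSE))
  }
  out
}

#' Apply a clone structure to the toy genome
#'
#' Builds the clone genome: wild type everywhere except the landing locus,
#' where the ligated chain of donor fragments replaces the segment between
#' the homology-arm boundaries (double-crossover exchange trims the
#' terminal EcoRI overhang remnants when the chain starts/ends in a
#' plus-orientation cassette). Every clone block carries projections onto
#' the mapping references (wild-type chromosomes and the donor-plasmid
#' reference), so exact depth tracks can be computed without an aligner.
#'
#' @param genome a [make_toy_genome()].
#' @param donor a [design_donor()] result (or a `donor_reference`).
#' @param structure a [clone_structure()].
#' @return object of class `sim_clone`: clone `chromosomes`, projection
#'   `blocks`, reference lengths, and a ground-truth record (`counts`,
#'   `junctions`, `lost_span`, `lost_genes`).
#' @export
apply_structure <- function(genome, donor, structure) {
  donor_ref <- if (inherits(donor, "donor_reference")) donor else donor$ref
  stopifnot(inherits(structure, "clone_structure"))
  lc <- genome$loci[[structure$locus]]
  if (is.null(lc)) stop("invalid structure: unknown locus ", structure$locus)
  segs <- structure$segments
  n <- nrow(segs)

  frags <- lapply(seq_len(n), function(i)
    chain_fragment(donor_ref, genome, structure$locus,
                   segs$kind[i], segs$orientation[i]))

  ## trim the 5' AATTC scar when the chain begins with a +cassette (the
  ## upstream crossover falls inside uHR), likewise the 3' G / fill-AATT
  trim_lead <- segs$kind[1] == "cassette" && segs$orientation[1] == "+"
  trim_tail <- segs$kind[n] == "cassette" && segs$orientation[n] == "+"
  if (trim_lead) {
    f <- frags[[1]]
    f$str <- substr(f$str, 6L, nchar(f$str))
    f$blocks$len[1] <- f$blocks$len[1] - 5L
    f$blocks$src[1] <- f$blocks$src[1] + 5L
    f$blocks$rel <- f$blocks$rel - 5L
    f$blocks$rel[1] <- 0L
    f$blocks <- f$blocks[f$blocks$rel >= 0, , drop = FALSE]
    frags[[1]] <- f
  }
  if (trim_tail) {
    f <- frags[[n]]
    f$str <- substr(f$str, 1L, nchar(f$str) - 1L)
    f$blocks$len[1] <- f$blocks$len[1] - 1L
    frags[[n]] <- f
  }

  chain <- paste(vapply(frags, function(f) f$str, character(1)), collapse = "")
  offs <- cumsum(c(0L, vapply(frags, function(f) nchar(f$str), integer(1))))
  if (!trim_tail) {
    sp <- fragment_span(donor_ref, segs$kind[n])
    fill_src <- if (segs$orientation[n] == "+") sp[2] else sp[1]
    chain <- paste0(chain, "AATT")
  }

  chrom <- genome$chromosomes[[lc$chrom]]
  L <- nchar(chrom)
  u0 <- lc$uHR_span[1]; d1 <- lc$dHR_span[2]
  left_flank <- substr0(chrom, 0, u0)
  right_flank <- if (structure$distal_loss) "" else substr0(chrom, d1, L)
  clone_chrom <- paste0(left_flank, chain, right_flank)

  ## projection blocks for the modified chromosome
  blocks <- list()
  addb <- function(clone_start, len, ref, src, strand)
    blocks[[length(blocks) + 1L]] <<- data.frame(
      clone_chrom = lc$chrom, clone_start = as.integer(clone_start),
      len = as.integer(len), ref = ref, src = as.integer(src),
      strand = strand, stringsAsFactors = FALSE)
  addb(0L, u0, lc$chrom, 0L, "+")
  for (i in seq_len(n)) {
    b <- frags[[i]]$blocks
    for (j in seq_len(nrow(b)))
      addb(u0 + offs[i] + b$rel[j], b$len[j], b$ref[j], b$src[j], b$strand[j])
  }
  chain_end <- u0 + nchar(chain)
  if (!trim_tail)
    addb(chain_end - 4L, 4L, "plasmid",
         if (segs$orientation[n] == "+") fill_src else fill_src, segs$orientation[n])
  if (!structure$distal_loss)
    addb(chain_end, L - d1, lc$chrom, d1, "+")

  ## unmodified chromosomes project to themselves; the native locus also
  ## projects onto the plasmid promoter/terminator regions
  chroms_out <- genome$chromosomes
  chroms_out[[lc$chrom]] <- clone_chrom
  for (nm in names(genome$chromosomes)) {
    if (nm != lc$chrom)
      blocks[[length(blocks) + 1L]] <- data.frame(
        clone_chrom = nm, clone_start = 0L,
        len = nchar(genome$chromosomes[[nm]]), ref = nm, src = 0L,
        strand = "+", stringsAsFactors = FALSE)
  }
  nl <- genome$native_locus
  reg <- donor_ref$regions
  if (nl$chrom != lc$chrom) {  # native locus sits on an unmodified chromosome
    for (el in c("promoter", "terminator")) {
      r <- reg[reg$name == el, ]
      sp <- nl[[paste0(el, "_span")]]
      blocks[[length(blocks) + 1L]] <- data.frame(
        clone_chrom = nl$chrom, clone_start = sp[1], len = sp[2] - sp[1],
        ref = "plasmid", src = r$start, strand = "+", stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, blocks)

  ## ground truth
  n_cass <- sum(segs$kind == "cassette")
  n_bb <- sum(segs$kind == "backbone")
  counts <- c(egfp = n_cass, promoter = n_cass + 1L, terminator = n_cass + 1L,
              uHR = n_cass, dHR = n_cass, cat = n_bb, ori = n_bb)
  junctions <- NULL
  if (n >= 2) {
    junctions <- data.frame(
      left_kind = segs$kind[-n], left_orientation = segs$orientation[-n],
      right_kind = segs$kind[-1], right_orientation = segs$orientation[-1],
      class = mapply(junction_class, segs$orientation[-n], segs$orientation[-1]),
      junction_seq = "GAATTC",
      clone_chrom = lc$chrom,
      clone_pos = u0 + offs[2:n],
      stringsAsFactors = FALSE)
    rownames(junctions) <- NULL
  }
  lost_span <- NULL; lost_genes <- character(0)
  if (structure$distal_loss) {
    lost_span <- c(d1, L)
    a <- genome$annotation
    lost_genes <- a$gene_id[a$chrom == lc$chrom & a$start >= d1]
  }
  structure(list(
    chromosomes = chroms_out, blocks = blocks,
    ref_lengths = c(vapply(genome$chromosomes, nchar, integer(1)),
                    plasmid = donor_ref$length),
    genome_refs = names(genome$chromosomes),
    donor_ref = donor_ref, clone_structure = structure,
    truth = list(counts = counts, junctions = junctions,
                 lost_span = lost_span, lost_genes = lost_genes)),
    class = "sim_clone")
}

#' @export
print.sim_clone <- function(x, ...) {
  st <- x$clone_structure
  cat(sprintf("<sim_clone %s: %d segment(s) at %s%s>\n", st$id,
              nrow(st$segments), st$locus,
              if (st$distal_loss) ", distal loss" else ""))
  cat("  truth counts:",
      paste(names(x$truth$counts), x$truth$counts, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Error-free contigs spanning the truth junctions
#'
#' Extracts windows of the clone genome centred on every inter-fragment
#' junction; used for hermetic loop-back tests of the junction classifier.
#'
#' @param clone a [apply_structure()] result.
#' @param flank nt of context on each side of the junction.
#' @return named character vector of contig sequences (empty if the clone
#'   has no junctions).
#' @export
truth_contigs <- function(clone, flank = 120L) {
  j <- clone$truth$junctions
  if (is.null(j)) return(character(0))
  out <- character(nrow(j))
  for (i in seq_len(nrow(j))) {
    s <- clone$chromosomes[[j$clone_chrom[i]]]
    a <- max(0L, j$clone_pos[i] - flank)
    b <- min(nchar(s), j$clone_pos[i] + flank)
    out[i] <- substr0(s, a, b)
  }
  names(out) <- sprintf("junction_contig_%02d", seq_len(nrow(j)))
  out
}

#' Write the clone genome and truth record to disk
#'
#' @param clone a `sim_clone`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_clone <- function(clone, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "clone_genome.fasta")
  write_fasta(clone$chromosomes, fa)
  tr <- file.path(dir, "truth.json")
  jsonlite::write_json(list(counts = as.list(clone$truth$counts),
                            junctions = clone$truth$junctions,
                            lost_span = clone$truth$lost_span,
                            lost_genes = clone$truth$lost_genes),
                       tr, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  tsv <- file.path(dir, "truth_counts.tsv")
  utils::write.table(data.frame(element = names(clone$truth$counts),
                                copies = as.integer(clone$truth$counts)),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, tr, tsv))
}
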