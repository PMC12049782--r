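## Synthetic study system: a toy multi-chromosome yeast genome with three
## CRISPR landing loci and one native locus carrying the cassette promoter
## and terminator, mirroring the geometry of the K. phaffii system
## (PFK1- and ROX1-like loci on chr2, the 04576-like locus on chr4, the
## ROX1-like cut 36.6 kb from the distal end of the 2.4-Mb chromosome).

#' Toy genome configuration
#'
#' @param preset `"full"` (9.15-Mb study-scale geometry: a 36.6-kb terminal
#'   loss is 1.5% of chr2 and 0.4% of the genome), `"midi"` (1/3 scale,
#'   used for replicate-heavy copy-number work where the genome must stay
#'   large against the cassette homology footprint) or `"mini"` (1/10
#'   scale, same local geometry; fastest).
#' @param arm_len homology-arm length, default 500 nt.
#' @param rox_distance distance of the ROX1-like cut from the distal end of
#'   chr2, default 36,600 nt.
#' @return a list of class `toy_genome_config`.
#' @export
toy_genome_config <- function(preset = c("full", "midi", "mini"),
                              arm_len = 500L, rox_distance = 36600L) {
  preset <- match.arg(preset)
  scale <- switch(preset, full = 1, midi = 1 / 3, mini = 0.1)
  lens <- round(c(chr1 = 2850000, chr2 = 2400000, chr3 = 2250000,
                  chr4 = 1650000) * scale)
  loci <- list(
    PFK1    = list(chrom = "chr2", cut = round(1200000 * scale)),
    ROX1    = list(chrom = "chr2", cut = lens[["chr2"]] - rox_distance),
    `04576` = list(chrom = "chr4", cut = round(1000000 * scale))
  )
  structure(list(
    preset = preset, chrom_lengths = lens, loci = loci,
    arm_len = as.integer(arm_len), rox_distance = as.integer(rox_distance),
    native_locus = list(chrom = "chr3", pos = round(1000000 * scale)),
    promoter_len = 493L, terminator_len = 202L, egfp_len = 720L,
    tdh3_len = 999L, cat_len = 660L, ori_len = 589L,
    n_distal_genes = 15L, n_distal_rrna = 2L, n_other_genes = 20L
  ), class = "toy_genome_config")
}

## random DNA free of the given enzymes' sites (scrubbed, deterministic
## given the RNG state)
clean_random_dna <- function(n, forbidden = c("BpiI", "BsaI", "EcoRI",
                                              "XhoI", "BamHI", "NotI")) {
  repeat {
    s <- pad_cc(scrub_sites(pad_cc(random_dna(n)), forbidden))
    clean <- TRUE
    for (e in forbidden) if (nrow(find_sites(s, e))) { clean <- FALSE; break }
    if (clean) return(s)
  }
}

#' Build the toy wild-type genome
#'
#' Deterministic for a fixed seed. The genome carries three landing loci
#' each admitting 500-nt homology arms, and a native locus on chr3 holding
#' one copy each of the cassette promoter (493 nt) and terminator (202 nt)
#' around a housekeeping ORF, so single-cassette clones show these elements
#' twice genome-wide. The annotation places 15 protein-coding genes and two
#' rRNA genes in the distal segment of chr2 beyond the ROX1-like cut.
#'
#' @param config a [toy_genome_config()].
#' @param seed integer seed.
#' @return object of class `toy_genome`: chromosomes, loci (with uHR/dHR
#'   spans), sequence elements (promoter, terminator, egfp, cat, ori, ...),
#'   and an annotation table.
#' @export
make_toy_genome <- function(config = toy_genome_config(), seed = 1L) {
  stopifnot(inherits(config, "toy_genome_config"))
  arm <- config$arm_len
  for (lc in config$loci) {
    L <- config$chrom_lengths[[lc$chrom]]
    if (lc$cut - arm < 0 || lc$cut + arm > L)
      stop("config error: locus does not admit ", arm, "-nt arms")
  }
  with_seed(seed, {
    chroms <- vapply(config$chrom_lengths, random_dna, character(1))
    elements <- list(
      promoter   = clean_random_dna(config$promoter_len),
      terminator = clean_random_dna(config$terminator_len),
      egfp       = clean_random_dna(config$egfp_len),
      tdh3       = clean_random_dna(config$tdh3_len),
      cat        = clean_random_dna(config$cat_len),
      ori        = clean_random_dna(config$ori_len),
      hairpin    = make_hairpin(),
      stuffer    = clean_random_dna(30L)
    )
    ## implant the native promoter-TDH3-terminator locus on chr3
    nl <- config$native_locus
    native <- paste0(elements$promoter, elements$tdh3, elements$terminator)
    ch <- chroms[[nl$chrom]]
    substr(ch, nl$pos + 1L, nl$pos + nchar(native)) <- native
    chroms[[nl$chrom]] <- ch

    loci <- lapply(config$loci, function(lc) {
      list(chrom = lc$chrom, cut = as.integer(lc$cut),
           uHR_span = c(lc$cut - arm, lc$cut),
           dHR_span = c(lc$cut, lc$cut + arm))
    })

    annotation <- build_annotation(config, loci)
  })
  structure(list(chromosomes = chroms, loci = loci, elements = elements,
                 native_locus = list(chrom = config$native_locus$chrom,
                                     promoter_span = c(config$native_locus$pos,
                                                       config$native_locus$pos + config$promoter_len),
                                     terminator_span = c(config$native_locus$pos + config$promoter_len + config$tdh3_len,
                                                         config$native_locus$pos + config$promoter_len + config$tdh3_len + config$terminator_len)),
                 annotation = annotation, config = config, seed = seed),
            class = "toy_genome")
}

## default hairpin: artificial transcriptional terminator placeholder,
## 20-nt stem + 8-nt loop inverted repeat, site-free by rejection
make_hairpin <- function(stem = 20L, loop = 8L) {
  repeat {
    st <- random_dna(stem)
    hp <- paste0(st, random_dna(loop), revcomp_chr(st))
    ok <- TRUE
    for (e in c("BpiI", "BsaI", "EcoRI", "XhoI", "BamHI", "NotI"))
      if (nrow(find_sites(hp, e)) > 0) { ok <- FALSE; break }
    if (ok) return(hp)
  }
}

build_annotation <- function(config, loci) {
  rows <- list()
  add <- function(id, chrom, start, end, type = "protein_coding")
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = id, chrom = chrom, start = as.integer(start),
      end = as.integer(end), type = type, stringsAsFactors = FALSE)
  ## distal chr2 segment beyond the ROX1-like dHR: ROX1 itself, 14 more
  ## protein-coding genes, and 2 rRNA genes
  rox <- loci$ROX1
  L2 <- config$chrom_lengths[["chr2"]]
  gene_len <- max(200L, min(1200L, (L2 - (rox$cut + 1000L)) %/%
                              (config$n_distal_genes + config$n_distal_rrna + 1L) - 400L))
  pos <- rox$cut + 1000L
  add("ROX1", "chr2", pos, pos + gene_len)
  pos <- pos + gene_len + 400L
  for (i in seq_len(config$n_distal_genes - 1L)) {
    add(sprintf("DIST%02d", i), "chr2", pos, pos + gene_len)
    pos <- pos + gene_len + 400L
  }
  for (i in seq_len(config$n_distal_rrna)) {
    add(sprintf("rRNA%d", i), "chr2", pos, pos + gene_len, type = "rRNA")
    pos <- pos + gene_len + 400L
  }
  if (pos > L2) stop("config error: distal annotation does not fit")
  ## native locus gene + background genes spread over the other chromosomes
  nl <- config$native_locus
  add("TDH3", nl$chrom, nl$pos + config$promoter_len,
      nl$pos + config$promoter_len + config$tdh3_len)
  chrs <- names(config$chrom_lengths)
  for (i in seq_len(config$n_other_genes)) {
    chrom <- chrs[(i - 1L) %% length(chrs) + 1L]
    at <- round(config$chrom_lengths[[chrom]] * 0.15 +
                  (i - 1L) %/% length(chrs) * 23000L)
    add(sprintf("GENE%03d", i), chrom, at, at + 900L)
  }
  do.call(rbind, rows)
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("<toy_genome (%s preset, seed %d): %d chromosomes, %.2f Mb>\n",
              x$config$preset, x$seed, length(x$chromosomes),
              sum(nchar(x$chromosomes)) / 1e6))
  for (nm in names(x$loci))
    cat(sprintf("  locus %-6s %s cut %d\n", nm, x$loci[[nm]]$chrom,
                x$loci[[nm]]$cut))
  invisible(x)
}

#' Export the toy annotation as GFF3
#'
#' @param genome a [make_toy_genome()] object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_annotation_gff3 <- function(genome, path) {
  a <- genome$annotation
  gr <- GenomicRanges::GRanges(
    seqnames = a$chrom,
    ranges = IRanges::IRanges(start = a$start + 1L, end = a$end),
    type = "gene", ID = a$gene_id, biotype = a$type)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an annotation table from GFF3 or BED
#'
#' @param path annotation file (`.gff3`/`.gff` or `.bed`).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open) and `type`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  id <- if (!is.null(md$ID)) md$ID else if (!is.null(md$name)) md$name
        else sprintf("feature%04d", seq_along(gr))
  data.frame(gene_id = as.character(id), chrom = as.character(md$seqnames),
             start = md$start - 1L, end = md$end,
             type = if (!is.null(md$biotype)) as.character(md$biotype)
                    else "feature",
             stringsAsFactors = FALSE)
}
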