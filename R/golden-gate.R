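#' Fusion-site vocabulary
#'
#' The fixed 4-nt overhang identities used as junction keys in the modular
#' cloning grammar: Fs1-Fs4 order parts within one transcription unit,
#' FsA-FsC order transcription units, and FsX is the in-frame junction at
#' the end of the alpha-mating-factor secretion leader.
#'
#' @param label fusion-site label, e.g. `"Fs1"`.
#' @return 4-nt overhang sequence.
#' @export
#' @examples
#' fusion_site("Fs1")
fusion_site <- function(label) {
  tab <- fusion_sites()
  if (!label %in% names(tab)) stop("unknown fusion site: ", label)
  tab[[label]]
}

#' @rdname fusion_site
#' @export
fusion_sites <- function() {
  c(Fs1 = "GGAG", Fs2 = "CATG", Fs3 = "GCTT", Fs4 = "CGCT",
    FsA = "GATC", FsB = "CCGG", FsC = "AATT", FsX = "AGCT")
}

resolve_fs <- function(x) {
  if (nchar(x) == 4 && !x %in% names(fusion_sites()) && !grepl("[^ACGT]", toupper(x)))
    return(toupper(x))
  fusion_site(x)
}

#' Build a Golden Gate part
#'
#' Wraps a payload sequence with outward-facing type IIS sites so that
#' digestion excises `upstream_fs + payload`, with left overhang
#' `upstream_fs` and right overhang `downstream_fs`. The payload interior
#' must be free of the assembly enzyme's recognition site.
#'
#' @param payload payload sequence (promoter, CDS, terminator, ...).
#' @param upstream_fs,downstream_fs fusion-site labels or explicit 4-mers.
#' @param enz assembly enzyme (type IIS), default BpiI.
#' @param role part role, recorded for provenance.
#' @param id molecule id.
#' @param circular if `TRUE` the part is returned as a circular plasmid
#'   (payload cloned on a small carrier backbone), as in a BB1-level module;
#'   otherwise a linear amplicon.
#' @return a [nucleic_seq()] carrying attributes `role` and `fs`.
#' @export
gg_part <- function(payload, upstream_fs, downstream_fs, enz = "BpiI",
                    role = "cds", id = role, circular = FALSE) {
  enz <- as_enzyme(enz)
  if (!inherits(enz, "type_iis_enzyme")) stop("assembly enzyme must be type IIS")
  up <- resolve_fs(upstream_fs); down <- resolve_fs(downstream_fs)
  if (length(str_find_all(payload, enz$recognition)) ||
      length(str_find_all(payload, revcomp_chr(enz$recognition))))
    stop("invalid part: payload contains an internal ", enz$name, " site")
  spacer_n <- strrep("A", enz$spacer)
  bases <- paste0(enz$recognition, spacer_n, up, payload, down,
                  spacer_n, revcomp_chr(enz$recognition))
  out <- nucleic_seq(bases, id = id,
                     topology = if (circular) "circular" else "linear")
  attr(out, "role") <- role
  attr(out, "fs") <- c(up = up, down = down)
  out
}

#' Golden Gate assembly
#'
#' Simulates a one-pot cut-ligate reaction: all molecules are digested with
#' the type IIS assembly enzyme, recognition-site-carrying waste fragments
#' are discarded, and the remaining fragments are joined on a directed graph
#' whose edges connect a right cohesive-end label to an identical left
#' label. The unique circular path through the vector backbone that uses
#' every insert payload exactly once is returned; by construction it carries
#' no residual recognition site, so re-digestion with the same enzyme is a
#' no-op.
#'
#' @param vector recipient plasmid (circular `nucleic_seq`) with exactly two
#'   sites of the assembly enzyme flanking its dispensable linker.
#' @param inserts list of insert molecules (e.g. from [gg_part()]), each with
#'   exactly two sites.
#' @param enz assembly enzyme, default BpiI.
#' @return circular [nucleic_seq()] assembly product.
#' @export
assemble_golden_gate <- function(vector, inserts, enz = "BpiI") {
  enz <- as_enzyme(enz)
  mols <- c(list(vector), inserts)
  has_site <- function(b) length(str_find_all(b, enz$recognition)) +
    length(str_find_all(b, revcomp_chr(enz$recognition)))
  payloads <- list(); origin <- integer(0)
  for (i in seq_along(mols)) {
    m <- as_nucleic_seq(mols[[i]])
    nsite <- nrow(find_sites(m, enz))
    if (nsite != 2)
      stop(sprintf("invalid part: molecule %d carries %d %s sites (expected 2)",
                   i, nsite, enz$name))
    keep <- Filter(function(f) has_site(f$bases) == 0, digest(m, enz))
    if (i > 1 && length(keep) != 1)
      stop("invalid part: insert ", i - 1, " does not yield a unique site-free payload")
    if (i == 1) {
      lens <- vapply(keep, length, integer(1))
      keep <- keep[which.max(lens)]  # vector backbone = large site-free fragment
    }
    payloads <- c(payloads, keep)
    origin <- c(origin, i)
  }
  lefts <- vapply(payloads, function(f) f$left_end %||% "", character(1))
  rights <- vapply(payloads, function(f) f$right_end %||% "", character(1))

  ## walk the ligation graph from the vector backbone
  path <- 1L
  repeat {
    cur <- path[length(path)]
    nxt <- which(lefts == rights[cur])
    if (length(nxt) == 0)
      stop("incompatible fusion sites: no left end matches label ",
           rights[cur], " (unmatched: ",
           paste(setdiff(union(lefts, rights),
                         intersect(lefts, rights)), collapse = ", "), ")")
    if (length(nxt) > 1)
      stop("ambiguous assembly: label ", rights[cur],
           " matches more than one fragment")
    if (nxt == 1L) break
    if (nxt %in% path) stop("ambiguous assembly: sub-cycle excludes the vector")
    path <- c(path, nxt)
  }
  if (!setequal(path, seq_along(payloads)))
    stop("incompatible fusion sites: payload(s) ",
         paste(setdiff(seq_along(payloads), path), collapse = ", "),
         " not incorporated in the closed assembly")
  bases <- paste(vapply(payloads[path], function(f) f$bases, character(1)),
                 collapse = "")
  prod <- nucleic_seq(bases, id = paste0(vector$id, "_assembled"),
                      topology = "circular")
  stopifnot(nrow(find_sites(prod, enz)) == 0)
  prod
}

#' Validate a construct against the cloning grammar
#'
#' Reports every occurrence of an assembly enzyme's recognition site, and
#' checks the linearization rule: the construct must lack at least one of
#' the configured single-cutter linearization sites so that the final donor
#' plasmid can be opened once.
#'
#' @param seq molecule to check.
#' @param assembly_enzymes enzymes whose sites are forbidden anywhere
#'   (default BpiI + BsaI).
#' @param linearization_sites candidate linearization enzymes
#'   (default EcoRI, XhoI, BamHI, NotI).
#' @return data.frame of violations (`enzyme`, `position`, `strand`,
#'   `type`); zero rows when the construct is clean.
#' @export
validate_part <- function(seq, assembly_enzymes = c("BpiI", "BsaI"),
                          linearization_sites = c("EcoRI", "XhoI", "BamHI", "NotI")) {
  seq <- as_nucleic_seq(seq)
  viol <- data.frame(enzyme = character(0), position = integer(0),
                     strand = character(0), type = character(0),
                     stringsAsFactors = FALSE)
  for (e in assembly_enzymes) {
    ez <- as_enzyme(e)
    hits <- find_sites(seq, ez)
    if (nrow(hits))
      viol <- rbind(viol, data.frame(enzyme = ez$name, position = hits$position,
                                     strand = hits$strand, type = "assembly_site",
                                     stringsAsFactors = FALSE))
  }
  if (length(linearization_sites)) {
    present <- vapply(linearization_sites,
                      function(e) nrow(find_sites(seq, as_enzyme(e))) > 0,
                      logical(1))
    if (all(present))
      viol <- rbind(viol, data.frame(enzyme = paste(linearization_sites, collapse = "+"),
                                     position = NA_integer_, strand = NA_character_,
                                     type = "linearization_rule",
                                     stringsAsFactors = FALSE))
  }
  viol
}
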