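## Donor-helper plasmid construction (crBB3-style): a chloramphenicol/ori
## backbone, two EcoRI sites flanking the cassette region, 500-nt homology
## arms, a hairpin terminator insulating the cassette, and a BpiI-excisable
## linker presenting fusion sites Fs1/Fs4 to receive one transcription unit.

#' Build an empty donor helper plasmid
#'
#' Layout (circular): `GAATTC | uHR | hairpin | Fs1-linker-Fs4 | dHR |
#' GAATTC | backbone(cat, ori)`. BpiI digestion of the plasmid excises the
#' linker and leaves the vector fragment with cohesive ends Fs4 (left) and
#' Fs1 (right), ready to receive promoter-gene-terminator parts; EcoRI
#' digestion releases the cassette region from the backbone.
#'
#' @param uHR,dHR homology-arm sequences (already scrubbed; see
#'   [extract_homology_arms()]).
#' @param elements named list providing `cat`, `ori`, `hairpin` and
#'   `stuffer` sequences (e.g. `genome$elements` from [make_toy_genome()]).
#' @param id plasmid id.
#' @return circular [nucleic_seq()] with a `features` attribute
#'   (data.frame of 0-based half-open spans).
#' @export
crbb3_vector <- function(uHR, dHR, elements, id = "crBB3") {
  fs <- fusion_sites()
  linker <- paste0(fs[["Fs1"]], "AA", revcomp_chr(enzyme("BpiI")$recognition),
                   elements$stuffer, enzyme("BpiI")$recognition, "AA",
                   fs[["Fs4"]])
  segs <- list(ecoRI_up = "GAATTC", uHR = uHR, hairpin = elements$hairpin,
               linker = linker, dHR = dHR, ecoRI_down = "GAATTC",
               cat = elements$cat, spacer = elements$stuffer,
               ori = elements$ori)
  bases <- paste(unlist(segs), collapse = "")
  off <- cumsum(c(0L, vapply(segs, nchar, integer(1))))
  feats <- data.frame(name = names(segs),
                      start = off[-length(off)], end = off[-1L],
                      stringsAsFactors = FALSE)
  out <- nucleic_seq(bases, id = id, topology = "circular")
  attr(out, "features") <- feats
  out
}

#' Assemble an expression-cassette donor plasmid
#'
#' Runs the hierarchical build for one transcription unit: wraps promoter,
#' gene and terminator payloads as BpiI parts (Fs1>Fs2, Fs2>Fs3, Fs3>Fs4),
#' then Golden-Gate-assembles them into the [crbb3_vector()].
#'
#' @param vector an empty donor helper plasmid from [crbb3_vector()].
#' @param promoter,gene,terminator payload sequences.
#' @param gene_fs fusion sites for the gene part, default `c("Fs2","Fs3")`;
#'   pass e.g. `c("Fs2","FsX")` plus an extra `signal` part for secretion
#'   constructs.
#' @param extra_parts optional list of additional [gg_part()]s.
#' @return circular [nucleic_seq()] donor cassette plasmid.
#' @export
crbb3_assemble_cassette <- function(vector, promoter, gene, terminator,
                                    gene_fs = c("Fs2", "Fs3"),
                                    extra_parts = list()) {
  parts <- c(list(
    gg_part(promoter, "Fs1", "Fs2", role = "promoter"),
    gg_part(gene, gene_fs[1], gene_fs[2], role = "cds")),
    extra_parts,
    list(gg_part(terminator, "Fs3", "Fs4", role = "terminator")))
  assemble_golden_gate(vector, parts, "BpiI")
}

#' Linearized donor reference with element coordinates
#'
#' Rotates the circular donor plasmid to start at the EcoRI cut that opens
#' the cassette fragment and appends the 4-nt filled overhang, giving the
#' mapping reference used for plasmid depth tracks. Element regions are
#' located by unique substring match.
#'
#' @param donor circular donor plasmid (from [crbb3_assemble_cassette()]).
#' @param elements named character vector/list of element sequences to
#'   locate (`uHR`, `promoter`, `egfp`, `terminator`, `dHR`, `cat`, `ori`).
#' @return list of class `donor_reference`: `ref` (character sequence),
#'   `regions` (data.frame name/start/end/native_multiplicity),
#'   `cassette_end` (0-based end of the cassette fragment = start of the
#'   backbone fragment) and `length`.
#' @export
donor_reference <- function(donor, elements) {
  donor <- as_nucleic_seq(donor)
  sites <- find_sites(donor, "EcoRI")
  if (nrow(sites) != 2)
    stop("donor plasmid must carry exactly two EcoRI sites")
  Lp <- nchar(donor$bases)
  cuts <- sort((sites$position + 1L) %% Lp)
  ## choose the rotation whose first fragment contains uHR ... dHR (cassette)
  for (i in 1:2) {
    r <- rotate_str(donor$bases, cuts[i])
    cassette_end <- ((cuts[3 - i] - cuts[i]) %% Lp + Lp) %% Lp
    u <- str_find_all(r, as.character(elements[["uHR"]]))
    d <- str_find_all(r, as.character(elements[["dHR"]]))
    if (length(u) == 1 && length(d) == 1 && u < d && d < cassette_end) {
      ref <- paste0(r, "AATT")
      native <- c(uHR = 1L, promoter = 1L, terminator = 1L, dHR = 1L,
                  egfp = 0L, cat = 0L, ori = 0L)
      regions <- do.call(rbind, lapply(names(elements), function(nm) {
        p <- str_find_all(ref, as.character(elements[[nm]]))
        if (length(p) != 1) return(NULL)
        data.frame(name = nm, start = p,
                   end = p + nchar(as.character(elements[[nm]])),
                   native_multiplicity = if (nm %in% names(native))
                     native[[nm]] else 0L,
                   stringsAsFactors = FALSE)
      }))
      return(structure(list(ref = ref, regions = regions,
                            cassette_end = cassette_end,
                            length = nchar(ref)),
                       class = "donor_reference"))
    }
  }
  stop("could not orient the donor reference (uHR/dHR not uniquely located)")
}

## pad element termini to CC and re-scrub until stable (see pad_cc)
pad_and_scrub <- function(s, forbidden = c("BpiI", "BsaI", "EcoRI")) {
  for (i in 1:10) {
    s <- scrub_sites(pad_cc(s), forbidden)
    if (substr(s, 1, 2) == "CC" && substr(s, nchar(s) - 1, nchar(s)) == "CC")
      return(s)
  }
  scrub_sites(s, forbidden)
}

#' Design a donor for a landing locus of the toy genome
#'
#' End-to-end construct path: extract and scrub the homology arms at the
#' locus cut, build the empty helper plasmid, assemble the eGFP expression
#' cassette, validate it, and derive the mapping reference.
#'
#' @param genome a [make_toy_genome()] object.
#' @param locus locus name (`"PFK1"`, `"ROX1"` or `"04576"`).
#' @return list with `plasmid` (circular donor) and `ref`
#'   (a [donor_reference()]).
#' @export
design_donor <- function(genome, locus) {
  lc <- genome$loci[[locus]]
  if (is.null(lc)) stop("unknown locus: ", locus)
  arms <- extract_homology_arms(genome$chromosomes[[lc$chrom]], lc$cut,
                                arm_len = genome$config$arm_len)
  arms <- lapply(arms, pad_and_scrub)
  vec <- crbb3_vector(arms$uHR, arms$dHR, genome$elements,
                      id = paste0("crBB3_", locus))
  donor <- crbb3_assemble_cassette(vec, genome$elements$promoter,
                                   genome$elements$egfp,
                                   genome$elements$terminator)
  v <- validate_part(donor)  # EcoRI may be present; XhoI/BamHI/NotI are not
  if (nrow(v)) stop("donor failed validation: ",
                    paste(unique(v$enzyme), collapse = ", "))
  els <- c(genome$elements[c("promoter", "egfp", "terminator", "cat", "ori")],
           list(uHR = arms$uHR, dHR = arms$dHR))
  list(plasmid = donor, ref = donor_reference(donor, els))
}
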