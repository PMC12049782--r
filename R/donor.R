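#' Remove restriction sites by point mutation
#'
#' Destroys every occurrence (both strands) of the forbidden enzymes'
#' recognition sites with single-base substitutions. Outside coding
#' sequence the third base of each offending site is substituted with the
#' lexicographically smallest base that clears it (deterministic, one edit
#' per site). With `frame` given, the sequence is treated as coding from
#' that 0-based offset and only synonymous substitutions are used; codons
#' overlapping the site are tried left to right.
#'
#' @param seq [nucleic_seq()] or character string.
#' @param forbidden enzymes (names or objects) whose sites must be removed.
#' @param frame optional 0-based offset of the reading frame start; the
#'   coding stretch from there must be a whole number of codons.
#' @return scrubbed object of the same type as `seq`.
#' @export
#' @examples
#' scrub_sites("AAGAATTCAA", "EcoRI")
scrub_sites <- function(seq, forbidden, frame = NULL) {
  was_ns <- inherits(seq, "nucleic_seq")
  obj <- as_nucleic_seq(seq)
  enzs <- lapply(forbidden, as_enzyme)
  s <- obj$bases
  if (!is.null(frame)) {
    frame <- as.integer(frame)
    if ((nchar(s) - frame) %% 3 != 0)
      stop("coding scrub: length from frame start must be a multiple of 3")
  }
  guard <- 0L
  repeat {
    hit <- NULL
    for (ez in enzs) {
      h <- find_sites(nucleic_seq(s, topology = obj$topology), ez)
      if (nrow(h)) {
        h$enzyme <- ez$name
        h$len <- nchar(ez$recognition)
        hit <- if (is.null(hit)) h else rbind(hit, h)
      }
    }
    if (is.null(hit)) break
    hit <- hit[order(hit$position), , drop = FALSE][1, ]
    s <- scrub_one(s, hit$position, hit$len, enzs, frame, obj$topology)
    guard <- guard + 1L
    if (guard > nchar(s)) stop("unscrubbable: site removal did not converge")
  }
  if (was_ns) { obj$bases <- s; obj } else s
}

## clears the site whose occupied top-strand span is [pos, pos+len)
scrub_one <- function(s, pos, len, enzs, frame, topology) {
  is_clean_at <- function(cand) {
    ## window around the edited span, checked for any forbidden site
    a <- max(0L, pos - 8L); b <- min(nchar(cand), pos + len + 8L)
    win <- substr0(cand, a, b)
    for (ez in enzs)
      if (length(str_find_all(win, ez$recognition)) ||
          length(str_find_all(win, revcomp_chr(ez$recognition)))) return(FALSE)
    TRUE
  }
  if (is.null(frame)) {
    p <- pos + 2L  # third base of the occupied span
    cur <- substr0(s, p, p + 1L)
    for (b in setdiff(c("A", "C", "G", "T"), cur)) {
      cand <- s; substr(cand, p + 1L, p + 1L) <- b
      if (is_clean_at(cand)) return(cand)
    }
    ## fall back to any position within the span
    for (off in setdiff(seq_len(len) - 1L, 2L)) for (b in c("A", "C", "G", "T")) {
      p2 <- pos + off
      if (substr0(s, p2, p2 + 1L) == b) next
      cand <- s; substr(cand, p2 + 1L, p2 + 1L) <- b
      if (is_clean_at(cand)) return(cand)
    }
    stop("unscrubbable: no single substitution clears the site at ", pos)
  }
  ## synonymous repair: try codons overlapping the site, left to right
  first_codon <- max(0L, (pos - frame) %/% 3L)
  last_codon <- (pos + len - 1L - frame) %/% 3L
  gc <- Biostrings::GENETIC_CODE
  for (ci in first_codon:last_codon) {
    a <- frame + 3L * ci
    if (a < 0L || a + 3L > nchar(s)) next
    cod <- substr0(s, a, a + 3L)
    aa <- gc[[cod]]
    syn <- names(gc)[gc == aa & names(gc) != cod]
    for (alt in syn) {
      cand <- s; substr(cand, a + 1L, a + 3L) <- alt
      if (is_clean_at(cand)) return(cand)
    }
  }
  stop("unscrubbable: no synonymous substitution clears the site at ", pos)
}

#' Cas9 guide target
#'
#' A 20-nt protospacer with its NGG PAM immediately 3' on the stated strand.
#'
#' @param protospacer 20-nt sequence (as read on `strand`).
#' @param pam 3-nt PAM; must match NGG.
#' @param strand `"+"` or `"-"`.
#' @param start 0-based genomic coordinate of the protospacer start
#'   (leftmost base of its top-strand footprint).
#' @return object of class `guide_target`.
#' @export
guide_target <- function(protospacer, pam, strand = "+", start) {
  protospacer <- toupper(protospacer); pam <- toupper(pam)
  if (nchar(protospacer) != 20) stop("invalid guide: protospacer must be 20 nt")
  if (!grepl("^[ACGT]GG$", pam)) stop("invalid guide: PAM must match NGG")
  if (!strand %in% c("+", "-")) stop("invalid guide: strand must be + or -")
  structure(list(protospacer = protospacer, pam = pam, strand = strand,
                 start = as.integer(start)), class = "guide_target")
}

#' Blunt Cas9 cut coordinate
#'
#' Returns the 0-based coordinate c of the blunt double-strand break such
#' that the upstream arm is `[c - arm, c)` and the downstream arm
#' `[c, c + arm)`. SpCas9 cuts between positions 17 and 18 of the
#' protospacer, 3 nt 5' of the PAM (`offset = 3`, configurable).
#'
#' @param guide a [guide_target()].
#' @param offset nt between the cut and the PAM-proximal protospacer end.
#' @return integer cut coordinate.
#' @export
cut_site <- function(guide, offset = 3L) {
  stopifnot(inherits(guide, "guide_target"))
  if (guide$strand == "+") guide$start + 20L - offset
  else guide$start + offset
}

#' Extract homology arms around a cut site
#'
#' Slices `arm_len` nt upstream and downstream of the Cas9 cut and scrubs
#' them of the assembly and linearization sites so they can be carried on a
#' donor helper plasmid.
#'
#' @param genome [nucleic_seq()] or character chromosome sequence.
#' @param cut 0-based cut coordinate (see [cut_site()]).
#' @param arm_len arm length in nt, default 500.
#' @param scrub enzymes to scrub from the arms; `NULL` to skip.
#' @return list with character `uHR` and `dHR`.
#' @export
extract_homology_arms <- function(genome, cut, arm_len = 500L,
                                  scrub = c("BpiI", "BsaI", "EcoRI")) {
  g <- as_nucleic_seq(genome)$bases
  cut <- as.integer(cut); arm_len <- as.integer(arm_len)
  if (cut - arm_len < 0 || cut + arm_len > nchar(g))
    stop("out of range: homology arm would run off the chromosome end")
  uHR <- substr0(g, cut - arm_len, cut)
  dHR <- substr0(g, cut, cut + arm_len)
  if (!is.null(scrub)) {
    uHR <- scrub_sites(uHR, scrub)
    dHR <- scrub_sites(dHR, scrub)
  }
  list(uHR = uHR, dHR = dHR)
}

#' Reverse-translate a protein with codon usage, avoiding forbidden sites
#'
#' Default policy: pick the most frequent codon per residue, then repair
#' forbidden sites left to right by swapping the leftmost involved codon to
#' its next-most-frequent synonym.
#'
#' @param protein amino-acid string (one-letter code, optional trailing `*`).
#' @param usage named numeric vector of codon frequencies (names are codons);
#'   defaults to a bundled approximate Komagataella phaffii usage table.
#' @param forbidden enzymes whose sites must not appear; `character(0)` for
#'   a pure argmax-usage sequence.
#' @return a [nucleic_seq()] coding sequence; its translation equals
#'   `protein`.
#' @export
codon_optimize <- function(protein, usage = kp_codon_usage(),
                           forbidden = c("BpiI", "BsaI", "EcoRI", "XhoI",
                                         "BamHI", "NotI")) {
  protein <- toupper(protein)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY*]", protein))
    stop("protein must use the 20 one-letter codes plus optional '*'")
  gc <- Biostrings::GENETIC_CODE
  ## per-residue codon ranking by usage (desc), ties broken alphabetically
  rank_for <- function(aa) {
    cods <- names(gc)[gc == aa]
    u <- usage[cods]; u[is.na(u)] <- 0
    cods[order(-u, cods)]
  }
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  ranks <- lapply(aas, rank_for)
  choice <- rep(1L, length(aas))
  build <- function() paste(mapply(function(r, i) r[i], ranks, choice),
                            collapse = "")
  enzs <- lapply(forbidden, as_enzyme)
  s <- build()
  guard <- 0L
  repeat {
    hit <- NULL
    for (ez in enzs) {
      for (pat in unique(c(ez$recognition, revcomp_chr(ez$recognition)))) {
        p <- str_find_all(s, pat)
        if (length(p)) {
          h <- data.frame(position = p, len = nchar(pat))
          hit <- if (is.null(hit)) h else rbind(hit, h)
        }
      }
    }
    if (is.null(hit)) break
    hit <- hit[order(hit$position), , drop = FALSE][1, ]
    cods <- (hit$position %/% 3L):((hit$position + hit$len - 1L) %/% 3L)
    cods <- cods[cods >= 0 & cods < length(aas)]
    repaired <- FALSE
    for (ci in cods) {
      if (choice[ci + 1L] < length(ranks[[ci + 1L]])) {
        choice[ci + 1L] <- choice[ci + 1L] + 1L
        repaired <- TRUE
        break
      }
    }
    if (!repaired)
      stop("unscrubbable: forbidden site at ", hit$position,
           " cannot be removed by synonym swaps")
    s <- build()
    guard <- guard + 1L
    if (guard > 10L * length(aas)) stop("unscrubbable: repair did not converge")
  }
  out <- nucleic_seq(s, id = "codon_optimized")
  attr(out, "protein") <- protein
  out
}

#' Translate a coding sequence
#'
#' @param x [nucleic_seq()] or character coding sequence (length multiple
#'   of 3).
#' @return amino-acid string (stop codons as `*`).
#' @export
translate_cds <- function(x) {
  s <- as_nucleic_seq(x)$bases
  if (nchar(s) %% 3 != 0) stop("coding sequence length must be a multiple of 3")
  gc <- Biostrings::GENETIC_CODE
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  paste(gc[cods], collapse = "")
}

#' Approximate K. phaffii codon usage
#'
#' A bundled, approximate codon-frequency table (relative frequencies per
#' amino acid) reflecting the strong A/T-ending codon preference typical of
#' this yeast. Adequate for deterministic reverse translation; supply your
#' own table for production designs.
#'
#' @return named numeric vector over the 64 codons.
#' @export
kp_codon_usage <- function() {
  gc <- Biostrings::GENETIC_CODE
  ## preferred codon per residue (yeast-like); others get geometrically
  ## decreasing weight in alphabetical order
  pref <- c(A = "GCT", R = "AGA", N = "AAC", D = "GAC", C = "TGT", Q = "CAA",
            E = "GAA", G = "GGT", H = "CAC", I = "ATT", L = "TTG", K = "AAG",
            M = "ATG", F = "TTC", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
            Y = "TAC", V = "GTT", `*` = "TAA")
  out <- numeric(0)
  for (aa in unique(gc)) {
    cods <- sort(names(gc)[gc == aa])
    w <- 0.6 * 0.5^(seq_along(cods) - 1L)
    names(w) <- cods
    if (aa %in% names(pref)) {
      w <- w[order(names(w) != pref[[aa]], names(w))]
      w[] <- sort(w, decreasing = TRUE)
    }
    out <- c(out, w / sum(w))
  }
  out
}

#' Linearize a plasmid
#'
#' Opens a circular plasmid with a single-cutter palindromic enzyme. Both
#' cohesive ends of the product carry the enzyme's overhang (AATT for
#' EcoRI). With more than one site the full multi-fragment digest is
#' returned, flagged via attribute `multi_fragment`.
#'
#' @param plasmid circular [nucleic_seq()].
#' @param enz palindromic enzyme, default EcoRI.
#' @return linear [nucleic_seq()] (or flagged list of fragments).
#' @export
linearize <- function(plasmid, enz = "EcoRI") {
  plasmid <- as_nucleic_seq(plasmid)
  enz <- as_enzyme(enz)
  if (plasmid$topology != "circular") stop("linearize expects a circular plasmid")
  n <- nrow(find_sites(plasmid, enz))
  if (n == 0) stop("cannot linearize: no ", enz$name, " site on the plasmid")
  frags <- digest(plasmid, enz)
  if (n == 1) return(frags[[1]])
  attr(frags, "multi_fragment") <- TRUE
  warning("linearize: ", n, " ", enz$name, " sites; returning all fragments")
  frags
}
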