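#' Restriction enzyme definitions
#'
#' Two enzyme flavours are modelled. Type IIS enzymes cut at a fixed spacer
#' downstream of a non-palindromic recognition site, leaving a designer 4-nt
#' 5' overhang (the "fusion site" of Golden Gate assembly). Palindromic
#' enzymes cut inside their site at a fixed offset from the recognition
#' start, leaving a sequence-determined overhang (EcoRI: G^AATTC -> AATT).
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (top strand).
#' @param spacer nt between recognition end and the top-strand cut.
#' @param overhang_len overhang length (4 for the enzymes used here).
#' @param cut_offset for palindromic enzymes, nt from recognition start to
#'   the top-strand cut.
#' @return an object of class `type_iis_enzyme` or `palindromic_enzyme`
#'   (both inherit from `restriction_enzyme`).
#' @export
#' @examples
#' enzyme("BsaI")
#' enzyme("EcoRI")
type_iis_enzyme <- function(name, recognition, spacer, overhang_len = 4L) {
  recognition <- toupper(recognition)
  if (revcomp_chr(recognition) == recognition)
    stop("type IIs recognition sites are non-palindromic")
  structure(list(name = name, recognition = recognition,
                 spacer = as.integer(spacer),
                 overhang_len = as.integer(overhang_len)),
            class = c("type_iis_enzyme", "restriction_enzyme"))
}

#' @rdname type_iis_enzyme
#' @export
palindromic_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (revcomp_chr(recognition) != recognition)
    stop("recognition site must be palindromic")
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset),
                 overhang_len = nchar(recognition) - 2L * as.integer(cut_offset)),
            class = c("palindromic_enzyme", "restriction_enzyme"))
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<%s %s: %s>\n", class(x)[1], x$name, x$recognition))
  invisible(x)
}

enzyme_table <- function() {
  list(
    BsaI  = type_iis_enzyme("BsaI",  "GGTCTC", spacer = 1L),
    BpiI  = type_iis_enzyme("BpiI",  "GAAGAC", spacer = 2L),
    BbsI  = type_iis_enzyme("BbsI",  "GAAGAC", spacer = 2L),  # isoschizomer of BpiI
    EcoRI = palindromic_enzyme("EcoRI", "GAATTC", cut_offset = 1L),
    XhoI  = palindromic_enzyme("XhoI",  "CTCGAG", cut_offset = 1L),
    BamHI = palindromic_enzyme("BamHI", "GGATCC", cut_offset = 1L),
    NotI  = palindromic_enzyme("NotI",  "GCGGCCGC", cut_offset = 2L)
  )
}

#' Built-in enzymes
#'
#' Look up one of the bundled enzymes by name: BsaI, BpiI (= BbsI), EcoRI,
#' XhoI, BamHI, NotI.
#'
#' @param name enzyme name (case-insensitive).
#' @return a `restriction_enzyme`.
#' @export
enzyme <- function(name) {
  tab <- enzyme_table()
  hit <- match(tolower(name), tolower(names(tab)))
  if (is.na(hit)) stop("unknown enzyme: ", name)
  tab[[hit]]
}

as_enzyme <- function(x) if (inherits(x, "restriction_enzyme")) x else enzyme(x)

#' Locate recognition sites
#'
#' Scans both strands for occurrences of the recognition sequence. Circular
#' molecules are scanned across the origin using the doubled-string trick.
#' For palindromic enzymes a site matches both strands at the same position
#' and is reported once, on the plus strand.
#'
#' @param seq a [nucleic_seq()] or character string (treated as linear).
#' @param enz a [enzyme()] object or name.
#' @return data.frame with 0-based top-strand `position` of the recognition
#'   start and `strand` (`"+"`/`"-"`).
#' @export
#' @examples
#' find_sites("GGTCTCAAAAA", "BsaI")
find_sites <- function(seq, enz) {
  seq <- as_nucleic_seq(seq)
  enz <- as_enzyme(enz)
  s <- seq$bases
  L <- nchar(s)
  rec <- enz$recognition
  k <- nchar(rec)
  subject <- if (seq$topology == "circular" && L >= 2)
    paste0(s, substr(s, 1, min(k - 1L, L))) else s
  pos_f <- str_find_all(subject, rec)
  hits <- data.frame(position = pos_f,
                     strand = rep("+", length(pos_f)),
                     stringsAsFactors = FALSE)
  rc <- revcomp_chr(rec)
  if (rc != rec) {
    pos_r <- str_find_all(subject, rc)
    hits <- rbind(hits, data.frame(position = pos_r,
                                   strand = rep("-", length(pos_r)),
                                   stringsAsFactors = FALSE))
  }
  hits <- hits[hits$position < L, , drop = FALSE]
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

## Cut geometry for one site: returns c(top, bottom) 0-based cut coordinates
## (may exceed [0, L) on circular molecules; caller wraps).
cut_coords <- function(enz, position, strand) {
  k <- nchar(enz$recognition)
  if (inherits(enz, "type_iis_enzyme")) {
    if (strand == "+") {
      top <- position + k + enz$spacer
      c(top = top, bottom = top + enz$overhang_len)
    } else {
      top <- position - enz$spacer - enz$overhang_len
      c(top = top, bottom = top + enz$overhang_len)
    }
  } else {
    top <- position + enz$cut_offset
    c(top = top, bottom = position + k - enz$cut_offset)
  }
}

#' Digest a molecule
#'
#' Cuts at every site of `enz`. Each junction is labelled by the top-strand
#' 4-mer spanning the staggered cut; the fragment that carries the junction
#' 4-mer at its left end "owns" it, so fragment lengths sum to the parent
#' length. A circular molecule with n sites yields n linear fragments; a
#' linear molecule with n sites yields n + 1.
#'
#' @inheritParams find_sites
#' @return list of linear [nucleic_seq()] fragments, ordered along the top
#'   strand starting from the first cut.
#' @export
#' @examples
#' frags <- digest(nucleic_seq("AAGAATTCTTAAGAATTCTT", topology = "circular"),
#'                 "EcoRI")
#' vapply(frags, function(f) f$left_end, character(1))
digest <- function(seq, enz) {
  seq <- as_nucleic_seq(seq)
  enz <- as_enzyme(enz)
  s <- seq$bases
  L <- nchar(s)
  sites <- find_sites(seq, enz)
  if (nrow(sites) == 0) return(list(seq))

  cuts <- t(mapply(function(p, st) cut_coords(enz, p, st),
                   sites$position, sites$strand))
  ohl <- enz$overhang_len
  if (seq$topology == "linear") {
    if (any(cuts[, "top"] < 0 | cuts[, "bottom"] > L))
      stop("degenerate cut: cut coordinate outside the linear molecule")
    ord <- order(cuts[, "top"])
    tops <- cuts[ord, "top"]
    labels <- vapply(tops, function(tc) substr0(s, tc, tc + ohl), character(1))
    bounds <- c(0L, tops, L)
    out <- vector("list", length(tops) + 1L)
    for (i in seq_along(out)) {
      left_lab <- if (i == 1L) seq$left_end else labels[i - 1L]
      right_lab <- if (i == length(out)) seq$right_end else labels[i]
      out[[i]] <- nucleic_seq(substr0(s, bounds[i], bounds[i + 1L]),
                              id = sprintf("%s_frag%d", seq$id, i),
                              left_end = left_lab, right_end = right_lab)
    }
    out
  } else {
    tops <- sort(unique(((cuts[, "top"] %% L) + L) %% L))
    labels <- vapply(tops, function(tc) {
      if (tc + ohl <= L) substr0(s, tc, tc + ohl)
      else paste0(substr0(s, tc, L), substr0(s, 0, tc + ohl - L))
    }, character(1))
    n <- length(tops)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      from <- tops[i]
      to <- if (i < n) tops[i + 1L] else tops[1L]
      frag <- if (i < n) substr0(s, from, to)
              else paste0(substr0(s, from, L), substr0(s, 0, to))
      out[[i]] <- nucleic_seq(frag, id = sprintf("%s_frag%d", seq$id, i),
                              left_end = labels[i],
                              right_end = labels[if (i < n) i + 1L else 1L])
    }
    out
  }
}
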