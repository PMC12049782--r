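#' DNA molecules with cohesive-end labels
#'
#' `nucleic_seq` is the universal currency of the construct module: a linear
#' or circular double-stranded DNA molecule represented by its top strand.
#' Linear molecules may carry 4-nt cohesive-end labels, the top-strand 5'->3'
#' junction 4-mer left by a staggered cut. Two ends can ligate iff one is a
#' right end and the other a left end with an identical label.
#'
#' @param bases top-strand sequence over A/C/G/T/N.
#' @param id molecule identifier.
#' @param topology `"linear"` or `"circular"`.
#' @param left_end,right_end optional 4-nt cohesive-end labels; only allowed
#'   on linear molecules.
#' @return an object of class `nucleic_seq`.
#' @export
#' @examples
#' frag <- nucleic_seq("AATTCGGG", left_end = "AATT")
#' revcomp(frag)
nucleic_seq <- function(bases, id = "seq", topology = c("linear", "circular"),
                        left_end = NULL, right_end = NULL) {
  topology <- match.arg(topology)
  bases <- toupper(bases)
  if (!nzchar(bases)) stop("nucleic_seq: bases must be non-empty")
  if (grepl("[^ACGTN]", bases))
    stop("nucleic_seq: bases restricted to A/C/G/T/N")
  if (topology == "circular" && (!is.null(left_end) || !is.null(right_end)))
    stop("nucleic_seq: circular molecules have no end labels")
  for (e in list(left_end, right_end))
    if (!is.null(e) && (nchar(e) < 1 || grepl("[^ACGT]", e)))
      stop("nucleic_seq: end labels must be short ACGT strings")
  structure(list(id = id, bases = bases, topology = topology,
                 left_end = left_end, right_end = right_end),
            class = "nucleic_seq")
}

#' @export
print.nucleic_seq <- function(x, ...) {
  n <- nchar(x$bases)
  ends <- if (x$topology == "linear")
    sprintf(" [%s|%s]", x$left_end %||% "-", x$right_end %||% "-") else ""
  preview <- if (n > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(sprintf("<nucleic_seq %s: %s, %d nt%s>\n  %s\n",
              x$id, x$topology, n, ends, preview))
  invisible(x)
}

#' @export
length.nucleic_seq <- function(x) nchar(x$bases)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement
#'
#' For a linear molecule the end labels swap sides and are themselves
#' reverse-complemented, so that ligation compatibility is preserved.
#'
#' @param x a `nucleic_seq` or character string.
#' @return object of the same type as `x`.
#' @export
revcomp <- function(x) UseMethod("revcomp")

#' @export
revcomp.character <- function(x) revcomp_chr(x)

#' @export
revcomp.nucleic_seq <- function(x) {
  nucleic_seq(revcomp_chr(x$bases), id = x$id, topology = x$topology,
              left_end = if (!is.null(x$right_end)) revcomp_chr(x$right_end),
              right_end = if (!is.null(x$left_end)) revcomp_chr(x$left_end))
}

#' Equality of molecules
#'
#' Linear molecules compare by string identity (plus end labels); circular
#' molecules compare by their canonical (lexicographically minimal) rotation,
#' so equality is rotation-invariant.
#'
#' @param a,b `nucleic_seq` objects.
#' @return logical.
#' @export
seq_identical <- function(a, b) {
  if (a$topology != b$topology) return(FALSE)
  if (a$topology == "circular")
    return(canonical_rotation(a$bases) == canonical_rotation(b$bases))
  identical(a$bases, b$bases) &&
    identical(a$left_end %||% "", b$left_end %||% "") &&
    identical(a$right_end %||% "", b$right_end %||% "")
}

as_nucleic_seq <- function(x, ...) {
  if (inherits(x, "nucleic_seq")) x else nucleic_seq(x, ...)
}
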