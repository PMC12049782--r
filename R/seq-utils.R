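## Low-level string/DNA helpers shared by all modules.
## Coordinates are 0-based, half-open, top strand throughout the package.

#' Reverse complement of a DNA string
#'
#' Operates on plain character vectors over the alphabet A/C/G/T/N.
#' For [nucleic_seq] objects use [revcomp()].
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp_chr("GAATTC")  # palindromic: "GAATTC"
revcomp_chr <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## 0-based, half-open substring: substr0(s, a, b) == s[a, b)
substr0 <- function(s, from, to) substr(s, from + 1L, to)

## fast seeded random DNA (uppercase)
random_dna <- function(n) {
  stopifnot(n >= 0)
  if (n == 0) return("")
  idx <- sample.int(4L, n, replace = TRUE)
  rawToChar(charToRaw("ACGT")[idx])
}

## Fix both termini of an element to "CC". Every enzyme site handled by the
## construct module contains a G in any spanning window, so CC|CC junctions
## between concatenated elements cannot create a new recognition site.
pad_cc <- function(s) {
  n <- nchar(s)
  if (n < 4) return(s)
  substr(s, 1, 2) <- "CC"
  substr(s, n - 1, n) <- "CC"
  s
}

## Evaluate expr with a temporary RNG state seeded by `seed`,
## restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## rotate a circular sequence string so that 0-based position `at` comes first
rotate_str <- function(s, at) {
  n <- nchar(s)
  at <- ((at %% n) + n) %% n
  if (at == 0) return(s)
  paste0(substr0(s, at, n), substr0(s, 0, at))
}

#' Canonical rotation of a circular sequence
#'
#' Lexicographically minimal rotation, used for rotation-invariant equality
#' of circular molecules.
#'
#' @param s a DNA string.
#' @return the minimal rotation of `s`.
#' @export
canonical_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1) return(s)
  rots <- vapply(seq_len(n) - 1L, function(i) rotate_str(s, i), character(1))
  sort(rots)[1]
}

## All 0-based start positions of fixed `pattern` in `subject`.
str_find_all <- function(subject, pattern) {
  if (nchar(pattern) == 0 || nchar(subject) < nchar(pattern)) return(integer(0))
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

## Count occurrences of pattern on either strand of subject.
count_both_strands <- function(subject, pattern) {
  n <- length(str_find_all(subject, pattern))
  rc <- revcomp_chr(pattern)
  if (rc != pattern) n <- n + length(str_find_all(subject, rc))
  n
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings for multi-record FASTA files; sequences
#' travel as named character vectors inside this package.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
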