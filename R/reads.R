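#' Simulate uniform paired-end reads from a clone genome
#'
#' Read-pair start positions are uniform over each clone chromosome
#' (2x300 bp MiSeq-style pairs by default); the simulator records every
#' read's true origin, so depth can be computed exactly without an aligner.
#' Substitution errors only; no indels.
#'
#' @param clone a [apply_structure()] result.
#' @param depth target mean depth, default 50.
#' @param read_len read length, default 300.
#' @param insert_size outer fragment length, default 650.
#' @param error_rate per-base substitution probability, default 0.
#' @param seed integer seed.
#' @param with_sequences materialize read sequences (needed for FASTQ
#'   export); positions-only mode is faster for depth work.
#' @return object of class `read_set`: data.frame `pairs` (chrom, 0-based
#'   half-open mate spans) plus parameters; `mate1`/`mate2` sequence
#'   vectors when requested.
#' @export
simulate_reads <- function(clone, depth = 50, read_len = 300L,
                           insert_size = 650L, error_rate = 0,
                           seed = 1L, with_sequences = FALSE) {
  stopifnot(inherits(clone, "sim_clone"))
  read_len <- as.integer(read_len)
  pairs <- with_seed(seed, {
    out <- lapply(names(clone$chromosomes), function(nm) {
      L <- nchar(clone$chromosomes[[nm]])
      if (read_len > L) stop("read length exceeds chromosome ", nm)
      ins <- min(insert_size, L)
      n_pairs <- max(1L, round(L * depth / (2 * read_len)))
      s <- sample.int(L - ins + 1L, n_pairs, replace = TRUE) - 1L
      data.frame(chrom = nm, start1 = s, end1 = s + read_len,
                 start2 = s + ins - read_len, end2 = s + ins,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  rs <- structure(list(pairs = pairs, depth = depth, read_len = read_len,
                       insert_size = insert_size, error_rate = error_rate,
                       seed = seed),
                  class = "read_set")
  if (with_sequences) {
    rs <- with_seed(seed + 104729L, {  # separate stream for bases/errors
      rs$mate1 <- extract_reads(clone, pairs$chrom, pairs$start1, pairs$end1,
                                FALSE, error_rate)
      rs$mate2 <- extract_reads(clone, pairs$chrom, pairs$start2, pairs$end2,
                                TRUE, error_rate)
      rs
    })
  }
  rs
}

extract_reads <- function(clone, chrom, start0, end0, rc, error_rate) {
  out <- character(length(chrom))
  for (nm in unique(chrom)) {
    i <- chrom == nm
    out[i] <- substring(clone$chromosomes[[nm]], start0[i] + 1L, end0[i])
  }
  if (rc) out <- revcomp_chr(out)
  if (error_rate > 0) {
    rl <- nchar(out[1])
    n_err <- stats::rbinom(1L, length(out) * rl, error_rate)
    if (n_err > 0) {
      at_read <- sample.int(length(out), n_err, replace = TRUE)
      at_pos <- sample.int(rl, n_err, replace = TRUE)
      for (k in seq_len(n_err)) {
        cur <- substr(out[at_read[k]], at_pos[k], at_pos[k])
        sub <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        substr(out[at_read[k]], at_pos[k], at_pos[k]) <- sub
      }
    }
  }
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set: %d pairs, 2x%d nt, target %gx, seed %d%s>\n",
              nrow(x$pairs), x$read_len, x$depth, x$seed,
              if (is.null(x$mate1)) " (positions only)" else ""))
  invisible(x)
}

#' Write a read set as paired FASTQ
#'
#' @param reads a [simulate_reads()] result with sequences.
#' @param prefix output prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @return the two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  if (is.null(reads$mate1))
    stop("read set has no sequences; rerun simulate_reads(with_sequences = TRUE)")
  ids <- sprintf("read%07d", seq_len(nrow(reads$pairs)))
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    seqs <- if (m == 1) reads$mate1 else reads$mate2
    q <- strrep("I", reads$read_len)
    writeLines(paste0("@", ids, "/", m, "\n", seqs, "\n+\n", q), paths[m])
  }
  invisible(paths)
}

#' Exact depth tracks for a simulated clone
#'
#' Computes per-position depth over the mapping references (wild-type
#' chromosomes plus the donor-plasmid reference) from the clone's
#' projection blocks. `"reads"` mode counts true-origin overlap of a
#' [simulate_reads()] set; `"analytic"` mode uses the expected uniform
#' profile (constant target depth with linear edge ramps of length
#' `read_len - 1` at chromosome ends).
#'
#' @param clone a [apply_structure()] result.
#' @param reads a `read_set` (reads mode).
#' @param target target depth (analytic mode).
#' @param read_len read length (analytic mode), default 300.
#' @param mode `"reads"` or `"analytic"`.
#' @return named list of [depth_track()] objects, one per reference.
#' @export
exact_depth <- function(clone, reads = NULL, target = 50, read_len = 300L,
                        mode = c("reads", "analytic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(clone, "sim_clone"))
  clone_depth <- lapply(names(clone$chromosomes), function(nm) {
    L <- nchar(clone$chromosomes[[nm]])
    if (mode == "analytic") {
      pos <- seq_len(L)
      pmin(1, pos / read_len, (L - pos + 1L) / read_len) * target
    } else {
      p <- reads$pairs[reads$pairs$chrom == nm, ]
      starts <- c(p$start1, p$start2) + 1L
      ends <- pmin(c(p$end1, p$end2), L)
      delta <- numeric(L + 1L)
      tab_s <- tabulate(starts, nbins = L)
      tab_e <- tabulate(ends + 1L, nbins = L + 1L)
      cumsum(tab_s - tab_e[seq_len(L)])
    }
  })
  names(clone_depth) <- names(clone$chromosomes)

  refd <- lapply(clone$ref_lengths, numeric)
  b <- clone$blocks
  for (i in seq_len(nrow(b))) {
    seg <- clone_depth[[b$clone_chrom[i]]][(b$clone_start[i] + 1L):
                                             (b$clone_start[i] + b$len[i])]
    if (b$strand[i] == "-") seg <- rev(seg)
    idx <- (b$src[i] + 1L):(b$src[i] + b$len[i])
    refd[[b$ref[i]]][idx] <- refd[[b$ref[i]]][idx] + seg
  }
  out <- lapply(names(refd), function(nm) depth_track(nm, refd[[nm]]))
  names(out) <- names(refd)
  out
}
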