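#' Detect terminal chromosome loss from a depth track
#'
#' Scans both ends of a chromosome for the longest terminal run of
#' positions with normalized depth at or below `zero_eps` and reports it
#' when it reaches `min_run` positions, together with the annotation
#' features that fall entirely inside the lost span. An interior
#' zero-coverage gap is not terminal loss and is ignored.
#'
#' @param track normalized [depth_track()] of one chromosome.
#' @param annotation annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, 0-based half-open), e.g. from [make_toy_genome()] or
#'   [read_annotation()].
#' @param genome_length total genome length in nt (for the lost-genome
#'   fraction); `NA` to skip.
#' @param zero_eps normalized-depth tolerance for "zero" coverage,
#'   default 0.02 (stray simulated or mismapped reads).
#' @param min_run minimal run length to report, default 1000 nt.
#' @return an `end_loss_report` (list) or `NULL` when no terminal loss is
#'   found. Fields: `chromosome`, `end` (`"left"`/`"right"`),
#'   `breakpoint` (0-based; lost span is `[breakpoint, L)` for the right
#'   end, `[0, breakpoint)` for the left), `lost_length`,
#'   `lost_chrom_pct`, `lost_genome_pct`, `lost_genes`.
#' @export
detect_terminal_loss <- function(track, annotation = NULL,
                                 genome_length = NA_real_,
                                 zero_eps = 0.02, min_run = 1000L) {
  if (track$state != "normalized")
    stop("detect_terminal_loss requires a normalized track")
  d <- track$depth
  L <- length(d)
  low <- d <= zero_eps
  run_right <- if (low[L]) L - max(which(!low), 0L) else 0L
  run_left <- if (low[1]) {
    first_hi <- which(!low)
    if (length(first_hi)) first_hi[1] - 1L else L
  } else 0L
  if (max(run_left, run_right) < min_run) return(NULL)
  if (run_right >= run_left) {
    end <- "right"; lost_len <- run_right
    span <- c(L - lost_len, L)
    breakpoint <- span[1]
  } else {
    end <- "left"; lost_len <- run_left
    span <- c(0L, lost_len)
    breakpoint <- span[2]
  }
  lost_genes <- character(0)
  if (!is.null(annotation)) {
    a <- annotation[annotation$chrom == track$reference, , drop = FALSE]
    inside <- a$start >= span[1] & a$end <= span[2]
    lost_genes <- a$gene_id[inside]
  }
  structure(list(chromosome = track$reference, end = end,
                 breakpoint = as.integer(breakpoint),
                 lost_length = as.integer(lost_len),
                 lost_chrom_pct = 100 * lost_len / L,
                 lost_genome_pct = if (is.na(genome_length)) NA_real_
                                   else 100 * lost_len / genome_length,
                 lost_genes = lost_genes),
            class = "end_loss_report")
}

#' @export
print.end_loss_report <- function(x, ...) {
  cat(sprintf(
    "Terminal loss on %s (%s end): %d nt lost (%.2f%% of chromosome%s)\n",
    x$chromosome, x$end, x$lost_length, x$lost_chrom_pct,
    if (is.na(x$lost_genome_pct)) ""
    else sprintf(", %.2f%% of genome", x$lost_genome_pct)))
  if (length(x$lost_genes))
    cat("  lost features:", paste(x$lost_genes, collapse = ", "), "\n")
  invisible(x)
}
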