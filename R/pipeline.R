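#' Pipeline run configuration
#'
#' Bundles every tunable of the simulate-and-verify demonstration pipeline.
#' The default clone set mirrors a nine-clone WGS verification panel:
#' for each of the three landing loci one single-copy (low fluorescence),
#' one medium and one strong clone, with multi-copy architectures that
#' include tandem head-to-tail cassettes, backbone-fragment inclusions in
#' all three junction orientations, and one terminal-deletion clone at the
#' ROX1-like locus.
#'
#' @param seed master seed; every stage derives its stream from it.
#' @param preset toy-genome preset (`"full"` or `"mini"`).
#' @param depth target read depth, default 50.
#' @param read_len read length, default 300.
#' @param insert_size read-pair outer distance, default 650.
#' @param error_rate substitution error rate, default 0.
#' @param zero_eps,min_run terminal-loss detector settings.
#' @param kmer junction anchor k-mer size, default 40.
#' @param rfu_threshold,od_min plate-assay settings.
#' @param clones optional list of clone specs (`id`, `locus`, `segments`
#'   data.frame, `distal_loss`); `NULL` for the default nine-clone panel.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, preset = "full", depth = 50,
                       read_len = 300L, insert_size = 650L, error_rate = 0,
                       zero_eps = 0.02, min_run = 1000L, kmer = 40L,
                       rfu_threshold = 600, od_min = 1.0, clones = NULL) {
  cfg <- list(seed = as.integer(seed), preset = preset, depth = depth,
              read_len = as.integer(read_len),
              insert_size = as.integer(insert_size),
              error_rate = error_rate, zero_eps = zero_eps,
              min_run = as.integer(min_run), kmer = as.integer(kmer),
              rfu_threshold = rfu_threshold, od_min = od_min,
              clones = clones %||% default_clone_panel())
  class(cfg) <- "run_config"
  cfg
}

seg_df <- function(spec) {
  ## "+cassette,+cassette,-backbone" -> data.frame(kind, orientation)
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  data.frame(kind = sub("^[+-]", "", parts),
             orientation = substr(parts, 1, 1), stringsAsFactors = FALSE)
}

seg_str <- function(segments)
  paste0(segments$orientation, segments$kind, collapse = ",")

default_clone_panel <- function() {
  spec <- list(
    list(id = "04576_37", locus = "04576", level = "low",
         segments = "+cassette", distal_loss = FALSE),
    list(id = "04576_38", locus = "04576", level = "medium",
         segments = paste(rep("+cassette", 5), collapse = ","),
         distal_loss = FALSE),
    list(id = "04576_35", locus = "04576", level = "strong",
         segments = paste(c(rep("+cassette", 7), "+backbone", "-backbone",
                            rep("+cassette", 7)), collapse = ","),
         distal_loss = FALSE),
    list(id = "PFK1_21", locus = "PFK1", level = "low",
         segments = "+cassette", distal_loss = FALSE),
    list(id = "PFK1_66", locus = "PFK1", level = "medium",
         segments = "+cassette,+cassette", distal_loss = FALSE),
    list(id = "PFK1_72", locus = "PFK1", level = "strong",
         segments = "+cassette,+cassette,+backbone,-backbone,-cassette",
         distal_loss = FALSE),
    list(id = "ROX1_97", locus = "ROX1", level = "low",
         segments = "+cassette", distal_loss = FALSE),
    list(id = "ROX1_87", locus = "ROX1", level = "medium",
         segments = "+cassette,+cassette", distal_loss = TRUE),
    list(id = "ROX1_96", locus = "ROX1", level = "strong",
         segments = paste(c(rep("+cassette", 8), "+backbone", "+backbone"),
                          collapse = ","), distal_loss = FALSE))
  lapply(spec, function(x) { x$segments <- seg_df(x$segments); x })
}

#' Write / read a run configuration as a flat key-value file
#'
#' Round-trips exactly: `read_run_config(write_run_config(cfg, f))` equals
#' `cfg`.
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  scal <- cfg[setdiff(names(cfg), "clones")]
  lines <- c("# knockin run configuration v1",
             sprintf("%s = %s", names(scal),
                     vapply(scal, function(v) format(v, digits = 15),
                            character(1))))
  for (cl in cfg$clones)
    lines <- c(lines, sprintf("clone.%s = %s;%s;%d", cl$id, cl$locus,
                              seg_str(cl$segments), as.integer(cl$distal_loss)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  is_clone <- startsWith(keys, "clone.")
  args <- as.list(vals[!is_clone])
  names(args) <- keys[!is_clone]
  num <- c("seed", "depth", "read_len", "insert_size", "error_rate",
           "zero_eps", "min_run", "kmer", "rfu_threshold", "od_min")
  for (k in intersect(num, names(args))) args[[k]] <- as.numeric(args[[k]])
  clones <- lapply(which(is_clone), function(i) {
    f <- strsplit(vals[i], ";", fixed = TRUE)[[1]]
    list(id = sub("^clone\\.", "", keys[i]), locus = f[1],
         segments = seg_df(f[2]), distal_loss = f[3] == "1")
  })
  if (length(clones)) args$clones <- clones
  do.call(run_config, args)
}

#' Run the simulate-and-verify pipeline
#'
#' End-to-end demonstration: builds the toy genome, designs one donor per
#' locus via Golden Gate assembly, simulates every configured clone with
#' truth-based reads, and verifies each from its depth tracks (copy-number
#' report against the locus's single-copy calibrator, junction
#' classification of truth contigs, backbone detection, terminal-loss
#' scan, QC metrics). Deterministic per seed.
#'
#' @param cfg a [run_config()].
#' @param outdir optional directory for TSV/JSON reports.
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_report`: `copy_table`,
#'   `junction_table`, `end_loss`, `qc_table`, `backbone`, plus the
#'   `genome` and per-locus `donors`.
#' @export
run_pipeline <- function(cfg = run_config(), outdir = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  genome <- make_toy_genome(toy_genome_config(cfg$preset), seed = cfg$seed)
  say(sprintf("[genome] %d chromosomes, %.2f Mb", length(genome$chromosomes),
              sum(nchar(genome$chromosomes)) / 1e6))
  loci <- unique(vapply(cfg$clones, function(x) x$locus, character(1)))
  donors <- lapply(loci, function(lc) design_donor(genome, lc))
  names(donors) <- loci
  say(sprintf("[construct] %d donor plasmid(s) assembled and validated",
              length(donors)))

  copy_rows <- list(); junc_rows <- list(); qc_rows <- list()
  end_loss <- list(); backbone <- list()
  calib_mean <- list()

  ## calibrators (single-copy clones) first, then the rest
  is_single <- vapply(cfg$clones, function(cl)
    nrow(cl$segments) == 1 && cl$segments$kind == "cassette", logical(1))
  order_idx <- c(which(is_single), which(!is_single))

  for (ci in order_idx) {
    cl <- cfg$clones[[ci]]
    donor <- donors[[cl$locus]]
    st <- clone_structure(cl$locus, cl$segments,
                          distal_loss = cl$distal_loss, id = cl$id)
    clone <- apply_structure(genome, donor, st)
    reads <- simulate_reads(clone, depth = cfg$depth,
                            read_len = cfg$read_len,
                            insert_size = cfg$insert_size,
                            error_rate = cfg$error_rate,
                            seed = cfg$seed + 1000L * ci)
    tracks <- exact_depth(clone, reads = reads, mode = "reads")
    ntr <- normalize_tracks(tracks, clone$genome_refs)

    regions <- donor_regions(donor$ref)
    egfp_reg <- regions[[which(vapply(regions, function(r) r$name, character(1)) == "egfp")]]
    own_egfp <- region_mean(ntr$plasmid, egfp_reg)
    if (is_single[ci]) calib_mean[[cl$locus]] <- own_egfp
    cm <- calib_mean[[cl$locus]] %||% own_egfp
    rep <- copy_number_report(ntr, regions, cm, clone_id = cl$id)
    copy_rows[[cl$id]] <- as.data.frame(rep)

    jc <- scan_contigs(truth_contigs(clone), donor_catalog(donor$ref, cfg$kmer))
    if (nrow(jc)) jc$clone <- cl$id
    junc_rows[[cl$id]] <- jc
    backbone[[cl$id]] <- detect_backbone(rep, jc)$present

    for (nm in clone$genome_refs) {
      el <- detect_terminal_loss(ntr[[nm]], genome$annotation,
                                 genome_length = sum(nchar(genome$chromosomes)),
                                 zero_eps = cfg$zero_eps,
                                 min_run = cfg$min_run)
      if (!is.null(el)) {
        el$clone <- cl$id
        end_loss[[paste(cl$id, nm)]] <- el
      }
    }
    q <- qc_metrics(tracks)
    q$clone <- cl$id
    qc_rows[[cl$id]] <- q
    say(sprintf("[clone %s] eGFP call %d%s", cl$id,
                rep$copies_cassette[rep$region == "egfp"],
                if (cl$distal_loss) " (terminal loss simulated)" else ""))
  }

  empty_copy <- data.frame(clone = character(0), region = character(0),
                           mean_normalized_coverage = numeric(0),
                           relative_to_egfp = numeric(0),
                           copies_genome = integer(0),
                           copies_cassette = integer(0),
                           low_confidence = logical(0))
  out <- structure(list(
    copy_table = if (length(copy_rows)) do.call(rbind, copy_rows) else empty_copy,
    junction_table = do.call(rbind, junc_rows),
    end_loss = end_loss,
    qc_table = do.call(rbind, qc_rows),
    backbone = unlist(backbone),
    genome = genome, donors = donors, config = cfg,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_report")
  rownames(out$copy_table) <- NULL
  if (!is.null(out$junction_table)) rownames(out$junction_table) <- NULL
  if (!is.null(out$qc_table)) rownames(out$qc_table) <- NULL
  if (!is.null(outdir)) write_pipeline_report(out, outdir)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report: %d clones, %d junction calls, %d end-loss event(s), %.1f s>\n",
              length(unique(x$copy_table$clone)),
              if (is.null(x$junction_table)) 0L else nrow(x$junction_table),
              length(x$end_loss), x$elapsed_s))
  egfp <- x$copy_table[x$copy_table$region == "egfp",
                       c("clone", "relative_to_egfp", "copies_cassette")]
  print(egfp, row.names = FALSE)
  invisible(x)
}

write_pipeline_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    path <- file.path(outdir, name)
    con <- file(path, "w")
    writeLines("# knockin report schema v1", con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wt(report$copy_table, "copy_number.tsv")
  if (!is.null(report$junction_table) && nrow(report$junction_table))
    wt(report$junction_table, "junctions.tsv")
  wt(report$qc_table, "qc.tsv")
  if (length(report$end_loss)) {
    el <- do.call(rbind, lapply(report$end_loss, function(e) data.frame(
      clone = e$clone, chromosome = e$chromosome, end = e$end,
      breakpoint = e$breakpoint, lost_length = e$lost_length,
      lost_chrom_pct = e$lost_chrom_pct, lost_genome_pct = e$lost_genome_pct,
      lost_genes = paste(e$lost_genes, collapse = ","),
      stringsAsFactors = FALSE)))
    wt(el, "end_loss.tsv")
  }
  jsonlite::write_json(
    list(schema = "knockin report v1",
         backbone = as.list(report$backbone),
         seed = report$config$seed),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
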