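#' Run the full structural-analysis pipeline on a synthetic fixture
#'
#' Builds (or loads) a circular mitogenome, scans it for SSRs, tandem
#' repeats and dispersed repeat pairs, enumerates the conformations of
#' every repeat pair above the size threshold, simulates (or loads)
#' long reads, classifies them, tallies per-repeat support, infers the
#' multipartite model, runs the MTPT scan against the plastid molecule,
#' computes genome statistics when an annotation is supplied, and
#' renders everything into one Markdown report.  All outputs are
#' deterministic under a fixed seed (stable ordering, fixed rounding).
#'
#' @param config configuration list, or path to a YAML file with the
#'   same structure; see the package vignette for the schema.  Main
#'   sections: `seed`, `genome` (synthetic genome parameters or a
#'   `fasta` path), `reads` (simulation parameters or a `fasta` path),
#'   `params` (`flank`, `anchor`, `min_identity`, `min_repeat_len`,
#'   `activity_threshold`), optional `annotation` (GFF3 path).
#' @param outdir output directory (created).
#' @return (invisibly) a list with every intermediate result.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prm <- config$params %||% list()
  flank <- prm$flank %||% 1000
  anchor <- prm$anchor %||% 100
  min_ident <- prm$min_identity %||% 0.85
  min_replen <- prm$min_repeat_len %||% 100
  thr <- prm$activity_threshold %||% 20
  seed <- config$seed %||% 1L
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what, t_prev) {
    t <- proc.time()[["elapsed"]]
    message(sprintf("[mitorecomb] %-22s %7.2f s", what, t - t_prev))
    t
  }

  # genome ------------------------------------------------------------
  truth <- NULL
  plastid <- NULL
  if (!is.null(config$genome$fasta)) {
    mito <- read_genome_fasta(config$genome$fasta)
    if (!is.null(config$genome$plastid_fasta))
      plastid <- read_genome_fasta(config$genome$plastid_fasta)
  } else {
    g <- config$genome
    spec <- sim_genome_spec(
      genome_length = g$length,
      repeats = if (!is.null(g$repeats)) as.data.frame(g$repeats) else NULL,
      mtpts = if (!is.null(g$mtpts)) as.data.frame(g$mtpts) else NULL,
      plastid_length = g$plastid_length %||% 0,
      gc = g$gc %||% 0.45, seed = seed)
    built <- build_genome(spec)
    mito <- built$mito
    plastid <- built$plastid
    truth <- built$truth
    write_fasta(setNames(mito$seq, mito$id), file.path(outdir, "mito.fasta"))
    if (!is.null(plastid))
      write_fasta(setNames(plastid$seq, plastid$id),
                  file.path(outdir, "plastid.fasta"))
    write_truth_tsv(truth, outdir)
  }
  tt <- stage("genome", t0)

  # repeat scans --------------------------------------------------------
  ssrs <- find_ssrs(mito)
  write_tsv(ssrs, file.path(outdir, "ssr.tsv"))
  tt <- stage("ssr scan", tt)
  tandems <- find_tandem_repeats(mito)
  write_tsv(tandems, file.path(outdir, "tandem.tsv"))
  tt <- stage("tandem scan", tt)
  pairs <- find_dispersed_repeats(mito, min_len = min_replen)
  write_tsv(pairs, file.path(outdir, "repeats.tsv"))
  write_bed(pairs, file.path(outdir, "repeats.bed"), mito$length, mito$id)
  tt <- stage("dispersed repeats", tt)

  # conformations & reads ----------------------------------------------
  confs <- list()
  for (i in seq_len(nrow(pairs))) {
    cs <- try(enumerate_conformations(mito, pairs[i, ], F = flank),
              silent = TRUE)
    if (!inherits(cs, "try-error")) confs[[cs$id]] <- cs
  }
  if (length(confs)) {
    jseqs <- unlist(lapply(confs, function(cs)
      setNames(c(cs$master_junctions, cs$alt_junctions),
               paste0(cs$id, "_", c("master1", "master2", "alt1", "alt2")))))
    write_fasta(jseqs, file.path(outdir, "junctions.fasta"))
  }
  tt <- stage("conformations", tt)

  if (!is.null(config$reads$fasta)) {
    ss <- Biostrings::readDNAStringSet(config$reads$fasta)
    reads <- data.frame(id = vapply(strsplit(names(ss), "\\s+"), `[`,
                                    character(1), 1),
                        sequence = as.character(ss),
                        stringsAsFactors = FALSE)
  } else {
    r <- config$reads
    w <- unlist(r$weights)
    rspec <- read_sim_spec(
      weights = w, n_reads = r$n_reads %||% 1000,
      meanlog = r$meanlog %||% log(20000), sdlog = r$sdlog %||% 0.6,
      sub_rate = r$sub_rate %||% 0, ins_rate = r$ins_rate %||% 0,
      del_rate = r$del_rate %||% 0, seed = seed + 1L)
    reads <- simulate_reads(mito, confs[intersect(names(w), names(confs))],
                            rspec)
    write_reads_fasta(reads, file.path(outdir, "reads.fasta"))
  }
  tt <- stage("reads", tt)

  # classification & support --------------------------------------------
  labels <- list()
  class_rows <- list()
  for (id in names(confs)) {
    if (confs[[id]]$flank < anchor) {
      message(sprintf(
        "[mitorecomb] %s: flank truncated to %d bp < anchor %d bp; skipped",
        id, confs[[id]]$flank, anchor))
      next
    }
    cl <- classify_reads(reads, confs[[id]], anchor = anchor,
                         min_identity = min_ident)
    labels[[id]] <- cl$label
    cl$repeat_id <- id
    class_rows[[id]] <- cl
  }
  if (length(class_rows))
    write_tsv(do.call(rbind, class_rows)[, c("repeat_id", "id", "label",
                                             "left", "right", "orientation")],
              file.path(outdir, "read_classes.tsv"))
  support <- if (length(labels)) support_table(labels, pairs) else
    support_table(setNames(list(), character(0)), NULL)
  if (length(labels)) write_tsv(support, file.path(outdir, "support.tsv"))
  tt <- stage("classification", tt)

  model <- infer_multipartite(support, mito, pairs,
                              activity_threshold = thr)
  write_multipartite_json(model, file.path(outdir, "multipartite.json"))
  write_multipartite_gff3(model, file.path(outdir, "multipartite.gff3"),
                          seqid = mito$id)
  tt <- stage("multipartite model", tt)

  # MTPT ----------------------------------------------------------------
  mtpt <- NULL
  if (!is.null(plastid)) {
    mtpt <- find_mtpts(mito, plastid)
    write_tsv(mtpt$records, file.path(outdir, "mtpt.tsv"))
    tt <- stage("MTPT scan", tt)
  }

  # annotation stats ----------------------------------------------------
  stats <- NULL
  if (!is.null(config$annotation)) {
    ann <- read_gff3_annotation(config$annotation)
    stats <- summarize_annotation(ann, mito)
    jsonlite::write_json(genome_stats_list(stats),
                         file.path(outdir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tt <- stage("genome stats", tt)
  }

  render_report(file.path(outdir, "report.md"), mito = mito, ssrs = ssrs,
                tandems = tandems, pairs = pairs, support = support,
                model = model, mtpt = mtpt, stats = stats, seed = seed)
  stage("report", tt)
  invisible(list(mito = mito, plastid = plastid, truth = truth, ssrs = ssrs,
                 tandems = tandems, pairs = pairs, confs = confs,
                 reads = reads, support = support, model = model,
                 mtpt = mtpt, stats = stats))
}

#' Render the aggregated Markdown report
#'
#' @param path output `.md` file.
#' @param mito [circular_seq] of the mitogenome.
#' @param ssrs,tandems,pairs,support result tables.
#' @param model a `multipartite_model` (or `NULL`).
#' @param mtpt result of [find_mtpts()] (or `NULL`).
#' @param stats a `genome_stats` (or `NULL`).
#' @param seed seed recorded for provenance.
#' @export
render_report <- function(path, mito, ssrs = NULL, tandems = NULL,
                          pairs = NULL, support = NULL, model = NULL,
                          mtpt = NULL, stats = NULL, seed = NA) {
  md <- c("# Mitochondrial genome structure report", "",
          sprintf("- molecule: %s (%d bp, GC %s%%)", mito$id, mito$length,
                  fmt2(gc_content(mito))),
          sprintf("- seed: %s", as.character(seed)), "")
  tab <- function(df) {
    if (is.null(df) || nrow(df) == 0) return("(none)")
    hdr <- paste(names(df), collapse = " | ")
    sep <- paste(rep("---", ncol(df)), collapse = " | ")
    body <- apply(df, 1, function(r) paste(trimws(r), collapse = " | "))
    c(hdr, sep, body)
  }
  if (!is.null(ssrs))
    md <- c(md, sprintf("## Simple sequence repeats (%d)", nrow(ssrs)), "",
            tab(utils::head(ssrs, 50)), "")
  if (!is.null(tandems))
    md <- c(md, sprintf("## Tandem repeats (%d)", nrow(tandems)), "",
            tab(tandems), "")
  if (!is.null(pairs))
    md <- c(md, sprintf("## Dispersed repeat pairs (%d)", nrow(pairs)), "",
            tab(pairs), "")
  if (!is.null(support) && nrow(support) > 0)
    md <- c(md, "## Read support for alternative conformations", "",
            tab(support), "")
  if (!is.null(model)) {
    md <- c(md, "## Multipartite model", "",
            utils::capture.output(print(model)), "")
  }
  if (!is.null(mtpt))
    md <- c(md, "## Plastid-derived fragments (MTPT)", "",
            sprintf("- fragments: %d", mtpt$n_fragments),
            sprintf("- merged total: %d bp (%s%% of the mitogenome, %s%% of the plastid)",
                    mtpt$total_bp, fmt2(mtpt$percent_mito),
                    fmt2(mtpt$percent_plastid)), "",
            tab(mtpt$records), "")
  if (!is.null(stats))
    md <- c(md, "## Genome statistics", "",
            utils::capture.output(print(stats)), "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(md, con, sep = "\n")
  invisible(path)
}
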