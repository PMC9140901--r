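#' GC content of a sequence
#'
#' `100 * (G + C) / (A + C + G + T)`, 2 decimals half-up; ambiguous
#' bases are excluded from the denominator.  `NA` for an all-N sequence.
#'
#' @param seq a [circular_seq] or character scalar.
#' @return percent (numeric scalar).
#' @export
gc_content <- function(seq) {
  s <- seq_of(seq)
  fr <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                    c("A", "C", "G", "T"))
  den <- sum(fr)
  if (den == 0) return(NA_real_)
  round_half_up(100 * (fr[["C"]] + fr[["G"]]) / den)
}

#' Read gene annotation from GFF3
#'
#' Extracts CDS, tRNA and rRNA features into a flat exon table.  The
#' gene name is taken from the `gene` attribute, falling back to
#' `Parent` then `ID`; a `pseudo` attribute (or `pseudogene` value)
#' marks pseudogenes.
#'
#' @param path GFF3 file.
#' @return data frame with columns `gene`, `type`, `strand`, `start`,
#'   `end`, `pseudo`.
#' @export
read_gff3_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  md <- md[md$type %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  if (nrow(md) == 0) return(empty_annotation())
  getcol <- function(nm) if (nm %in% names(md)) as.character(md[[nm]]) else
    rep(NA_character_, nrow(md))
  gene <- getcol("gene")
  parent <- getcol("Parent")
  idc <- getcol("ID")
  gene[is.na(gene) | gene == ""] <- parent[is.na(gene) | gene == ""]
  gene[is.na(gene) | gene == ""] <- idc[is.na(gene) | gene == ""]
  pseudo <- if ("pseudo" %in% names(md))
    !is.na(md$pseudo) & md$pseudo %in% c("true", "TRUE", "1") else
    rep(FALSE, nrow(md))
  data.frame(gene = gene, type = as.character(md$type),
             strand = as.character(md$strand), start = md$start,
             end = md$end, pseudo = pseudo, stringsAsFactors = FALSE)
}

empty_annotation <- function() {
  data.frame(gene = character(0), type = character(0), strand = character(0),
             start = integer(0), end = integer(0), pseudo = logical(0))
}

#' Read gene annotation from a GenBank flat file
#'
#' Minimal feature-table parser covering what the genome statistics
#' need: `CDS`, `tRNA` and `rRNA` features with `join(...)` /
#' `complement(...)` locations, `/gene` qualifiers and `/pseudo` flags.
#'
#' @param path GenBank flat file.
#' @return data frame as in [read_gff3_annotation()].
#' @export
read_genbank_annotation <- function(path) {
  lines <- readLines(path)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0) stop("no FEATURES block in ", path)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1 else length(lines)
  feat <- lines[(fstart[1] + 1):fend]
  recs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || !(cur$key %in% c("CDS", "tRNA", "rRNA"))) return(NULL)
    loc <- parse_genbank_location(cur$loc)
    if (nrow(loc) == 0) return(NULL)
    data.frame(gene = cur$gene %||% NA_character_, type = cur$key,
               strand = loc$strand, start = loc$start, end = loc$end,
               pseudo = isTRUE(cur$pseudo), stringsAsFactors = FALSE)
  }
  for (ln in feat) {
    if (grepl("^ {5}\\S", ln)) {          # new feature
      recs[[length(recs) + 1L]] <- flush(cur)
      key <- sub("^ {5}(\\S+).*", "\\1", ln)
      loc <- sub("^ {5}\\S+\\s+", "", ln)
      cur <- list(key = key, loc = loc, gene = NULL, pseudo = FALSE)
    } else if (!is.null(cur)) {
      q <- sub("^\\s+", "", ln)
      if (startsWith(q, "/gene=")) {
        cur$gene <- gsub("\"", "", sub("^/gene=", "", q))
      } else if (q == "/pseudo" || startsWith(q, "/pseudo=")) {
        cur$pseudo <- TRUE
      } else if (!startsWith(q, "/")) {
        cur$loc <- paste0(cur$loc, q)    # continued location line
      }
    }
  }
  recs[[length(recs) + 1L]] <- flush(cur)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0) return(empty_annotation())
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

parse_genbank_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- regmatches(loc, gregexpr("[0-9]+\\.\\.[0-9]+|[0-9]+", loc))[[1]]
  nums <- nums[grepl("\\.\\.", nums)]
  if (length(nums) == 0) return(data.frame(strand = character(0),
                                           start = integer(0),
                                           end = integer(0)))
  sp <- strsplit(nums, "\\.\\.")
  data.frame(strand = strand,
             start = as.integer(vapply(sp, `[`, character(1), 1)),
             end = as.integer(vapply(sp, `[`, character(1), 2)),
             stringsAsFactors = FALSE)
}

functional_class <- function(gene) {
  g <- tolower(ifelse(is.na(gene), "", gene))
  ifelse(grepl("^nad", g), "Complex I (NADH dehydrogenase)",
  ifelse(grepl("^sdh", g), "Succinate dehydrogenase",
  ifelse(grepl("^cob", g), "Complex III (ubiquinol cytochrome c reductase)",
  ifelse(grepl("^cox", g), "Complex IV (cytochrome c oxidase)",
  ifelse(grepl("^atp", g), "Complex V (ATP synthase)",
  ifelse(grepl("^ccm", g), "Cytochrome c biogenesis",
  ifelse(grepl("^mttb|^tatc", g), "SecY-independent transport",
  ifelse(grepl("^rps", g), "Ribosomal protein small subunit",
  ifelse(grepl("^rpl", g), "Ribosomal protein large subunit",
  ifelse(grepl("^matr", g), "Intron maturase",
  ifelse(grepl("^rrn", g), "Ribosomal RNAs",
  ifelse(grepl("^trn", g), "Transfer RNA", "Other"))))))))))))
}

#' Descriptive genome statistics from sequence plus annotation
#'
#' Length, GC content, feature counts, coding and structural-RNA base
#' totals (unions of exon intervals, so overlapping genes are not
#' double-counted), intron counts (exons minus one, summed over
#' multi-exon genes) and a functional class table.  Exon intervals
#' falling outside the genome are rejected with a warning.
#'
#' @param records annotation exon table from [read_gff3_annotation()] or
#'   [read_genbank_annotation()].
#' @param genome a [circular_seq].
#' @return An object of class `genome_stats`.
#' @export
summarize_annotation <- function(records, genome) {
  stopifnot(inherits(genome, "circular_seq"))
  L <- genome$length
  if (nrow(records) > 0) {
    bad <- records$start < 1 | records$end > L | records$start > records$end
    if (any(bad)) {
      warning(sum(bad), " annotation interval(s) outside the genome; rejected")
      records <- records[!bad, , drop = FALSE]
    }
  }
  union_bp <- function(df) {
    if (nrow(df) == 0) return(0L)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = df$start, end = df$end))))
  }
  cds <- records[records$type == "CDS", , drop = FALSE]
  trna <- records[records$type == "tRNA", , drop = FALSE]
  rrna <- records[records$type == "rRNA", , drop = FALSE]
  coding_bp <- union_bp(cds)
  rna_bp <- union_bp(rbind(trna, rrna))
  # introns: exons - 1 within each gene/type group
  grp <- if (nrow(records))
    paste(records$gene, records$type, sep = "\r") else character(0)
  exon_counts <- table(grp)
  multi <- exon_counts[exon_counts > 1]
  n_introns <- if (length(multi)) sum(multi - 1) else 0L
  genes_with_introns <- if (length(multi))
    sort(unique(vapply(strsplit(names(multi), "\r", fixed = TRUE), `[`,
                       character(1), 1))) else character(0)
  cds_genes <- unique(cds$gene[!is.na(cds$gene)])
  class_tab <- if (nrow(records)) {
    per_gene <- unique(records[, c("gene", "type", "pseudo")])
    cls <- functional_class(per_gene$gene)
    as.data.frame(table(class = cls), stringsAsFactors = FALSE)
  } else data.frame(class = character(0), Freq = integer(0))
  names(class_tab) <- c("class", "n_genes")
  structure(list(
    genome_id = genome$id, length = L, gc_percent = gc_content(genome),
    n_protein_coding = length(cds_genes),
    n_trna = nrow(unique(trna[, c("gene", "start")])),
    n_rrna = nrow(unique(rrna[, c("gene", "start")])),
    coding_bp = coding_bp, coding_percent = pct_of(coding_bp, L),
    rna_bp = rna_bp, rna_percent = pct_of(rna_bp, L),
    n_introns = n_introns, genes_with_introns = genes_with_introns,
    class_table = class_tab,
    n_pseudo = length(unique(records$gene[records$pseudo]))),
    class = "genome_stats")
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf("<genome_stats> %s\n", x$genome_id))
  cat(sprintf("  length          %d bp\n", x$length))
  cat(sprintf("  GC content      %s%%\n", fmt2(x$gc_percent)))
  cat(sprintf("  protein-coding  %d genes, %d bp (%s%%)\n",
              x$n_protein_coding, x$coding_bp, fmt2(x$coding_percent)))
  cat(sprintf("  tRNA / rRNA     %d / %d, %d bp (%s%%)\n",
              x$n_trna, x$n_rrna, x$rna_bp, fmt2(x$rna_percent)))
  cat(sprintf("  introns         %d in %d gene(s)\n", x$n_introns,
              length(x$genes_with_introns)))
  invisible(x)
}

genome_stats_list <- function(x) {
  list(genome_id = x$genome_id, length = x$length,
       gc_percent = x$gc_percent,
       n_protein_coding = x$n_protein_coding, n_trna = x$n_trna,
       n_rrna = x$n_rrna, coding_bp = x$coding_bp,
       coding_percent = x$coding_percent, rna_bp = x$rna_bp,
       rna_percent = x$rna_percent, n_introns = x$n_introns,
       genes_with_introns = x$genes_with_introns,
       n_pseudo = x$n_pseudo)
}
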