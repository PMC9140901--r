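#' Pairwise homologous segments between two genomes
#'
#' Word-size-7 seeded, maximally extended ungapped local matches on both
#' strands, filtered by length and identity.  Both molecules may be
#' circular; matches are reported in canonical coordinates on each
#' circle (ends may exceed the molecule length for wrapped segments).
#'
#' @param A,B [circular_seq] objects (or character scalars, assumed
#'   circular).
#' @param min_len minimum segment length in bp (default 100).
#' @param min_identity minimum identity fraction (default 0.9).
#' @param word seed word size (default 7).
#' @return data frame with columns `a_start`, `a_end`, `b_start`,
#'   `b_end`, `strand` (`+`/`-`), `length`, `identity`.
#' @export
pairwise_homology <- function(A, B, min_len = 100, min_identity = 0.9,
                              word = 7) {
  sa <- seq_of(A); sb <- seq_of(B)
  if (nchar(sa) == 0 || nchar(sb) == 0) stop("empty input sequence")
  La <- nchar(sa); Lb <- nchar(sb)
  circ_a <- !inherits(A, "circular_seq") || A$topology == "circular"
  circ_b <- !inherits(B, "circular_seq") || B$topology == "circular"
  qa <- if (circ_a) paste0(sa, sa) else sa
  qb <- if (circ_b) paste0(sb, sb) else sb
  exact <- min_identity >= 1
  fw <- cpp_seed_extend(qa, qb, word, min_len, min_identity, exact, 0L, 3L, 12L)
  rv <- cpp_seed_extend(qa, revcomp(qb), word, min_len, min_identity, exact,
                        0L, 3L, 12L)
  nb2 <- nchar(qb)
  recs <- list()
  if (nrow(fw) > 0) {
    len <- fw$q_end - fw$q_start + 1
    fw <- fw[len <= min(La, Lb), , drop = FALSE]
    if (nrow(fw) > 0)
      recs[[length(recs) + 1L]] <- data.frame(
        a_start = mod1(fw$q_start, La), b_start = mod1(fw$s_start, Lb),
        length = fw$q_end - fw$q_start + 1, matches = fw$matches,
        strand = "+", stringsAsFactors = FALSE)
  }
  if (nrow(rv) > 0) {
    len <- rv$q_end - rv$q_start + 1
    rv <- rv[len <= min(La, Lb), , drop = FALSE]
    if (nrow(rv) > 0)
      recs[[length(recs) + 1L]] <- data.frame(
        a_start = mod1(rv$q_start, La),
        b_start = mod1(nb2 - rv$s_end + 1, Lb),
        length = rv$q_end - rv$q_start + 1, matches = rv$matches,
        strand = "-", stringsAsFactors = FALSE)
  }
  if (length(recs) == 0) return(empty_homology())
  out <- unique(do.call(rbind, recs))
  # drop sub-segments contained in a longer segment with the same pairing
  out <- out[order(-out$length, out$a_start, out$b_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j] || out$strand[i] != out$strand[j]) next
      ca <- circ_intersect_width(out$a_start[i], out$length[i],
                                 out$a_start[j], out$length[j], La)
      cb <- circ_intersect_width(out$b_start[i], out$length[i],
                                 out$b_start[j], out$length[j], Lb)
      if (ca == out$length[i] && cb == out$length[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  data.frame(a_start = out$a_start, a_end = out$a_start + out$length - 1,
             b_start = out$b_start, b_end = out$b_start + out$length - 1,
             strand = out$strand, length = out$length,
             identity = round(out$matches / out$length, 4),
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_homology <- function() {
  data.frame(a_start = integer(0), a_end = integer(0), b_start = integer(0),
             b_end = integer(0), strand = character(0), length = integer(0),
             identity = numeric(0))
}

#' Shared-DNA summary for a genome pair
#'
#' Coverage on each genome is the width of the union of its homologous
#' segment intervals (overlap-merged, circular-aware); percentages are
#' reported against each genome's own length, 2 decimals, half-up.
#'
#' @param segments segment table from [pairwise_homology()] (columns
#'   `a_start`, `b_start`, `length`), or any data frame with those
#'   columns.
#' @param a_length,b_length molecule lengths in bp.
#' @param a_id,b_id molecule labels.
#' @return one-row data frame: `genome_a`, `genome_b`, `covered_bp_a`,
#'   `percent_a`, `covered_bp_b`, `percent_b`.
#' @export
shared_fraction <- function(segments, a_length, b_length,
                            a_id = "A", b_id = "B") {
  if (a_length <= 0 || b_length <= 0) stop("zero-length genome")
  cov_a <- circ_union_width(segments$a_start, segments$length, a_length)
  cov_b <- circ_union_width(segments$b_start, segments$length, b_length)
  data.frame(genome_a = a_id, genome_b = b_id,
             covered_bp_a = cov_a, percent_a = pct_of(cov_a, a_length),
             covered_bp_b = cov_b, percent_b = pct_of(cov_b, b_length),
             stringsAsFactors = FALSE)
}

#' Identify plastid-derived fragments (MTPT) in a mitochondrial genome
#'
#' MTPT segments are homologous segments between the mitochondrial and
#' plastid molecules; totals are computed on the overlap-merged
#' mitochondrial intervals so nested or overlapping fragments are not
#' double counted.
#'
#' @param mito,plastid [circular_seq] objects.
#' @param min_len minimum match length in bp (default 100).
#' @param min_identity minimum identity fraction (default 0.9).
#' @return list with `records` (segment table, mito side first),
#'   `n_fragments`, `total_bp` (merged mito coverage), `percent_mito`
#'   and `percent_plastid`.
#' @export
find_mtpts <- function(mito, plastid, min_len = 100, min_identity = 0.9) {
  seg <- pairwise_homology(mito, plastid, min_len = min_len,
                           min_identity = min_identity)
  Lm <- nchar(seq_of(mito)); Lp <- nchar(seq_of(plastid))
  names(seg) <- sub("^a_", "mito_", sub("^b_", "plastid_", names(seg)))
  total <- circ_union_width(seg$mito_start, seg$length, Lm)
  total_p <- circ_union_width(seg$plastid_start, seg$length, Lp)
  list(records = seg, n_fragments = nrow(seg), total_bp = total,
       percent_mito = pct_of(total, Lm),
       percent_plastid = pct_of(total_p, Lp))
}

#' Write homologous segments as a link table
#'
#' Tab-separated `molA start end molB start end` rows, consumable by
#' Circos-class plotting tools.
#'
#' @param segments table from [pairwise_homology()].
#' @param path output file.
#' @param a_id,b_id molecule labels.
#' @export
write_link_table <- function(segments, path, a_id = "A", b_id = "B") {
  df <- data.frame(molA = a_id, a_start = segments$a_start,
                   a_end = segments$a_end, molB = b_id,
                   b_start = segments$b_start, b_end = segments$b_end)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, eol = "\n")
  invisible(path)
}
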