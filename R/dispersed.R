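#' Detect dispersed repeat pairs on a circular molecule
#'
#' Self-comparison of the molecule with word-size-7 seeding and maximal
#' ungapped extension, reporting direct and inverted (reverse-complement)
#' pairs of length at least `min_len` and identity at least
#' `min_identity`.  Circularity is handled by scanning the doubled
#' sequence and collapsing records to canonical coordinates on the
#' circle, so pairs wrapping the origin are found.  With
#' `min_identity = 1` the extension is exact and the output is the set
#' of maximal exact repeated pairs.
#'
#' @param seq a [circular_seq] or character scalar (assumed circular).
#' @param min_len minimum repeat length in bp (default 100).
#' @param min_identity minimum identity fraction (default 0.9).
#' @param word seed word size (default 7).
#' @return data frame with columns `id`, `length`, `start1`, `end1`,
#'   `start2`, `end2`, `orientation` (`direct`/`inverted`) and
#'   `identity`, ordered by length descending (ids follow that order).
#'   Coordinates are 1-based inclusive; `end` may exceed the molecule
#'   length for copies wrapping the origin.  `start1 < start2` by
#'   canonical ordering; self-hits are suppressed.
#' @export
find_dispersed_repeats <- function(seq, min_len = 100, min_identity = 0.9,
                                   word = 7) {
  s <- seq_of(seq)
  L <- nchar(s)
  if (L < min_len) stop("sequence shorter than min_len")
  circular <- !inherits(seq, "circular_seq") || seq$topology == "circular"
  sx <- if (circular) paste0(s, s) else s
  exact <- min_identity >= 1
  skip <- if (circular) L else nchar(sx)
  dir_hits <- cpp_seed_extend(sx, sx, word, min_len, min_identity, exact,
                              skip, 3L, 12L)
  inv_hits <- cpp_seed_extend(sx, revcomp(sx), word, min_len, min_identity,
                              exact, 0L, 3L, 12L)
  n2 <- nchar(sx)
  recs <- list()
  if (nrow(dir_hits) > 0) {
    len <- dir_hits$q_end - dir_hits$q_start + 1
    keep <- len <= L
    dh <- dir_hits[keep, , drop = FALSE]
    if (nrow(dh) > 0) {
      recs[[length(recs) + 1L]] <- data.frame(
        start1 = mod1(dh$q_start, L), start2 = mod1(dh$s_start, L),
        length = dh$q_end - dh$q_start + 1, matches = dh$matches,
        orientation = "direct", stringsAsFactors = FALSE)
    }
  }
  if (nrow(inv_hits) > 0) {
    len <- inv_hits$q_end - inv_hits$q_start + 1
    keep <- len <= L
    ih <- inv_hits[keep, , drop = FALSE]
    if (nrow(ih) > 0) {
      # subject coordinates are on the reverse complement; map back
      recs[[length(recs) + 1L]] <- data.frame(
        start1 = mod1(ih$q_start, L),
        start2 = mod1(n2 - ih$s_end + 1, L),
        length = ih$q_end - ih$q_start + 1, matches = ih$matches,
        orientation = "inverted", stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) return(empty_repeat_pairs())
  out <- do.call(rbind, recs)
  # canonical unordered pair: copy1 before copy2
  swap <- out$start2 < out$start1
  tmp <- out$start1[swap]
  out$start1[swap] <- out$start2[swap]
  out$start2[swap] <- tmp
  out <- out[out$start1 != out$start2, , drop = FALSE]  # self-hits
  out <- unique(out)
  if (nrow(out) == 0) return(empty_repeat_pairs())
  # drop records whose both copies are contained in a longer record's
  # copies (sub-extensions of the same repeat found from another seed)
  out <- out[order(-out$length, out$start1, out$start2), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (out$orientation[i] != out$orientation[j]) next
      c11 <- circ_intersect_width(out$start1[i], out$length[i],
                                  out$start1[j], out$length[j], L)
      c22 <- circ_intersect_width(out$start2[i], out$length[i],
                                  out$start2[j], out$length[j], L)
      if (c11 == out$length[i] && c22 == out$length[i]) {
        keep[i] <- FALSE
        break
      }
      c12 <- circ_intersect_width(out$start1[i], out$length[i],
                                  out$start2[j], out$length[j], L)
      c21 <- circ_intersect_width(out$start2[i], out$length[i],
                                  out$start1[j], out$length[j], L)
      if (c12 == out$length[i] && c21 == out$length[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  data.frame(id = sprintf("R%d", seq_len(nrow(out))),
             length = out$length,
             start1 = out$start1, end1 = out$start1 + out$length - 1,
             start2 = out$start2, end2 = out$start2 + out$length - 1,
             orientation = out$orientation,
             identity = round(out$matches / out$length, 4),
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_repeat_pairs <- function() {
  data.frame(id = character(0), length = integer(0), start1 = integer(0),
             end1 = integer(0), start2 = integer(0), end2 = integer(0),
             orientation = character(0), identity = numeric(0))
}

#' Write repeat records as BED (0-based half-open)
#'
#' Intervals wrapping the circular origin are split into two BED lines.
#'
#' @param df a record data frame with `start`/`end` columns, or a repeat
#'   pair table from [find_dispersed_repeats()] (both copies emitted).
#' @param path output file.
#' @param L molecule length (for wraparound splitting).
#' @param chrom chromosome/molecule name used in column 1.
#' @export
write_bed <- function(df, path, L, chrom = "genome") {
  rows <- list()
  add <- function(start, end, name) {
    len <- end - start + 1
    pieces <- circ_pieces(start, len, L)
    for (r in seq_len(nrow(pieces)))
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom, start = pieces$start[r] - 1L, end = pieces$end[r],
        name = name, stringsAsFactors = FALSE)
  }
  if (all(c("start1", "start2") %in% names(df))) {
    for (i in seq_len(nrow(df))) {
      add(df$start1[i], df$end1[i], paste0(df$id[i], "_copy1"))
      add(df$start2[i], df$end2[i], paste0(df$id[i], "_copy2"))
    }
  } else {
    for (i in seq_len(nrow(df))) {
      nm <- if ("motif" %in% names(df)) df$motif[i] else
        if ("id" %in% names(df)) df$id[i] else sprintf("rec%d", i)
      add(df$start[i], df$end[i], nm)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, eol = "\n")
  invisible(path)
}
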