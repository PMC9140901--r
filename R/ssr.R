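#' Detect simple sequence repeats (microsatellites)
#'
#' Finds maximal perfect tandem runs of 1-6 bp motifs at or above the
#' per-motif-length minimum copy numbers used for organelle genome
#' surveys (10/5/4/3/3/3 for mono- through hexanucleotide units).
#' Motifs are reported in canonical form (lexicographic minimum over
#' rotations) and only for primitive motifs, so a mononucleotide run is
#' never re-reported as a dinucleotide record.  On circular molecules
#' runs may wrap the origin; their `end` coordinate then exceeds the
#' molecule length.
#'
#' @param seq a [circular_seq] or character scalar (assumed circular).
#' @param minima integer vector of length 6: minimum copy numbers for
#'   unit lengths 1-6.
#' @return data frame with columns `motif`, `unit_length`, `copy_number`,
#'   `start`, `end`, `length` (1-based inclusive), ordered by `start`.
#'   Runs containing `N` are never part of an SSR.
#' @export
find_ssrs <- function(seq, minima = c(10, 5, 4, 3, 3, 3)) {
  stopifnot(length(minima) == 6, all(minima >= 2))
  s <- seq_of(seq)
  L <- nchar(s)
  circular <- !inherits(seq, "circular_seq") || seq$topology == "circular"
  sx <- if (circular) paste0(s, s) else s
  v <- strsplit(sx, "", fixed = TRUE)[[1]]
  ok <- v %in% c("A", "C", "G", "T")
  n <- length(v)
  recs <- list()
  for (p in 1:6) {
    if (n <= p) next
    eq <- v[seq_len(n - p)] == v[(p + 1):n] &
      ok[seq_len(n - p)] & ok[(p + 1):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    for (h in hit) {
      i <- starts[h]
      m <- r$lengths[h]
      array_len <- min(m + p, L)
      copies <- array_len %/% p
      if (copies < minima[p]) next
      motif <- substr(sx, i, i + p - 1)
      if (!is_primitive_motif(motif)) next
      recs[[length(recs) + 1L]] <- data.frame(
        motif = canonical_motif(motif), unit_length = p,
        copy_number = copies, start = i,
        end = i + copies * p - 1L, length = copies * p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0)
    return(data.frame(motif = character(0), unit_length = integer(0),
                      copy_number = integer(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  out <- do.call(rbind, recs)
  if (circular) {
    out <- out[out$start <= L, , drop = FALSE]
    out <- drop_circ_contained(out, L)
  }
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# A motif is primitive when it is not a whole-number repetition of a
# shorter motif.
is_primitive_motif <- function(m) {
  p <- nchar(m)
  if (p == 1) return(TRUE)
  for (d in seq_len(p - 1)) {
    if (p %% d != 0) next
    if (m == strrep(substr(m, 1, d), p / d)) return(FALSE)
  }
  TRUE
}

canonical_motif <- function(m) {
  p <- nchar(m)
  if (p == 1) return(m)
  rots <- vapply(0:(p - 1), function(o)
    paste0(substr(m, o + 1, p), substr(m, 1, o)), character(1))
  min(rots)
}

# Drop records whose locus (mod L) is contained in another record's locus
# (duplicates arising from scanning the doubled circular sequence).
drop_circ_contained <- function(df, L) {
  if (nrow(df) < 2) return(df)
  keep <- rep(TRUE, nrow(df))
  lens <- df$length
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j || !keep[i]) next
      if (lens[i] > lens[j]) next
      if (lens[i] == lens[j] && i < j) next
      ov <- circ_intersect_width(df$start[i], lens[i], df$start[j], lens[j], L)
      if (ov == lens[i]) { keep[i] <- FALSE; break }
    }
  }
  df[keep, , drop = FALSE]
}

circ_intersect_width <- function(s1, l1, s2, l2, L) {
  a <- circ_pieces(s1, l1, L)
  b <- circ_pieces(s2, l2, L)
  ia <- IRanges::IRanges(start = a$start, end = a$end)
  ib <- IRanges::IRanges(start = b$start, end = b$end)
  sum(IRanges::width(IRanges::intersect(ia, ib)))
}
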