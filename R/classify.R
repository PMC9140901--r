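#' Classify a long read by the genome conformation it supports
#'
#' A read supports a conformation when it spans one of that
#' conformation's recombination junctions: it must cover the repeat and
#' align at least `anchor` bases at `min_identity` or better in BOTH
#' flanks, and the flank combination must be consistent with only one
#' conformation.  Reads contained in the repeat, touching one flank
#' only, failing identity, or whose flank combination is ambiguous are
#' uninformative.
#'
#' The read is first located on the repeat by exact k-mer seeding (both
#' orientations); the repeat boundaries on the read are extrapolated
#' from the seed diagonals, and the read segments immediately up- and
#' downstream of the repeat are aligned (fitting alignment) against the
#' two candidate flanks on each side.
#'
#' @param read character scalar (read sequence).
#' @param confs a `conformation_set` from [enumerate_conformations()].
#' @param anchor minimum aligned flank length in bp (default 100; must
#'   not exceed the flank length of `confs`).
#' @param min_identity minimum flank identity (default 0.85).
#' @param k seed k-mer size (default 13).
#' @return character scalar: `"master"`, `"alternative"` or
#'   `"uninformative"`.
#' @export
classify_read <- function(read, confs, anchor = 100, min_identity = 0.85,
                          k = 13) {
  classify_reads(as.character(read), confs, anchor = anchor,
                 min_identity = min_identity, k = k, stride = 1)$label[1]
}

#' Classify many reads against a conformation set
#'
#' Vectorized form of [classify_read()]: the repeat k-mer index is
#' built once and shared across reads, and reverse-complement seeding
#' is only attempted for reads the forward scan cannot place.
#'
#' @param reads character vector of read sequences, or a
#'   `simulated_reads` data frame from [simulate_reads()].
#' @param stride scan every `stride`-th read position for seeds
#'   (default 3; repeat-spanning reads still yield hundreds of seeds).
#' @inheritParams classify_read
#' @return data frame with columns `id`, `label`, `left`, `right`,
#'   `orientation`.
#' @export
classify_reads <- function(reads, confs, anchor = 100, min_identity = 0.85,
                           k = 13, stride = 3) {
  stopifnot(inherits(confs, "conformation_set"))
  if (anchor > confs$flank)
    stop("anchor exceeds the flank length of the conformation set")
  if (is.data.frame(reads)) {
    ids <- reads$id
    seqs <- reads$sequence
  } else {
    ids <- if (!is.null(names(reads))) names(reads) else
      sprintf("read%05d", seq_along(reads))
    seqs <- as.character(reads)
  }
  n <- length(seqs)
  R <- confs$repeat_seq
  replen <- nchar(R)
  seqs[is.na(seqs)] <- ""
  hits_f <- cpp_seed_hits_batch(seqs, R, k, stride)
  placed <- vapply(hits_f, function(h) seeds_place(h, k, replen), logical(1))
  ori <- ifelse(placed, "+", NA_character_)
  hits <- hits_f
  rd <- seqs
  todo <- which(!placed & nchar(seqs) >= k)
  if (length(todo)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[todo])))
    hits_r <- cpp_seed_hits_batch(rc, R, k, stride)
    placed_r <- vapply(hits_r, function(h) seeds_place(h, k, replen),
                       logical(1))
    hits[todo] <- hits_r
    rd[todo] <- rc
    ori[todo][placed_r] <- "-"
    placed[todo] <- placed_r
  }
  label <- rep("uninformative", n)
  left <- rep("none", n)
  right <- rep("none", n)
  slack <- ceiling(0.35 * anchor) + 15L
  for (i in which(placed)) {
    h <- hits[[i]]
    qpos <- h[, 1]; rpos <- h[, 2]
    o <- order(rpos)
    lo <- o[seq_len(min(8L, length(o)))]
    hi <- rev(o)[seq_len(min(8L, length(o)))]
    a_start <- round(median(qpos[lo] - rpos[lo] + 1))
    a_end <- round(median(qpos[hi] + (replen - rpos[hi])))
    nread <- nchar(rd[i])
    left[i] <- flank_side(rd[i], a_start, "left", confs$flanks$LA,
                          confs$flanks$LB, anchor, min_identity, slack, nread)
    if (left[i] %in% c("A", "B")) {
      right[i] <- flank_side(rd[i], a_end, "right", confs$flanks$RA,
                             confs$flanks$RB, anchor, min_identity, slack,
                             nread)
      if (right[i] %in% c("A", "B"))
        label[i] <- if (left[i] == right[i]) "master" else "alternative"
    }
  }
  data.frame(id = ids, label = label, left = left, right = right,
             orientation = ori, stringsAsFactors = FALSE)
}

# Can this seed-hit set place the repeat on the read?  Requires a
# handful of seeds covering most of the repeat's length.
seeds_place <- function(h, k, replen) {
  if (nrow(h) < 3) return(FALSE)
  (max(h[, 2]) - min(h[, 2]) + k) / replen >= 0.6
}

# Decide which of two candidate flanks (A/B) the read carries on one side
# of the repeat: "A", "B", "none" or "ambiguous".
flank_side <- function(rd, bound, side, flankA, flankB, anchor,
                       min_identity, slack, nread) {
  Fl <- nchar(flankA)
  if (side == "left") {
    t_start <- max(1L, bound - anchor - slack)
    t_end <- min(nread, bound - 1L + 15L)
    patA <- substr(flankA, Fl - anchor + 1, Fl)
    patB <- substr(flankB, Fl - anchor + 1, Fl)
  } else {
    t_start <- max(1L, bound + 1L - 15L)
    t_end <- min(nread, bound + anchor + slack)
    patA <- substr(flankA, 1, anchor)
    patB <- substr(flankB, 1, anchor)
  }
  if (t_end - t_start + 1 < 0.8 * anchor) return("none")
  text <- substr(rd, t_start, t_end)
  idA <- cpp_fit_align(patA, text)$identity
  idB <- cpp_fit_align(patB, text)$identity
  pa <- idA >= min_identity
  pb <- idB >= min_identity
  if (pa && pb) "ambiguous" else if (pa) "A" else if (pb) "B" else "none"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-repeat read-support table
#'
#' Tallies conformation labels per repeat and reports support fractions
#' over informative reads only: `frac_master = 100 * n_master /
#' (n_master + n_alt)` (2 decimals, half-up), and the complementary
#' `frac_alt`.  Fractions are `NA` when no informative reads exist.
#'
#' @param labels named list: repeat id -> character vector of labels
#'   from [classify_reads()] (`master` / `alternative` /
#'   `uninformative`).
#' @param pairs optional repeat-pair table supplying `id` and `length`;
#'   when given, rows are ordered by repeat length descending.
#' @return data frame of class `read_support` with columns `id`,
#'   `length` (if available), `n_master`, `n_alt`, `n_uninformative`,
#'   `frac_master`, `frac_alt`.
#' @export
support_table <- function(labels, pairs = NULL) {
  ids <- names(labels)
  rows <- lapply(ids, function(id) {
    lb <- labels[[id]]
    n_m <- sum(lb == "master")
    n_a <- sum(lb == "alternative")
    n_u <- sum(lb == "uninformative")
    fr <- support_fractions(n_m, n_a)
    data.frame(id = id, n_master = n_m, n_alt = n_a, n_uninformative = n_u,
               frac_master = fr$frac_master, frac_alt = fr$frac_alt,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), n_master = integer(0), n_alt = integer(0),
               n_uninformative = integer(0), frac_master = numeric(0),
               frac_alt = numeric(0))
  if (!is.null(pairs) && nrow(out) > 0) {
    out$length <- pairs$length[match(out$id, pairs$id)]
    out <- out[order(-out$length, out$id),
               c("id", "length", "n_master", "n_alt", "n_uninformative",
                 "frac_master", "frac_alt")]
  }
  rownames(out) <- NULL
  class(out) <- c("read_support", "data.frame")
  out
}

#' Support fractions from raw informative-read counts
#'
#' @param n_master,n_alt counts of reads supporting the master circle
#'   and the alternative conformation.
#' @return list with `frac_master` and `frac_alt` (percent, 2 decimals,
#'   half-up; `NA` when both counts are zero).
#' @examples
#' support_fractions(40, 48)   # 45.45 / 54.55
#' support_fractions(184, 6)   # 96.84 / 3.16
#' @export
support_fractions <- function(n_master, n_alt) {
  stopifnot(n_master >= 0, n_alt >= 0)
  tot <- n_master + n_alt
  if (tot == 0) return(list(frac_master = NA_real_, frac_alt = NA_real_))
  list(frac_master = round_half_up(100 * n_master / tot),
       frac_alt = round_half_up(100 * n_alt / tot))
}
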