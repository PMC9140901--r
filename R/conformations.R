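#' Enumerate the conformations mediated by a dispersed repeat pair
#'
#' Homologous recombination across a dispersed repeat pair interconverts
#' the master circle and an alternative conformation: for a direct pair,
#' two subgenomic circles each retaining one repeat copy; for an
#' inverted pair, a single circle with the intervening segment
#' reverse-complemented.  This function builds the four junction
#' reference sequences (repeat copy plus `F` bp of upstream and
#' downstream flank) that distinguish the two conformations: two
#' junctions in master order and the two recombinant joins.
#'
#' @param genome the master-circle [circular_seq].
#' @param pair one row of a repeat-pair table ([find_dispersed_repeats()]
#'   columns `id`, `length`, `start1`, `start2`, `orientation`).
#' @param F flank length in bp (default 1000); truncated when an
#'   inter-repeat arc is too short to supply full flanks.
#' @return An object of class `conformation_set`: fields `id`, `pair`,
#'   `flank`, `repeat_seq`, `flanks` (`LA`, `RA`, `LB`, `RB`),
#'   `master_junctions` and `alt_junctions` (each two sequences of
#'   length `length + 2*flank`).
#' @details With the repeat written in the orientation of copy 1, the
#'   read-distinguishing structure of every junction is (left flank,
#'   repeat, right flank).  Master junctions combine flanks `(LA, RA)`
#'   and `(LB, RB)`; the recombinant junctions exchange them:
#'   `(LA, RB)` and `(LB, RA)`.  For an inverted pair `LB` and `RB` are
#'   the reverse-complemented flanks of copy 2, which reduces the
#'   inverted case to the same exchange rule.
#' @export
as_pair_list <- function(pair) {
  if (is.data.frame(pair)) as.list(pair[1, , drop = FALSE]) else as.list(pair)
}

enumerate_conformations <- function(genome, pair, F = 1000) {
  stopifnot(inherits(genome, "circular_seq"), F >= 1)
  pair <- as_pair_list(pair)
  L <- genome$length
  len <- pair$length
  s1 <- pair$start1; s2 <- pair$start2
  if (len >= L) stop("repeat as long as the molecule")
  if (circ_overlaps(s1, len, s2, len, L))
    stop("repeat copies overlap; the recombinational exchange is undefined")
  e1 <- s1 + len - 1; e2 <- s2 + len - 1
  # flanks are truncated to the shorter inter-repeat arc so that every
  # junction reference is an exact substring of its conformation molecule
  gapA <- (s2 - e1 - 1) %% L
  gapB <- (s1 - e2 - 1) %% L
  Fe <- min(F, gapA, gapB)
  if (Fe < 1) stop("molecule too short for any flank")
  R <- circ_substr(genome, s1, len)
  LA <- circ_substr(genome, s1 - Fe, Fe)
  RA <- circ_substr(genome, e1 + 1, Fe)
  if (pair$orientation == "direct") {
    LB <- circ_substr(genome, s2 - Fe, Fe)
    RB <- circ_substr(genome, e2 + 1, Fe)
  } else {
    LB <- revcomp(circ_substr(genome, e2 + 1, Fe))
    RB <- revcomp(circ_substr(genome, s2 - Fe, Fe))
  }
  structure(list(
    id = if (!is.null(pair$id)) pair$id else "R1",
    pair = pair, flank = Fe, repeat_seq = R,
    flanks = list(LA = LA, RA = RA, LB = LB, RB = RB),
    master_junctions = c(j1 = paste0(LA, R, RA), j2 = paste0(LB, R, RB)),
    alt_junctions = c(a1 = paste0(LA, R, RB), a2 = paste0(LB, R, RA)),
    genome_id = genome$id),
    class = "conformation_set")
}

#' @export
print.conformation_set <- function(x, ...) {
  cat(sprintf(
    "<conformation_set> %s: %s repeat, %d bp, copies at %d and %d, flank %d bp\n",
    x$id, x$pair$orientation, x$pair$length, x$pair$start1, x$pair$start2,
    x$flank))
  invisible(x)
}

#' Molecules of the alternative conformation of a repeat pair
#'
#' Performs the recombinational string surgery: a direct pair splits the
#' master circle into two subgenomic circles (one inter-repeat arc plus
#' one repeat copy each); an inverted pair yields one circle of
#' unchanged length with the inner segment reverse-complemented.
#'
#' @param genome the master-circle [circular_seq].
#' @param pair repeat pair row (as in [enumerate_conformations()]).
#' @return list with `orientation`, `molecules` (list of
#'   [circular_seq]; for a direct pair the two subcircles, sizes summing
#'   to the master length) and `anchors` (data frame `mol`, `pos`: the
#'   1-based start of the retained repeat copy on each molecule).
#' @export
conformation_molecules <- function(genome, pair) {
  stopifnot(inherits(genome, "circular_seq"))
  pair <- as_pair_list(pair)
  L <- genome$length
  len <- pair$length
  s1 <- pair$start1; s2 <- pair$start2
  if (circ_overlaps(s1, len, s2, len, L))
    stop("repeat copies overlap; the recombinational exchange is undefined")
  id <- if (!is.null(pair$id)) pair$id else "R"
  if (pair$orientation == "direct") {
    lenA <- (s2 - s1) %% L
    lenB <- L - lenA
    if (lenA < len || lenB < len)
      stop("subcircle smaller than the repeat; copies too close")
    A <- circular_seq(paste0(id, ".A"), circ_substr(genome, s1, lenA))
    B <- circular_seq(paste0(id, ".B"), circ_substr(genome, s2, lenB))
    list(orientation = "direct", molecules = list(A, B),
         anchors = data.frame(mol = c(1L, 2L), pos = c(1L, 1L)))
  } else {
    e1 <- s1 + len - 1
    inner_len <- (s2 - 1 - e1) %% L
    rest_len <- L - len - inner_len
    gr <- circ_substr(genome, s1, L)  # master linearized at copy 1
    inner <- substr(gr, len + 1, len + inner_len)
    alt <- paste0(substr(gr, 1, len), revcomp(inner),
                  substr(gr, len + inner_len + 1, L))
    M <- circular_seq(paste0(id, ".inv"), alt)
    list(orientation = "inverted", molecules = list(M),
         anchors = data.frame(mol = c(1L, 1L),
                              pos = c(1L, as.integer(len + inner_len + 1))))
  }
}
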