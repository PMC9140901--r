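#' Detect tandem repeat arrays
#'
#' Finds tandem arrays of period up to `max_period` whose alignment
#' against their own consensus periodicity scores at least `min_score`
#' under the convention of +`match` per matching base and -`mismatch` /
#' -`indel` per mismatching or inserted/deleted base (defaults 2/7/7
#' with a minimum score of 50 and maximum period of 500, the settings
#' used for organelle genome surveys).  A perfect array therefore
#' scores twice its length.
#'
#' Candidate arrays are located by recurring k-mers at a fixed distance
#' (the candidate period), extended while the sequence remains periodic,
#' and validated with a wraparound dynamic program against the majority
#' consensus, so modest substitution/indel divergence within an array is
#' tolerated.
#'
#' @param seq a [circular_seq] or character scalar (assumed circular).
#' @param match,mismatch,indel positive alignment weights.
#' @param min_score minimum reported alignment score.
#' @param max_period maximum period size in bp.
#' @return data frame with columns `period`, `copy_number` (1 decimal,
#'   may be fractional), `consensus`, `score`, `start`, `end`, `length`.
#' @export
find_tandem_repeats <- function(seq, match = 2, mismatch = 7, indel = 7,
                                min_score = 50, max_period = 500) {
  stopifnot(match > 0, mismatch > 0, indel > 0)
  s <- seq_of(seq)
  L <- nchar(s)
  circular <- !inherits(seq, "circular_seq") || seq$topology == "circular"
  sx <- if (circular) paste0(s, s) else s
  v <- strsplit(sx, "", fixed = TRUE)[[1]]
  n <- length(v)
  k <- 5L
  if (n < 2 * k) return(empty_tandem())
  # recurring k-mer distances (candidate periods)
  km <- substring(sx, seq_len(n - k + 1), k:n)
  ids <- match(km, km)  # first-occurrence ids, cheap hashing
  o <- order(ids, seq_along(ids))
  pos <- seq_along(ids)[o]
  same <- ids[o][-length(o)] == ids[o][-1]
  d <- diff(pos)
  sel <- which(same & d >= 1 & d <= max_period)
  if (length(sel) == 0) return(empty_tandem())
  cand_pos <- pos[sel]
  cand_d <- d[sel]
  recs <- list()
  for (p in sort(unique(cand_d))) {
    pp <- sort(cand_pos[cand_d == p])
    gaps <- c(Inf, diff(pp))
    grp <- cumsum(gaps > max(2 * p, 25))
    for (g in unique(grp)) {
      q <- pp[grp == g]
      span <- q[length(q)] - q[1] + p + k - 1
      # demand dense recurrence: true arrays recur at almost every offset
      if (length(q) < 4 || length(q) < 0.3 * (span - p)) next
      a <- q[1]
      b <- min(q[length(q)] + p + k - 1, n)
      # extend while the sequence stays p-periodic
      while (a > 1 && v[a - 1] == v[a - 1 + p]) a <- a - 1
      while (b < n && v[b + 1] == v[b + 1 - p]) b <- b + 1
      len <- b - a + 1
      if (len < 2 * p || len > 2 * L) next
      cons <- column_consensus(v[a:b], p)
      sc <- cpp_periodic_score(paste(v[a:b], collapse = ""), cons,
                               match, mismatch, indel)$score
      if (sc < min_score) next
      recs[[length(recs) + 1L]] <- data.frame(
        period = p, copy_number = round(len / p, 1), consensus = cons,
        score = sc, start = a, end = b, length = len,
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) return(empty_tandem())
  out <- do.call(rbind, recs)
  if (circular) out <- out[out$start <= L, , drop = FALSE]
  if (nrow(out) == 0) return(empty_tandem())
  # prefer high scores, then small (primitive) periods; drop records
  # largely overlapping an already kept record
  out <- out[order(-out$score, out$period, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (i == 1L || !keep[j]) next
      ov <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j]) + 1
      if (ov > 0.5 * min(out$length[i], out$length[j])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_tandem <- function() {
  data.frame(period = integer(0), copy_number = numeric(0),
             consensus = character(0), score = numeric(0),
             start = integer(0), end = integer(0), length = integer(0))
}

column_consensus <- function(chars, p) {
  col <- (seq_along(chars) - 1L) %% p
  cons <- vapply(0:(p - 1L), function(j) {
    tb <- table(chars[col == j])
    names(tb)[which.max(tb)]
  }, character(1))
  paste(cons, collapse = "")
}
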