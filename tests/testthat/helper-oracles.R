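# Independent oracles used to validate the scanners and the conformation
# surgery.  These are deliberately written from first principles (regex
# engine, fixed-string search, explicit cut-and-join), not via the
# package's own algorithms.

mod1_h <- function(x, L) ((x - 1) %% L) + 1

# --- SSR oracle: overlapped regex matches + left-maximality filter ------

oracle_ssrs <- function(s, minima = c(10, 5, 4, 3, 3, 3)) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  recs <- list()
  for (p in 1:6) {
    pat <- sprintf("(?=(([ACGT]{%d})\\2{%d,}))", p, minima[p] - 1)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(attr(m, "capture.start")[, 1])
    lens <- as.integer(attr(m, "capture.length")[, 1])
    for (h in seq_along(starts)) {
      i <- starts[h]
      len <- lens[h]
      # left-maximal: the array cannot be extended one base left
      if (i > 1) {
        prev <- v[i - 1]
        if (prev %in% c("A", "C", "G", "T") && prev == v[i - 1 + p]) next
      }
      motif <- substr(s, i, i + p - 1)
      if (!oracle_primitive(motif)) next
      recs[[length(recs) + 1L]] <- data.frame(
        motif = oracle_canonical(motif), unit_length = p,
        copy_number = len %/% p, start = i, end = i + len - 1L,
        length = len, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0)
    return(data.frame(motif = character(0), unit_length = integer(0),
                      copy_number = integer(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  out <- unique(do.call(rbind, recs))
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_primitive <- function(m) {
  p <- nchar(m)
  if (p == 1) return(TRUE)
  for (d in seq_len(p - 1)) {
    if (p %% d == 0 && m == strrep(substr(m, 1, d), p / d)) return(FALSE)
  }
  TRUE
}

oracle_canonical <- function(m) {
  p <- nchar(m)
  min(vapply(0:(p - 1), function(o)
    paste0(substr(m, o + 1, p), substr(m, 1, o)), character(1)))
}

# --- dispersed repeat oracle: fixed-string search + char-wise extension --

# All maximal exact repeated pairs of length >= min_len on a circle,
# direct and inverted, canonicalized to unordered pairs of start
# positions in [1, L].
oracle_dispersed <- function(s, min_len = 100) {
  L <- nchar(s)
  d <- paste0(s, s)
  v <- strsplit(d, "", fixed = TRUE)[[1]]
  cd <- function(i) v[mod1_h(i, L)]
  t <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(d)))
  w <- strsplit(t, "", fixed = TRUE)[[1]]
  ct <- function(i) w[mod1_h(i, L)]
  recs <- list()
  for (i in seq_len(L)) {
    pat <- substr(d, i, i + min_len - 1)
    # direct
    hits <- gregexpr(pat, d, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    for (j in hits) {
      if (mod1_h(j, L) == mod1_h(i, L)) next
      if (cd(i - 1) == cd(j - 1)) next        # not left-maximal
      len <- min_len
      while (len < L && cd(i + len) == cd(j + len)) len <- len + 1
      if (len >= L) next
      a <- mod1_h(i, L); b <- mod1_h(j, L)
      recs[[length(recs) + 1L]] <- data.frame(
        start1 = min(a, b), start2 = max(a, b), length = len,
        orientation = "direct", stringsAsFactors = FALSE)
    }
    # inverted
    hits <- gregexpr(pat, t, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    for (j in hits) {
      if (cd(i - 1) == ct(j - 1)) next
      len <- min_len
      while (len < L && cd(i + len) == ct(j + len)) len <- len + 1
      if (len >= L) next
      a <- mod1_h(i, L)
      b <- mod1_h(2 * L - (j + len - 1) + 1, L)  # map back from the rc frame
      if (a == b) next                        # palindrome on one locus
      recs[[length(recs) + 1L]] <- data.frame(
        start1 = min(a, b), start2 = max(a, b), length = len,
        orientation = "inverted", stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0)
    return(data.frame(start1 = integer(0), start2 = integer(0),
                      length = integer(0), orientation = character(0)))
  out <- unique(do.call(rbind, recs))
  out <- out[order(out$orientation, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- conformation surgery oracle: explicit cut-and-join ------------------

# Master written linearly as X1 R1 M R2 X2 (requires
# 1 <= s1 < e1 < s2 < e2 <= L, no wraparound).  Direct: circles R1+M and
# R2+X2+X1.  Inverted: X1 + R + rc(M) + R' + X2.
oracle_surgery <- function(gseq, s1, len, s2, orientation) {
  L <- nchar(gseq)
  e1 <- s1 + len - 1
  e2 <- s2 + len - 1
  stopifnot(s1 >= 1, e1 < s2, e2 <= L)
  X1 <- substr(gseq, 1, s1 - 1)
  R1 <- substr(gseq, s1, e1)
  M <- substr(gseq, e1 + 1, s2 - 1)
  R2 <- substr(gseq, s2, e2)
  X2 <- substr(gseq, e2 + 1, L)
  rc <- function(x) if (nchar(x)) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x))) else ""
  if (orientation == "direct") {
    list(A = paste0(R1, M), B = paste0(R2, X2, X1))
  } else {
    list(alt = paste0(X1, R1, rc(M), R2, X2))
  }
}

# substring test on a circular molecule (either strand)
in_circle <- function(needle, mol_seq) {
  dd <- paste0(mol_seq, mol_seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dd)))
  grepl(needle, dd, fixed = TRUE) || grepl(needle, rc, fixed = TRUE)
}

base_counts <- function(s) {
  tb <- table(strsplit(s, "", fixed = TRUE)[[1]])
  tb[order(names(tb))]
}

# random toy genome with planted repeat pair, no wraparound, well separated
toy_repeat_genome <- function(L, len, orientation, seed) {
  withr::with_seed(seed, {
    s1 <- sample(2:(L %/% 4), 1)
    s2 <- sample((L %/% 2):(L - 2 * len - 2), 1)
    spec <- sim_genome_spec(L, repeats = data.frame(
      length = len, start1 = s1, start2 = s2, orientation = orientation),
      seed = seed + 1)
    list(genome = build_genome(spec)$mito, s1 = s1, s2 = s2, len = len,
         pair = data.frame(id = "R1", length = len, start1 = s1,
                           start2 = s2, orientation = orientation))
  })
}
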