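#' @useDynLib mitorecomb, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rbinom rlnorm runif setNames
#' @importFrom utils write.table read.table
NULL

# Round half away from zero at `digits` decimals (reports use 2).
# base round() is banker's rounding, which a fraction table must not use.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage of num/den, 2 decimals half-up; NA when den == 0.
pct_of <- function(num, den, digits = 2) {
  ifelse(is.na(den) | den <= 0, NA_real_, round_half_up(100 * num / den, digits))
}

# Map a position onto 1..L (circular coordinates).
mod1 <- function(x, L) ((x - 1) %% L) + 1

# Split a circular interval (start, len) into one or two linear pieces on
# [1, L]; len >= L collapses to the whole circle.
circ_pieces <- function(start, len, L) {
  if (len <= 0) return(data.frame(start = integer(0), end = integer(0)))
  if (len >= L) return(data.frame(start = 1L, end = as.integer(L)))
  s <- mod1(start, L)
  e <- s + len - 1
  if (e <= L) {
    data.frame(start = as.integer(s), end = as.integer(e))
  } else {
    data.frame(start = as.integer(c(s, 1)), end = as.integer(c(L, e - L)))
  }
}

# Width of the union of circular intervals (vectors of starts and lengths).
circ_union_width <- function(starts, lens, L) {
  if (length(starts) == 0) return(0L)
  pieces <- do.call(rbind, Map(circ_pieces, starts, lens, MoreArgs = list(L = L)))
  ir <- IRanges::IRanges(start = pieces$start, end = pieces$end)
  sum(IRanges::width(IRanges::reduce(ir)))
}

# Do two circular intervals overlap?
circ_overlaps <- function(s1, l1, s2, l2, L) {
  a <- circ_pieces(s1, l1, L)
  b <- circ_pieces(s2, l2, L)
  ia <- IRanges::IRanges(start = a$start, end = a$end)
  ib <- IRanges::IRanges(start = b$start, end = b$end)
  length(IRanges::findOverlaps(ia, ib)) > 0
}

# Deterministic TSV writer: fixed column order, no quotes, no scientific
# notation, Unix newlines -- re-running a report must be byte-identical.
write_tsv <- function(df, path) {
  old <- options(scipen = 15)
  on.exit(options(old), add = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
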