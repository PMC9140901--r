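#' Circular (or linear) DNA sequence
#'
#' Lightweight container for a single DNA molecule with circular coordinate
#' semantics: every interval operation is allowed to wrap across the
#' origin when `topology = "circular"`.
#'
#' @param id character scalar, molecule identifier.
#' @param sequence character scalar over `A,C,G,T,N` (uppercased on input).
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `circular_seq` with fields `id`, `seq`,
#'   `length` and `topology`.
#' @examples
#' m <- circular_seq("toy", "ACGTACGTAA")
#' circ_substr(m, 9, 4)  # wraps across the origin: "AAAC"
#' @export
circular_seq <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence for molecule '", id, "'")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence of '", id, "' contains characters outside A,C,G,T,N")
  structure(list(id = id, seq = sequence, length = nchar(sequence),
                 topology = topology),
            class = "circular_seq")
}

#' @export
print.circular_seq <- function(x, ...) {
  cat(sprintf("<circular_seq> %s: %s molecule, %d bp\n",
              x$id, x$topology, x$length))
  invisible(x)
}

#' @export
length.circular_seq <- function(x) x$length

#' @export
as.character.circular_seq <- function(x, ...) x$seq

seq_of <- function(x) {
  if (inherits(x, "circular_seq")) x$seq else as.character(x)
}

#' Extract a substring with circular wraparound
#'
#' @param x a [circular_seq] or a character scalar (then assumed circular).
#' @param start 1-based start (any integer; mapped onto the circle).
#' @param len number of bases; must not exceed the molecule length.
#' @return character scalar of length `len`.
#' @export
circ_substr <- function(x, start, len) {
  s <- seq_of(x)
  L <- nchar(s)
  topo <- if (inherits(x, "circular_seq")) x$topology else "circular"
  if (len < 0) stop("negative substring length")
  if (len == 0) return("")
  if (len > L) stop("substring longer than the molecule (", len, " > ", L, ")")
  if (topo == "linear") {
    if (start < 1 || start + len - 1 > L)
      stop("interval outside a linear molecule")
    return(substr(s, start, start + len - 1))
  }
  st <- mod1(start, L)
  e <- st + len - 1
  if (e <= L) substr(s, st, e) else paste0(substr(s, st, L), substr(s, 1, e - L))
}

#' Rotate a circular sequence
#'
#' Moves the origin so that base `offset + 1` of `x` becomes base 1.
#' Repeat annotation on a circle must be invariant to this operation
#' (up to coordinate rotation).
#'
#' @param x a [circular_seq].
#' @param offset number of bases to rotate by.
#' @return a [circular_seq] of the same length.
#' @export
rotate_seq <- function(x, offset) {
  stopifnot(inherits(x, "circular_seq"))
  if (x$topology != "circular") stop("cannot rotate a linear molecule")
  L <- x$length
  off <- offset %% L
  if (off == 0) return(x)
  circular_seq(x$id, paste0(substr(x$seq, off + 1, L), substr(x$seq, 1, off)))
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar or [circular_seq].
#' @return character scalar.
#' @export
revcomp <- function(x) {
  s <- seq_of(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read the first record of a FASTA file as a circular sequence
#'
#' @param path FASTA file.
#' @param topology passed to [circular_seq()].
#' @return a [circular_seq].
#' @export
read_genome_fasta <- function(path, topology = "circular") {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path)
  nm <- strsplit(names(ss)[1], "\\s+")[[1]][1]
  circular_seq(nm, as.character(ss[[1]]), topology = topology)
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector (or list of [circular_seq]).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs)) {
    nm <- vapply(seqs, function(x) x$id, character(1))
    seqs <- setNames(vapply(seqs, seq_of, character(1)), nm)
  }
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
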