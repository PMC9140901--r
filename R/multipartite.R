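#' Infer the multipartite genome model from read support
#'
#' Repeats whose alternative-conformation support fraction reaches the
#' activity threshold are marked recombinationally active; for each
#' active repeat independently, the model lists the circles its
#' recombination generates (two subgenomic circles for a direct pair,
#' sizes summing to the master length; one inverted-segment circle for
#' an inverted pair).  When the copies of two active direct repeats
#' interleave on the master circle, simultaneous recombination products
#' are not enumerable pairwise and the model flags the combinatorial
#' ambiguity instead of resolving it.
#'
#' @param support a `read_support` table from [support_table()].
#' @param genome the master-circle [circular_seq].
#' @param pairs repeat-pair table covering every id in `support`.
#' @param activity_threshold percent alternative support at or above
#'   which a repeat is considered active (default 20).
#' @return An object of class `multipartite_model`: `master_length`,
#'   `active` (support rows of active repeats), `inactive`, `circles`
#'   (per active repeat: circle sizes and ordered segment intervals on
#'   the master), and `ambiguous` (logical).
#' @export
infer_multipartite <- function(support, genome, pairs,
                               activity_threshold = 20) {
  stopifnot(inherits(genome, "circular_seq"))
  missing_ids <- setdiff(support$id, pairs$id)
  if (length(missing_ids))
    stop("support rows without a repeat pair: ",
         paste(missing_ids, collapse = ", "))
  L <- genome$length
  act <- !is.na(support$frac_alt) & support$frac_alt >= activity_threshold
  active <- support[act, , drop = FALSE]
  inactive <- support[!act, , drop = FALSE]
  circles <- list()
  for (id in active$id) {
    p <- pairs[pairs$id == id, , drop = FALSE]
    len <- p$length
    s1 <- p$start1; s2 <- p$start2
    e1 <- s1 + len - 1
    if (p$orientation == "direct") {
      lenA <- (s2 - s1) %% L
      lenB <- L - lenA
      segA <- data.frame(
        start = c(mod1(s1, L), mod1(e1 + 1, L)),
        length = c(len, lenA - len),
        role = c("repeat_copy", "arc"), stringsAsFactors = FALSE)
      segB <- data.frame(
        start = c(mod1(s2, L), mod1(s2 + len, L)),
        length = c(len, lenB - len),
        role = c("repeat_copy", "arc"), stringsAsFactors = FALSE)
      circles[[id]] <- list(
        repeat_id = id, orientation = "direct",
        sizes = c(lenA, lenB),
        segments = list(A = segA[segA$length > 0, , drop = FALSE],
                        B = segB[segB$length > 0, , drop = FALSE]))
    } else {
      circles[[id]] <- list(
        repeat_id = id, orientation = "inverted", sizes = L,
        segments = list(inv = data.frame(
          start = mod1(e1 + 1, L), length = (s2 - 1 - e1) %% L,
          role = "inverted_segment", stringsAsFactors = FALSE)))
    }
  }
  ambiguous <- FALSE
  dir_ids <- active$id[vapply(active$id, function(id)
    pairs$orientation[pairs$id == id][1] == "direct", logical(1))]
  if (length(dir_ids) > 1) {
    for (i in seq_len(length(dir_ids) - 1)) {
      for (j in seq(i + 1, length(dir_ids))) {
        a <- pairs[pairs$id == dir_ids[i], ]
        b <- pairs[pairs$id == dir_ids[j], ]
        arc <- (a$start2 - a$start1) %% L
        in_arc <- function(x) ((x - a$start1) %% L) < arc
        if (in_arc(b$start1) != in_arc(b$start2)) ambiguous <- TRUE
      }
    }
  }
  if (ambiguous)
    warning("copies of two active direct repeats interleave; ",
            "pairwise circle products are reported but their joint ",
            "structure is combinatorially ambiguous")
  structure(list(master_length = L, activity_threshold = activity_threshold,
                 active = active, inactive = inactive, circles = circles,
                 ambiguous = ambiguous),
            class = "multipartite_model")
}

#' @export
print.multipartite_model <- function(x, ...) {
  cat(sprintf("<multipartite_model> master circle %d bp\n", x$master_length))
  if (nrow(x$active) == 0) {
    cat("  no recombinationally active repeats: master circle only\n")
  } else {
    for (id in x$active$id) {
      ci <- x$circles[[id]]
      fa <- x$active$frac_alt[x$active$id == id]
      if (ci$orientation == "direct") {
        cat(sprintf(
          "  %s (direct, %.2f%% alternative): subgenomic circles of %d and %d bp\n",
          id, fa, ci$sizes[1], ci$sizes[2]))
      } else {
        cat(sprintf(
          "  %s (inverted, %.2f%% alternative): inverted-segment circle, %d bp\n",
          id, fa, ci$sizes[1]))
      }
    }
  }
  if (nrow(x$inactive) > 0)
    cat(sprintf("  inactive repeats (< %.4g%%): %s\n", x$activity_threshold,
                paste(sprintf("%s (%.2f%%)", x$inactive$id,
                              x$inactive$frac_alt), collapse = ", ")))
  if (x$ambiguous)
    cat("  WARNING: active direct repeats interleave; joint structure ambiguous\n")
  invisible(x)
}

#' Serialize a multipartite model to JSON
#'
#' @param model a `multipartite_model`.
#' @param path output file.
#' @export
write_multipartite_json <- function(model, path) {
  obj <- list(
    master_length = model$master_length,
    activity_threshold = model$activity_threshold,
    ambiguous = model$ambiguous,
    active = model$active, inactive = model$inactive,
    circles = lapply(model$circles, function(ci)
      list(repeat_id = ci$repeat_id, orientation = ci$orientation,
           sizes = ci$sizes, segments = ci$segments)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write model segment intervals as GFF3
#'
#' @param model a `multipartite_model`.
#' @param path output file.
#' @param seqid sequence name for column 1.
#' @export
write_multipartite_gff3 <- function(model, path, seqid = "master") {
  lines <- c("##gff-version 3")
  L <- model$master_length
  for (id in names(model$circles)) {
    ci <- model$circles[[id]]
    for (nm in names(ci$segments)) {
      seg <- ci$segments[[nm]]
      for (i in seq_len(nrow(seg))) {
        pieces <- circ_pieces(seg$start[i], seg$length[i], L)
        for (r in seq_len(nrow(pieces))) {
          lines <- c(lines, paste(
            seqid, "mitorecomb", "region", pieces$start[r], pieces$end[r],
            ".", "+", ".",
            sprintf("ID=%s_%s_%d;Parent=%s;role=%s", id, nm, i, id,
                    seg$role[i]),
            sep = "\t"))
        }
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
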