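#' Specification of a synthetic circular mitogenome
#'
#' Describes a ground-truthed test genome: a circular molecule of given
#' length and GC composition carrying planted dispersed-repeat pairs
#' (direct or inverted) and plastid-derived segments (MTPT), plus a
#' companion circular plastid molecule.  Every planted feature is echoed
#' in a truth table so downstream detectors can be scored exactly.
#'
#' @param genome_length mitogenome length in bp.
#' @param repeats `NULL` or a data frame with columns `length`, `start1`,
#'   `start2`, `orientation` (`"direct"` or `"inverted"`); one row per
#'   planted repeat pair.  Coordinates are 1-based starts on the circle
#'   (wraparound allowed).
#' @param mtpts `NULL` or a data frame with columns `length` and
#'   `mito_start`: segments that will be present identically in the
#'   mitochondrial and plastid molecules.
#' @param plastid_length plastid molecule length in bp (0 = no plastid).
#' @param gc GC fraction of the i.i.d. background in `[0, 1]`.
#' @param seed integer seed governing the whole construction.
#' @return An object of class `sim_genome_spec`.
#' @export
sim_genome_spec <- function(genome_length, repeats = NULL, mtpts = NULL,
                            plastid_length = 0, gc = 0.45, seed = 1L) {
  stopifnot(genome_length > 0, gc >= 0, gc <= 1, plastid_length >= 0)
  L <- as.integer(genome_length)
  plants <- data.frame(what = character(0), start = integer(0),
                       len = integer(0))
  if (!is.null(repeats)) {
    stopifnot(all(c("length", "start1", "start2", "orientation") %in%
                    names(repeats)))
    if (any(repeats$length <= 0)) stop("repeat lengths must be positive")
    if (!all(repeats$orientation %in% c("direct", "inverted")))
      stop("repeat orientation must be 'direct' or 'inverted'")
    if (any(repeats$length > L)) stop("repeat longer than the genome")
    for (i in seq_len(nrow(repeats))) {
      plants <- rbind(plants,
        data.frame(what = sprintf("repeat %d copy 1", i),
                   start = repeats$start1[i], len = repeats$length[i]),
        data.frame(what = sprintf("repeat %d copy 2", i),
                   start = repeats$start2[i], len = repeats$length[i]))
    }
  }
  if (!is.null(mtpts)) {
    stopifnot(all(c("length", "mito_start") %in% names(mtpts)))
    if (any(mtpts$length <= 0)) stop("MTPT lengths must be positive")
    for (i in seq_len(nrow(mtpts)))
      plants <- rbind(plants,
        data.frame(what = sprintf("MTPT %d", i),
                   start = mtpts$mito_start[i], len = mtpts$length[i]))
  }
  # planted intervals must not collide on the circle
  n <- nrow(plants)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (circ_overlaps(plants$start[i], plants$len[i],
                        plants$start[j], plants$len[j], L)) {
        stop(sprintf(
          "planted intervals collide: %s [%d, %d bp] overlaps %s [%d, %d bp]",
          plants$what[i], plants$start[i], plants$len[i],
          plants$what[j], plants$start[j], plants$len[j]))
      }
    }
  }
  if (!is.null(mtpts) && nrow(mtpts) > 0) {
    if (plastid_length < 500 + sum(mtpts$length + 200))
      stop("plastid_length too small to host the planted MTPT segments")
  }
  structure(list(genome_length = L, repeats = repeats, mtpts = mtpts,
                 plastid_length = as.integer(plastid_length), gc = gc,
                 seed = as.integer(seed)),
            class = "sim_genome_spec")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

plant_into <- function(chars, start, replacement, L) {
  r <- strsplit(replacement, "", fixed = TRUE)[[1]]
  pos <- mod1(start + seq_along(r) - 1, L)
  chars[pos] <- r
  chars
}

#' Build a synthetic mitogenome (and plastid) with planted ground truth
#'
#' The mitochondrial background is i.i.d. at the specified GC fraction;
#' repeat pairs are planted by copying the first copy's sequence to the
#' second copy's coordinates (reverse-complemented for inverted pairs),
#' and each MTPT segment is copied from the mitochondrial molecule into
#' the plastid molecule so that both carry it identically.
#'
#' @param spec a [sim_genome_spec()].
#' @return A list with elements `mito` ([circular_seq]), `plastid`
#'   ([circular_seq] or `NULL`) and `truth` (list of data frames
#'   `repeats` and `mtpts` with 1-based inclusive coordinates; `end`
#'   may exceed the molecule length for intervals wrapping the origin).
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_genome_spec"))
  L <- spec$genome_length
  withr::with_seed(spec$seed, {
    chars <- strsplit(random_dna(L, spec$gc), "", fixed = TRUE)[[1]]
    rep_truth <- NULL
    if (!is.null(spec$repeats) && nrow(spec$repeats) > 0) {
      rp <- spec$repeats
      ord <- order(-rp$length, rp$start1)
      rp <- rp[ord, , drop = FALSE]
      for (i in seq_len(nrow(rp))) {
        len <- rp$length[i]
        copy1 <- paste(chars[mod1(rp$start1[i] + 0:(len - 1), L)],
                       collapse = "")
        planted <- if (rp$orientation[i] == "inverted") revcomp(copy1) else copy1
        chars <- plant_into(chars, rp$start2[i], planted, L)
      }
      rep_truth <- data.frame(
        id = sprintf("R%d", seq_len(nrow(rp))),
        length = rp$length,
        start1 = mod1(rp$start1, L), end1 = mod1(rp$start1, L) + rp$length - 1,
        start2 = mod1(rp$start2, L), end2 = mod1(rp$start2, L) + rp$length - 1,
        orientation = rp$orientation,
        stringsAsFactors = FALSE)
    }
    mito_seq <- paste(chars, collapse = "")
    plastid <- NULL
    mtpt_truth <- NULL
    if (spec$plastid_length > 0) {
      pchars <- strsplit(random_dna(spec$plastid_length, spec$gc), "",
                         fixed = TRUE)[[1]]
      if (!is.null(spec$mtpts) && nrow(spec$mtpts) > 0) {
        mt <- spec$mtpts
        p_start <- integer(nrow(mt))
        cursor <- 501L  # spaced placements on the plastid, fixed layout
        for (i in seq_len(nrow(mt))) {
          p_start[i] <- cursor
          seg <- paste(strsplit(mito_seq, "", fixed = TRUE)[[1]][
            mod1(mt$mito_start[i] + 0:(mt$length[i] - 1), L)], collapse = "")
          pchars <- plant_into(pchars, p_start[i], seg, spec$plastid_length)
          cursor <- cursor + mt$length[i] + 200L
        }
        mtpt_truth <- data.frame(
          id = sprintf("P%d", seq_len(nrow(mt))),
          length = mt$length,
          mito_start = mod1(mt$mito_start, L),
          mito_end = mod1(mt$mito_start, L) + mt$length - 1,
          plastid_start = p_start,
          plastid_end = p_start + mt$length - 1,
          stringsAsFactors = FALSE)
      }
      plastid <- circular_seq(sprintf("plastid_sim seed=%d", spec$seed),
                              paste(pchars, collapse = ""))
    }
    mito <- circular_seq(sprintf("mito_sim seed=%d", spec$seed), mito_seq)
    list(mito = mito, plastid = plastid,
         truth = list(repeats = rep_truth, mtpts = mtpt_truth))
  })
}

#' Specification of a long-read simulation
#'
#' @param weights named numeric vector of conformation probabilities
#'   (must sum to 1); names are `"master"` and/or ids of conformation
#'   sets passed to [simulate_reads()].
#' @param n_reads number of reads.
#' @param meanlog,sdlog log-normal read-length parameters (bp); lengths
#'   are floored at 200 bp so reads can span repeat flanks.
#' @param sub_rate,ins_rate,del_rate per-base error probabilities, each
#'   in `[0, 0.2]`.
#' @param seed integer seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(weights = c(master = 1), n_reads = 1000,
                          meanlog = log(20000), sdlog = 0.6,
                          sub_rate = 0, ins_rate = 0, del_rate = 0,
                          seed = 1L) {
  stopifnot(n_reads > 0, !is.null(names(weights)), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8)
    stop("conformation weights must sum to 1")
  for (r in c(sub_rate, ins_rate, del_rate))
    if (r < 0 || r > 0.2) stop("error rates must lie in [0, 0.2]")
  structure(list(weights = weights, n_reads = as.integer(n_reads),
                 meanlog = meanlog, sdlog = sdlog, sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

mutate_read <- function(s, sub, ins, del) {
  if (sub <= 0 && ins <= 0 && del <= 0) return(s)
  n <- nchar(s)
  bases <- c("A", "C", "G", "T")
  sub_pos <- integer(0); sub_base <- character(0)
  if (sub > 0) {
    m <- rbinom(1L, n, sub)
    if (m > 0) {
      sub_pos <- sample.int(n, m)
      cur <- substring(s, sub_pos, sub_pos)
      idx <- match(cur, bases)
      off <- sample.int(3, m, replace = TRUE)
      sub_base <- bases[(idx - 1 + off) %% 4 + 1]
      sub_base[is.na(idx)] <- cur[is.na(idx)]  # leave ambiguous bases alone
    }
  }
  del_pos <- if (del > 0) {
    nd <- rbinom(1L, n, del)
    if (nd > 0) sample.int(n, nd) else integer(0)
  } else integer(0)
  ins_pos <- integer(0); ins_base <- character(0)
  if (ins > 0) {
    ni <- rbinom(1L, n, ins)
    if (ni > 0) {
      ins_pos <- sample.int(n, ni)
      ins_base <- bases[sample.int(4, ni, replace = TRUE)]
    }
  }
  cpp_apply_edits(s, sub_pos, sub_base, del_pos, ins_pos, ins_base)
}

#' Simulate long reads from a mixture of genome conformations
#'
#' Reads are drawn from the master circle and/or from the alternative
#' conformations mediated by dispersed repeat pairs (see
#' [conformation_molecules()]); each read records the conformation and
#' molecule it came from.  Read origins are uniform on the chosen
#' circular molecule (`focus = "uniform"`), or uniform over windows
#' upstream of the repeat junctions (`focus = "junctions"`), which
#' emulates the pool of junction-spanning reads used for conformation
#' support counting.
#'
#' @param genome the master-circle [circular_seq].
#' @param confs list of conformation sets from [enumerate_conformations()]
#'   (may be `NULL` when only the master circle is sampled).
#' @param spec a [read_sim_spec()].
#' @param focus `"uniform"` or `"junctions"`.
#' @param focus_window bp; junction windows extend this far upstream of
#'   each repeat copy.
#' @return A data frame of class `simulated_reads` with columns `id`,
#'   `true_conformation`, `molecule`, `start`, `length`, `strand`,
#'   `wrapped`, `sequence`.  Reads longer than their molecule are
#'   truncated to one full wrap and flagged.
#' @export
simulate_reads <- function(genome, confs = NULL, spec,
                           focus = c("uniform", "junctions"),
                           focus_window = 3000) {
  stopifnot(inherits(genome, "circular_seq"), inherits(spec, "read_sim_spec"))
  focus <- match.arg(focus)
  if (!is.null(confs) && inherits(confs, "conformation_set"))
    confs <- list(confs)
  conf_ids <- if (is.null(confs)) character(0) else
    vapply(confs, function(cs) cs$id, character(1))
  unknown <- setdiff(names(spec$weights), c("master", conf_ids))
  if (length(unknown))
    stop("weights refer to unknown conformations: ",
         paste(unknown, collapse = ", "))
  # molecule sets per conformation id
  sets <- list()
  master_anchors <- integer(0)
  if (!is.null(confs)) {
    for (cs in confs)
      master_anchors <- c(master_anchors, cs$pair$start1, cs$pair$start2)
  }
  if (length(master_anchors) == 0) master_anchors <- 1L
  sets[["master"]] <- list(
    mols = list(genome),
    anchors = data.frame(mol = 1L, pos = as.integer(master_anchors)))
  if (!is.null(confs)) {
    for (cs in confs) {
      cm <- conformation_molecules(genome, cs$pair)
      sets[[cs$id]] <- list(mols = cm$molecules, anchors = cm$anchors)
    }
  }
  withr::with_seed(spec$seed, {
    n <- spec$n_reads
    conf_choice <- if (length(spec$weights) == 1L)
      rep(names(spec$weights), n)
    else
      sample(names(spec$weights), n, replace = TRUE, prob = spec$weights)
    lens <- pmax(200L, as.integer(round(rlnorm(n, spec$meanlog, spec$sdlog))))
    mol_pick <- integer(n)
    start <- integer(n)
    wrapped <- logical(n)
    for (i in seq_len(n)) {             # placement draws (cheap RNG pass)
      st <- sets[[conf_choice[i]]]
      nm <- length(st$mols)
      mi <- if (nm == 1L) 1L else {
        sz <- vapply(st$mols, function(m) m$length, numeric(1))
        sample.int(nm, 1L, prob = sz)
      }
      mol_pick[i] <- mi
      Lm <- st$mols[[mi]]$length
      if (lens[i] > Lm) { lens[i] <- Lm; wrapped[i] <- TRUE }
      if (focus == "uniform") {
        start[i] <- sample.int(Lm, 1L)
      } else {
        anc <- st$anchors[st$anchors$mol == mi, , drop = FALSE]
        if (nrow(anc) == 0) anc <- data.frame(mol = mi, pos = 1L)
        a <- anc$pos[sample.int(nrow(anc), 1L)]
        lo <- 150L
        hi <- max(lo + 1L, as.integer(focus_window))
        start[i] <- mod1(a - (sample.int(hi - lo + 1L, 1L) + lo - 1L), Lm)
      }
    }
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    seqs <- character(n)
    mol_ids <- character(n)
    for (i in seq_len(n)) {             # extraction (no RNG)
      mol <- sets[[conf_choice[i]]]$mols[[mol_pick[i]]]
      mol_ids[i] <- mol$id
      seqs[i] <- circ_substr(mol, start[i], lens[i])
    }
    neg <- which(strand == "-")
    if (length(neg))
      seqs[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[neg])))
    if (spec$sub_rate > 0 || spec$ins_rate > 0 || spec$del_rate > 0)
      for (i in seq_len(n))             # error draws, in read order
        seqs[i] <- mutate_read(seqs[i], spec$sub_rate, spec$ins_rate,
                               spec$del_rate)
    res <- data.frame(
      id = sprintf("read%05d", seq_len(n)),
      true_conformation = conf_choice, molecule = mol_ids,
      start = start, length = lens, strand = strand, wrapped = wrapped,
      sequence = seqs, stringsAsFactors = FALSE)
    class(res) <- c("simulated_reads", "data.frame")
    res
  })
}

#' Write simulated reads to FASTA (or FASTQ with constant qualities)
#'
#' @param reads a `simulated_reads` data frame.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_reads_fasta <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  hdr <- sprintf("%s conf=%s mol=%s start=%d strand=%s",
                 reads$id, reads$true_conformation, reads$molecule,
                 reads$start, reads$strand)
  if (format == "fasta") {
    write_fasta(setNames(reads$sequence, hdr), path)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    qual <- vapply(nchar(reads$sequence),
                   function(n) strrep("I", n), character(1))
    writeLines(paste0("@", hdr, "\n", reads$sequence, "\n+\n", qual),
               con, sep = "\n")
  }
  invisible(path)
}

#' Write the planted-feature truth tables of a synthetic genome
#'
#' @param truth the `truth` element returned by [build_genome()].
#' @param dir output directory (created if needed).
#' @return Paths of the files written.
#' @export
write_truth_tsv <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(truth$repeats)) {
    p <- file.path(dir, "truth_repeats.tsv")
    write_tsv(truth$repeats, p)
    paths <- c(paths, p)
  }
  if (!is.null(truth$mtpts)) {
    p <- file.path(dir, "truth_mtpts.tsv")
    write_tsv(truth$mtpts, p)
    paths <- c(paths, p)
  }
  paths
}
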