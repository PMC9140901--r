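# --- SSRs ----------------------------------------------------------------

test_that("SSR minimum copy numbers act as exact boundaries", {
  lin <- function(s) circular_seq("t", s, topology = "linear")
  r10 <- find_ssrs(lin(paste0("CT", strrep("A", 10), "GT")))
  expect_equal(nrow(r10), 1)
  expect_equal(r10$motif, "A")
  expect_equal(r10$copy_number, 10)
  expect_equal(c(r10$start, r10$end), c(3, 12))

  expect_equal(nrow(find_ssrs(lin(paste0("CT", strrep("A", 9), "GT")))), 0)

  r4 <- find_ssrs(lin(paste0("TT", strrep("ACG", 4), "TT")))
  expect_equal(nrow(r4), 1)
  expect_equal(r4$unit_length, 3)
  expect_equal(r4$copy_number, 4)
})

test_that("N runs are never part of an SSR and motifs are canonical", {
  lin <- function(s) circular_seq("t", s, topology = "linear")
  expect_equal(nrow(find_ssrs(lin(strrep("N", 30)))), 0)
  # array written in a non-canonical phase
  r <- find_ssrs(lin(paste0("CC", strrep("GA", 6), "CC")))
  expect_equal(r$motif, "AG")
})

test_that("SSR scanner matches the regex oracle on random sequences with planted arrays", {
  withr::with_seed(404, {
    for (rep in 1:3) {
      v <- strsplit(mitorecomb:::random_dna(50000, 0.45), "",
                    fixed = TRUE)[[1]]
      plants <- list(strrep("A", 11), strrep("AT", 6), strrep("CTG", 5),
                     strrep("ACGT", 3), strrep("AACGT", 3),
                     strrep("ACGTC", 4))
      at <- seq(1000, by = 7000, length.out = length(plants))
      for (i in seq_along(plants)) {
        p <- strsplit(plants[[i]], "", fixed = TRUE)[[1]]
        v[at[i] + seq_along(p) - 1] <- p
      }
      s <- paste(v, collapse = "")
      got <- find_ssrs(circular_seq("t", s, topology = "linear"))
      want <- oracle_ssrs(s)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
      expect_gte(nrow(got), length(plants))
    }
  })
})

test_that("SSR detection wraps the circular origin", {
  # 12 A's straddling the origin: 6 at each end
  s <- paste0(strrep("A", 6), mitorecomb:::random_dna(200, 0.5), "C",
              strrep("A", 6))
  withr::with_seed(1, s <- paste0(strrep("A", 6),
                                  gsub("^A+|A+$", "C",
                                       mitorecomb:::random_dna(200, 0.5)),
                                  strrep("A", 6)))
  g <- circular_seq("t", s)
  r <- find_ssrs(g)
  wrap <- r[r$motif == "A" & r$copy_number >= 12, , drop = FALSE]
  expect_equal(nrow(wrap), 1)
  expect_gt(wrap$end, g$length)  # wrapped record, end beyond the origin
})

# --- tandem repeats ------------------------------------------------------

test_that("tandem scoring follows the match/mismatch/indel convention", {
  lin <- function(s) circular_seq("t", s, topology = "linear")
  pad1 <- "CGGTCAGGCTTCAAGCCTGACCGCGTTAAGCGTGCACGTG"
  pad2 <- "TGCACGTTAACGCGGTCAGGCTTGAAGCCTGACCGACGTG"
  r <- find_tandem_repeats(lin(paste0(pad1, strrep("AT", 30), pad2)))
  expect_equal(nrow(r), 1)
  expect_equal(r$period, 2)
  expect_equal(r$score, 120)           # 2 x 60 perfect bases
  expect_equal(r$copy_number, 30)

  # 12 copies score 48 < 50: below the reporting threshold
  r2 <- find_tandem_repeats(lin(paste0(pad1, strrep("AT", 12), pad2)))
  expect_equal(nrow(r2), 0)

  # one substitution inside an array: 2*(len-1) - 7
  arr <- strrep("ACGTT", 20)
  substr(arr, 48, 48) <- "A"
  r3 <- find_tandem_repeats(lin(paste0(pad1, arr, pad2)))
  expect_equal(nrow(r3), 1)
  expect_equal(r3$score, 2 * 99 - 7)
})

test_that("arrays with period above the maximum are excluded", {
  withr::with_seed(7, {
    unit <- mitorecomb:::random_dna(600, 0.5)
    s <- paste0(mitorecomb:::random_dna(100, 0.5), strrep(unit, 3),
                mitorecomb:::random_dna(100, 0.5))
  })
  r <- find_tandem_repeats(circular_seq("t", s, topology = "linear"))
  expect_true(nrow(r[r$period > 500, , drop = FALSE]) == 0)
  # the same array is reported once the ceiling admits its period
  r2 <- find_tandem_repeats(circular_seq("t", s, topology = "linear"),
                            max_period = 600)
  expect_true(any(r2$period == 600 & r2$copy_number >= 3))
})

# --- dispersed repeats ---------------------------------------------------

test_that("planted pairs are recovered with correct orientation; short ones are not", {
  t1 <- toy_repeat_genome(1000, 150, "direct", 31)
  r1 <- find_dispersed_repeats(t1$genome, min_len = 100, min_identity = 1)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$orientation, "direct")
  expect_gte(r1$length, 150)

  t2 <- toy_repeat_genome(1000, 150, "inverted", 32)
  r2 <- find_dispersed_repeats(t2$genome, min_len = 100, min_identity = 1)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$orientation, "inverted")

  t3 <- toy_repeat_genome(2000, 99, "direct", 33)
  r3 <- find_dispersed_repeats(t3$genome, min_len = 100, min_identity = 1)
  expect_equal(nrow(r3), 0)
})

test_that("dispersed repeat finder matches the exact-pair oracle on toy circles", {
  for (seed in c(101, 102, 103)) {
    t1 <- toy_repeat_genome(3000, 180, if (seed %% 2) "direct" else
      "inverted", seed)
    got <- find_dispersed_repeats(t1$genome, min_len = 100, min_identity = 1)
    want <- oracle_dispersed(t1$genome$seq, min_len = 100)
    got_k <- got[order(got$orientation, got$start1, got$start2),
                 c("start1", "start2", "length", "orientation")]
    rownames(got_k) <- rownames(want) <- NULL
    expect_equal(got_k, want)
  }
})

test_that("pairs wrapping the circular origin are found", {
  spec <- sim_genome_spec(3000, repeats = data.frame(
    length = 200, start1 = 2950, start2 = 1501, orientation = "direct"),
    seed = 9)
  g <- build_genome(spec)$mito
  r <- find_dispersed_repeats(g, min_len = 100, min_identity = 1)
  expect_equal(nrow(r), 1)
  expect_gte(r$length, 200)
  # one copy straddles the origin
  expect_true(any(r$end1 > 3000 | r$end2 > 3000 |
                    (r$start1 <= 2950 & 2950 <= r$end1) |
                    (r$start2 <= 2950 & 2950 <= r$end2)))
})

test_that("rotating the circle rotates repeat coordinates but nothing else", {
  t1 <- toy_repeat_genome(2500, 150, "direct", 55)
  base <- find_dispersed_repeats(t1$genome, min_len = 100, min_identity = 1)
  L <- t1$genome$length
  for (off in c(13, 1207)) {
    rot <- find_dispersed_repeats(rotate_seq(t1$genome, off),
                                  min_len = 100, min_identity = 1)
    expect_equal(nrow(rot), nrow(base))
    expect_equal(sort(rot$length), sort(base$length))
    starts_rot <- sort(c(mitorecomb:::mod1(base$start1 - off, L),
                         mitorecomb:::mod1(base$start2 - off, L)))
    expect_equal(sort(c(rot$start1, rot$start2)), starts_rot)
  }
})
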