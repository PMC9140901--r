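test_that("planted repeat copies are exact (direct) or reverse complements (inverted)", {
  spec <- sim_genome_spec(1000, repeats = data.frame(
    length = 50, start1 = 1, start2 = 401, orientation = "direct"), seed = 7)
  b <- build_genome(spec)
  g <- b$mito
  expect_equal(g$length, 1000)
  expect_equal(circ_substr(g, 1, 50), circ_substr(g, 401, 50))
  tr <- b$truth$repeats
  expect_equal(tr$start1, 1)
  expect_equal(tr$start2, 401)

  spec2 <- sim_genome_spec(1000, repeats = data.frame(
    length = 50, start1 = 1, start2 = 401, orientation = "inverted"),
    seed = 7)
  g2 <- build_genome(spec2)$mito
  expect_equal(circ_substr(g2, 401, 50), revcomp(circ_substr(g2, 1, 50)))
})

test_that("genome length is exact at the emulated mitogenome scale", {
  spec <- sim_genome_spec(380980, repeats = data.frame(
    length = c(5616, 4148, 283),
    start1 = c(1, 30846, 264966),
    start2 = c(265249, 305624, 380698),
    orientation = "direct"), seed = 1)
  g <- build_genome(spec)$mito
  expect_equal(g$length, 380980)
  expect_equal(circ_substr(g, 265249, 5616), circ_substr(g, 1, 5616))
})

test_that("colliding planted intervals are rejected with the interval names", {
  expect_error(
    sim_genome_spec(1000, repeats = data.frame(
      length = 100, start1 = 1, start2 = 50, orientation = "direct")),
    "collide.*copy 1.*copy 2")
  expect_error(
    sim_genome_spec(1000, repeats = data.frame(
      length = 100, start1 = 1, start2 = 500, orientation = "direct"),
      mtpts = data.frame(length = 50, mito_start = 520),
      plastid_length = 2000),
    "collide")
})

test_that("construction is deterministic: same spec and seed give identical FASTA", {
  spec <- sim_genome_spec(5000, repeats = data.frame(
    length = 200, start1 = 101, start2 = 2001, orientation = "direct"),
    mtpts = data.frame(length = 300, mito_start = 4001),
    plastid_length = 2000, seed = 13)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(f1, f2)))
  b1 <- build_genome(spec); b2 <- build_genome(spec)
  write_fasta(list(b1$mito, b1$plastid), f1)
  write_fasta(list(b2$mito, b2$plastid), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("truth intervals re-extract the planted sequences exactly", {
  spec <- sim_genome_spec(10000, repeats = data.frame(
    length = c(300, 150), start1 = c(101, 4001), start2 = c(2001, 9950),
    orientation = c("direct", "inverted")),
    mtpts = data.frame(length = c(115, 887), mito_start = c(6001, 7001)),
    plastid_length = 5000, seed = 5)
  b <- build_genome(spec)
  tr <- b$truth$repeats
  for (i in seq_len(nrow(tr))) {
    c1 <- circ_substr(b$mito, tr$start1[i], tr$length[i])
    c2 <- circ_substr(b$mito, tr$start2[i], tr$length[i])
    if (tr$orientation[i] == "direct") expect_equal(c2, c1)
    else expect_equal(c2, revcomp(c1))
  }
  mt <- b$truth$mtpts
  for (i in seq_len(nrow(mt))) {
    expect_equal(circ_substr(b$plastid, mt$plastid_start[i], mt$length[i]),
                 circ_substr(b$mito, mt$mito_start[i], mt$length[i]))
  }
})

test_that("zero-error pure-master reads are exact substrings of the circle", {
  spec <- sim_genome_spec(5000, seed = 3)
  g <- build_genome(spec)$mito
  rspec <- read_sim_spec(weights = c(master = 1), n_reads = 100,
                         meanlog = log(600), sdlog = 0.4, seed = 4)
  reads <- simulate_reads(g, NULL, rspec)
  dd <- paste0(g$seq, g$seq)
  rc <- revcomp(dd)
  hit <- vapply(reads$sequence, function(s)
    grepl(s, dd, fixed = TRUE) || grepl(s, rc, fixed = TRUE), logical(1))
  expect_true(all(hit))
  expect_true(all(nchar(reads$sequence) >= 200))
})

test_that("read simulation is deterministic and respects mixture weights", {
  spec <- sim_genome_spec(20000, repeats = data.frame(
    length = 500, start1 = 1001, start2 = 10001, orientation = "direct"),
    seed = 9)
  g <- build_genome(spec)$mito
  pair <- data.frame(id = "R1", length = 500, start1 = 1001, start2 = 10001,
                     orientation = "direct")
  cs <- enumerate_conformations(g, pair, F = 300)
  rspec <- read_sim_spec(weights = c(master = 0.5, R1 = 0.5), n_reads = 2000,
                         meanlog = log(600), sdlog = 0.4, seed = 11)
  r1 <- simulate_reads(g, list(cs), rspec)
  r2 <- simulate_reads(g, list(cs), rspec)
  expect_identical(r1, r2)
  n_ac <- sum(r1$true_conformation == "R1")
  # 99% binomial band around 1000
  expect_gte(n_ac, qbinom(0.005, 2000, 0.5))
  expect_lte(n_ac, qbinom(0.995, 2000, 0.5))
})

test_that("label frequencies converge to the weights (chi-square, n = 10000)", {
  spec <- sim_genome_spec(2000, seed = 2)
  g <- build_genome(spec)$mito
  pair <- data.frame(id = "R1", length = 100, start1 = 101, start2 = 1001,
                     orientation = "direct")
  # weights over master and one alternative conformation
  w <- c(master = 0.6, R1 = 0.4)
  rspec <- read_sim_spec(weights = w, n_reads = 10000,
                         meanlog = log(250), sdlog = 0.2, seed = 21)
  reads <- simulate_reads(g, list(enumerate_conformations(g, pair, F = 50)),
                          rspec)
  tab <- table(factor(reads$true_conformation, levels = names(w)))
  p <- suppressWarnings(chisq.test(tab, p = w)$p.value)
  expect_gt(p, 0.01)
})

test_that("read errors land within the Poisson bound on edit distance", {
  spec <- sim_genome_spec(30000, seed = 6)
  g <- build_genome(spec)$mito
  rspec <- read_sim_spec(weights = c(master = 1), n_reads = 5,
                         meanlog = log(5000), sdlog = 0.1,
                         sub_rate = 0.05, ins_rate = 0.01, del_rate = 0.01,
                         seed = 8)
  reads <- simulate_reads(g, NULL, rspec)
  for (i in seq_len(nrow(reads))) {
    origin <- circ_substr(g, reads$start[i], reads$length[i])
    if (reads$strand[i] == "-") origin <- revcomp(origin)
    d <- utils::adist(reads$sequence[i], origin)[1, 1]
    lambda <- 0.07 * reads$length[i]
    expect_lte(d, qpois(0.9995, lambda))
    expect_gte(d, qpois(0.0005, lambda) * 0.8)  # slack for cancelling edits
  }
})

test_that("reads longer than the molecule are truncated to one wrap and flagged", {
  spec <- sim_genome_spec(400, seed = 14)
  g <- build_genome(spec)$mito
  rspec <- read_sim_spec(weights = c(master = 1), n_reads = 20,
                         meanlog = log(1000), sdlog = 0.1, seed = 15)
  reads <- simulate_reads(g, NULL, rspec)
  expect_true(all(reads$length <= 400))
  expect_true(any(reads$wrapped))
  expect_true(all(nchar(reads$sequence[reads$wrapped]) == 400))
})

test_that("invalid read-sim specifications are rejected", {
  expect_error(read_sim_spec(weights = c(master = 0.7, R1 = 0.5)), "sum to 1")
  expect_error(read_sim_spec(weights = c(master = 1), sub_rate = 0.5),
               "rates")
  expect_error(read_sim_spec(weights = c(master = 1), n_reads = 0))
})
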