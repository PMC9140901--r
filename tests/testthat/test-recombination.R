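# --- conformation enumeration and surgery --------------------------------

test_that("a direct pair splits the circle into subcircles of the expected sizes", {
  spec <- sim_genome_spec(1000, repeats = data.frame(
    length = 50, start1 = 1, start2 = 401, orientation = "direct"), seed = 7)
  g <- build_genome(spec)$mito
  pair <- data.frame(id = "R1", length = 50, start1 = 1, start2 = 401,
                     orientation = "direct")
  cm <- conformation_molecules(g, pair)
  expect_equal(sort(vapply(cm$molecules, function(m) m$length, numeric(1))),
               c(400, 600))
})

test_that("an inverted pair conserves molecule length", {
  t1 <- toy_repeat_genome(1200, 80, "inverted", 71)
  cm <- conformation_molecules(t1$genome, t1$pair)
  expect_equal(length(cm$molecules), 1L)
  expect_equal(cm$molecules[[1]]$length, 1200)
})

test_that("junction references are exact substrings of the surgery-oracle molecules", {
  for (seed in 201:225) {
    orientation <- if (seed %% 2) "direct" else "inverted"
    t1 <- toy_repeat_genome(2000, 120, orientation, seed)
    cs <- enumerate_conformations(t1$genome, t1$pair, F = 200)
    cm <- conformation_molecules(t1$genome, t1$pair)
    orc <- oracle_surgery(t1$genome$seq, t1$s1, t1$len, t1$s2, orientation)
    # master junctions live on the master circle
    for (j in cs$master_junctions)
      expect_true(in_circle(j, t1$genome$seq))
    # alternative junctions live on the oracle's recombinant molecules
    alt_mols <- unlist(orc)
    for (j in cs$alt_junctions)
      expect_true(any(vapply(alt_mols, in_circle, logical(1),
                             needle = j)))
    # and the package surgery agrees with the oracle up to rotation/strand
    for (m in cm$molecules) {
      hit <- any(vapply(alt_mols, function(om)
        nchar(om) == m$length && in_circle(circ_substr(m, 1, m$length), om),
        logical(1)))
      expect_true(hit)
    }
  }
})

test_that("alternative conformations conserve the base content of the master", {
  # direct: across both subcircles; inverted: as a double-stranded molecule
  t1 <- toy_repeat_genome(1500, 100, "direct", 301)
  cm <- conformation_molecules(t1$genome, t1$pair)
  expect_equal(base_counts(paste0(cm$molecules[[1]]$seq,
                                  cm$molecules[[2]]$seq)),
               base_counts(t1$genome$seq))
  t2 <- toy_repeat_genome(1500, 100, "inverted", 302)
  cm2 <- conformation_molecules(t2$genome, t2$pair)
  alt <- cm2$molecules[[1]]$seq
  expect_equal(base_counts(paste0(alt, revcomp(alt))),
               base_counts(paste0(t2$genome$seq, revcomp(t2$genome$seq))))
})

test_that("overlapping repeat copies are rejected", {
  g <- circular_seq("t", mitorecomb:::random_dna(1000, 0.5))
  pair <- data.frame(id = "R1", length = 200, start1 = 101, start2 = 201,
                     orientation = "direct")
  expect_error(enumerate_conformations(g, pair), "overlap")
  expect_error(conformation_molecules(g, pair), "overlap")
})

# --- read classification -------------------------------------------------

test_that("error-free junction-spanning reads classify by conformation", {
  spec <- sim_genome_spec(4000, repeats = data.frame(
    length = 300, start1 = 501, start2 = 2501, orientation = "direct"),
    seed = 41)
  g <- build_genome(spec)$mito
  pair <- data.frame(id = "R1", length = 300, start1 = 501, start2 = 2501,
                     orientation = "direct")
  cs <- enumerate_conformations(g, pair, F = 500)
  cm <- conformation_molecules(g, pair)
  # master order around copy 1
  expect_equal(classify_read(circ_substr(g, 1, 1300), cs), "master")
  # reverse strand is handled
  expect_equal(classify_read(revcomp(circ_substr(g, 1, 1300)), cs), "master")
  # recombinant join on each subcircle
  for (m in cm$molecules)
    expect_equal(classify_read(circ_substr(m, -499, 1300), cs),
                 "alternative")
  # read inside the repeat: consistent with every junction
  expect_equal(classify_read(circ_substr(g, 551, 200), cs, anchor = 50,
                             k = 11), "uninformative")
  # read touching one flank only
  expect_equal(classify_read(circ_substr(g, 400, 450), cs), "uninformative")
  # empty read
  expect_equal(classify_read("", cs), "uninformative")
})

test_that("a 50/50 mixture at 5% read error is recovered within 5 points", {
  spec <- sim_genome_spec(60000, repeats = data.frame(
    length = 2000, start1 = 10001, start2 = 40001, orientation = "direct"),
    seed = 51)
  g <- build_genome(spec)$mito
  pair <- data.frame(id = "R1", length = 2000, start1 = 10001,
                     start2 = 40001, orientation = "direct")
  cs <- enumerate_conformations(g, pair, F = 1000)
  rspec <- read_sim_spec(weights = c(master = 0.5, R1 = 0.5), n_reads = 2000,
                         meanlog = log(6000), sdlog = 0.4,
                         sub_rate = 0.025, ins_rate = 0.0125,
                         del_rate = 0.0125, seed = 52)
  reads <- simulate_reads(g, list(cs), rspec, focus = "junctions")
  cl <- classify_reads(reads, cs)
  st <- support_table(list(R1 = cl$label))
  expect_gt(st$n_master + st$n_alt, 500)
  expect_lt(abs(st$frac_alt - 50), 5)
  # classifications rarely contradict the simulated truth
  informative <- cl$label != "uninformative"
  truth_label <- ifelse(reads$true_conformation == "master", "master",
                        "alternative")
  agree <- mean(cl$label[informative] == truth_label[informative])
  expect_gt(agree, 0.98)
})

# --- support tables ------------------------------------------------------

test_that("support fractions follow the two-decimal half-up rule", {
  expect_equal(support_fractions(40, 48),
               list(frac_master = 45.45, frac_alt = 54.55))
  expect_equal(support_fractions(66, 64),
               list(frac_master = 50.77, frac_alt = 49.23))
  expect_equal(support_fractions(0, 5),
               list(frac_master = 0, frac_alt = 100))
  expect_true(is.na(support_fractions(0, 0)$frac_master))
})

test_that("support tables order repeats by length and keep uninformative counts", {
  labels <- list(Rsmall = c("master", "alternative", "uninformative"),
                 Rbig = rep(c("master", "uninformative"), c(4, 2)))
  pairs <- data.frame(id = c("Rsmall", "Rbig"), length = c(100, 900))
  st <- support_table(labels, pairs)
  expect_equal(st$id, c("Rbig", "Rsmall"))
  expect_equal(st$n_uninformative, c(2, 1))
  expect_equal(st$frac_master, c(100, 50))
})

# --- multipartite inference ----------------------------------------------

test_that("active direct repeats yield subcircles summing to the master length", {
  spec <- sim_genome_spec(380980, repeats = data.frame(
    length = 5616, start1 = 1, start2 = 265249, orientation = "direct"),
    seed = 61)
  g <- build_genome(spec)$mito
  pairs <- data.frame(id = "R1", length = 5616, start1 = 1, end1 = 5616,
                      start2 = 265249, end2 = 270864,
                      orientation = "direct")
  support <- support_table(list(R1 = rep(c("master", "alternative"),
                                         c(40, 48))), pairs)
  model <- infer_multipartite(support, g, pairs, activity_threshold = 20)
  expect_equal(nrow(model$active), 1)
  ci <- model$circles[["R1"]]
  expect_equal(sort(ci$sizes), c(115732, 265248))
  expect_equal(sum(ci$sizes), 380980)
  # every master base belongs to exactly one subcircle segment
  segs <- rbind(ci$segments$A, ci$segments$B)
  expect_equal(sum(segs$length), 380980)
  expect_equal(mitorecomb:::circ_union_width(segs$start, segs$length,
                                             380980), 380980)
})

test_that("repeats below the activity threshold stay inactive; none means master only", {
  g <- circular_seq("t", mitorecomb:::random_dna(2000, 0.5))
  pairs <- data.frame(id = "R1", length = 100, start1 = 101, start2 = 1001,
                      orientation = "direct")
  support <- support_table(list(R1 = rep(c("master", "alternative"),
                                         c(98, 2))), pairs)
  model <- infer_multipartite(support, g, pairs)
  expect_equal(nrow(model$active), 0)
  expect_equal(length(model$circles), 0)
  expect_equal(model$inactive$frac_alt, 2)

  empty <- support_table(setNames(list(), character(0)))
  m2 <- infer_multipartite(empty, g, pairs[0, ])
  expect_equal(length(m2$circles), 0)
})

test_that("interleaving active direct repeats are flagged as ambiguous", {
  g <- circular_seq("t", mitorecomb:::random_dna(10000, 0.5))
  pairs <- data.frame(id = c("R1", "R2"), length = c(200, 200),
                      start1 = c(1001, 3001), start2 = c(5001, 7001),
                      orientation = "direct")
  labels <- list(R1 = rep(c("master", "alternative"), c(5, 5)),
                 R2 = rep(c("master", "alternative"), c(5, 5)))
  support <- support_table(labels, pairs)
  expect_warning(model <- infer_multipartite(support, g, pairs),
                 "interleave")
  expect_true(model$ambiguous)
  # nested placement is not ambiguous
  pairs2 <- data.frame(id = c("R1", "R2"), length = c(200, 200),
                       start1 = c(1001, 2001), start2 = c(8001, 3001),
                       orientation = "direct")
  expect_silent(m2 <- infer_multipartite(support, g, pairs2))
  expect_false(m2$ambiguous)
})

test_that("zero-error pure-master simulation yields exactly zero alternative support", {
  spec <- sim_genome_spec(30000, repeats = data.frame(
    length = 1000, start1 = 5001, start2 = 20001, orientation = "direct"),
    seed = 81)
  g <- build_genome(spec)$mito
  pair <- data.frame(id = "R1", length = 1000, start1 = 5001,
                     start2 = 20001, orientation = "direct")
  cs <- enumerate_conformations(g, pair, F = 1000)
  rspec <- read_sim_spec(weights = c(master = 1), n_reads = 400,
                         meanlog = log(4000), sdlog = 0.3, seed = 82)
  reads <- simulate_reads(g, list(cs), rspec, focus = "junctions")
  cl <- classify_reads(reads, cs)
  expect_equal(sum(cl$label == "alternative"), 0)
  st <- support_table(list(R1 = cl$label))
  expect_equal(st$frac_alt, 0)
  expect_gt(st$n_master, 0)
})
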