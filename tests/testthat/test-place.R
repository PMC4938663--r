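test_that("alignments bin by the leftmost nucleotide, strand-independent", {
  expect_equal(bin_of(0L, 50L), 0L)
  expect_equal(bin_of(49L, 50L), 0L)
  expect_equal(bin_of(50L, 50L), 1L)
  expect_equal(bin_of(120L, 50L), 2L)
  expect_equal(bin_of(c(0L, 49L, 50L, 51L, 149L, 150L)),
               c(0L, 0L, 1L, 1L, 2L, 3L))
})

test_that("tallies count unique reads fully and MMAP reads fractionally", {
  cfg <- placement_config(mode = "U")
  u1 <- unique_reads_at("u", "chr1", 10L)
  aln <- make_alignments(u1$reads, u1$sites, c(chr1 = 1000L))
  t1 <- build_tallies(aln, cfg)
  expect_equal(t1$u$chr1[1], 1)
  expect_equal(t1$f$chr1[1], 1)
  expect_true(all(t1$u$chr1[-1] == 0))

  m2 <- make_alignments(
    data.frame(read_id = "m", sequence = strrep("A", 21L), n = 2L,
               overflow = FALSE),
    data.frame(read_id = "m", reference = "chr1", pos = c(10L, 510L),
               strand = "+", length = 21L),
    c(chr1 = 1000L))
  t2 <- build_tallies(m2, cfg)
  expect_equal(t2$f$chr1[1], 0.5)
  expect_equal(t2$f$chr1[11], 0.5)
  expect_true(all(t2$u$chr1 == 0))

  empty <- make_alignments(
    data.frame(read_id = character(0), sequence = character(0),
               n = integer(0), overflow = logical(0)),
    data.frame(read_id = character(0), reference = character(0),
               pos = integer(0), strand = character(0), length = integer(0)),
    c(chr1 = 1000L))
  t0 <- build_tallies(empty, cfg)
  expect_true(all(t0$u$chr1 == 0) && all(t0$f$chr1 == 0))
  # each retained read contributes total fractional weight 1
  expect_equal(sum(t2$f$chr1), 1)
})

test_that("vicinity sums cover five bins and truncate at reference ends", {
  cfg <- placement_config(mode = "U")
  pos <- c(100L, 200L, 300L, 400L, 500L, 600L)  # bins 2,4,6,8,10,12
  fur <- unique_reads_at("u", "chr1", pos)
  aln <- make_alignments(fur$reads, fur$sites, c(chr1 = 1000L))
  tl <- build_tallies(aln, cfg)
  # site in bin 10 sums bins 8..12
  vw <- vicinity_weight(list(reference = "chr1", pos = 500L), tl)
  expect_equal(vw$u, 3)
  # site in bin 0 sums bins 0..2 (left truncation)
  vw0 <- vicinity_weight(list(reference = "chr1", pos = 10L), tl)
  expect_equal(vw0$u, 1)
  # far right bin sums what exists
  vw19 <- vicinity_weight(list(reference = "chr1", pos = 980L), tl)
  expect_equal(vw19$u, 0)
})

test_that("U-mode probabilities reproduce the seven-vs-one worked example", {
  ex <- worked_example(unique_near_A = 7L, unique_near_B = 1L)
  cfg <- placement_config(mode = "U")
  tl <- build_tallies(ex$aln, cfg)
  pp <- placement_probabilities(ex$group, tl, cfg)
  expect_false(pp$tie)
  expect_equal(pp$p, c(0.875, 0.125))
  expect_equal(sum(pp$p), 1)
})

test_that("R-mode probabilities are uniform and never tied", {
  ex <- worked_example()
  cfg <- placement_config(mode = "R")
  tl <- build_tallies(ex$aln, cfg)
  pp <- placement_probabilities(ex$group, tl, cfg)
  expect_false(pp$tie)
  expect_equal(pp$p, c(0.5, 0.5))
})

test_that("F-mode reproduces the 73.7/26.3 split with self-exclusion", {
  # locus 1 vicinity: seven unique reads (weight 7); locus 2 vicinity: one
  # unique read plus three two-position reads (1 + 3 * 0.5 = 2.5), with the
  # placed read's own +/-0.5 contributions excluded
  ex <- worked_example(unique_near_A = 7L, unique_near_B = 1L,
                       mmap2_near_B = 3L)
  cfg <- placement_config(mode = "F")
  tl <- build_tallies(ex$aln, cfg)
  pp <- placement_probabilities(ex$group, tl, cfg)
  expect_false(pp$tie)
  expect_equal(pp$p, c(7, 2.5) / 9.5)
  expect_equal(round(100 * pp$p, 1), c(73.7, 26.3))
  # including self would break the printed example
  pp_self <- placement_probabilities(ex$group, tl, cfg, exclude_self = FALSE)
  expect_false(isTRUE(all.equal(pp_self$p, c(7, 2.5) / 9.5)))
})

test_that("zero and equal vicinities are ties; suppression follows the threshold", {
  cfg <- placement_config(mode = "U")
  # four sites, no unique reads anywhere: tie
  reads <- data.frame(read_id = "g", sequence = strrep("A", 21L), n = 4L,
                      overflow = FALSE)
  sites <- data.frame(read_id = "g", reference = "chr1",
                      pos = c(100L, 2000L, 4000L, 6000L), strand = "+",
                      length = 21L)
  aln <- make_alignments(reads, sites, c(chr1 = 10000L))
  tl <- build_tallies(aln, cfg)
  pp <- placement_probabilities(
    make_alignments(reads, sites, c(chr1 = 10000L)), tl, cfg)
  expect_true(pp$tie)
  set.seed(1)
  d4 <- choose_primary(make_alignments(reads, sites, c(chr1 = 10000L)),
                       pp, cfg)
  expect_identical(d4$chosen, "SUPPRESSED")
  expect_length(d4$probabilities, 0L)
  # n = 3 tie: placed uniformly at random, never suppressed
  reads3 <- transform(reads, n = 3L)
  sites3 <- sites[1:3, ]
  g3 <- make_alignments(reads3, sites3, c(chr1 = 10000L))
  set.seed(2)
  picks <- replicate(200L, choose_primary(g3, pp, cfg)$chosen)
  expect_true(all(picks %in% 1:3))
  expect_gt(length(unique(picks)), 1L)
})

test_that("overflow groups and singletons bypass weighting", {
  cfg <- placement_config(mode = "U")
  over <- make_alignments(
    data.frame(read_id = "o", sequence = strrep("A", 21L), n = 50L,
               overflow = TRUE),
    data.frame(read_id = "o", reference = "chr1",
               pos = seq(0L, by = 100L, length.out = 50L), strand = "+",
               length = 21L),
    c(chr1 = 10000L))
  d <- choose_primary(over, NULL, cfg)
  expect_identical(d$chosen, "UNMAPPED_OVERFLOW")
  single <- make_alignments(
    data.frame(read_id = "s", sequence = strrep("A", 21L), n = 1L,
               overflow = FALSE),
    data.frame(read_id = "s", reference = "chr1", pos = 5L, strand = "+",
               length = 21L),
    c(chr1 = 10000L))
  d1 <- choose_primary(single, NULL, cfg)
  expect_identical(d1$chosen, 1L)
  expect_equal(d1$probabilities, 1.0)
})

test_that("categorical selection follows its weights (80/20)", {
  probs <- list(p = c(0.8, 0.2), tie = FALSE, mode = "U")
  g <- make_alignments(
    data.frame(read_id = "g", sequence = strrep("A", 21L), n = 2L,
               overflow = FALSE),
    data.frame(read_id = "g", reference = "chr1", pos = c(0L, 1000L),
               strand = "+", length = 21L),
    c(chr1 = 10000L))
  cfg <- placement_config(mode = "U")
  set.seed(123)
  picks <- replicate(10000L, choose_primary(g, probs, cfg)$chosen)
  f1 <- mean(picks == 1L)
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(f1 - 0.8), 4 * se)
  sure <- choose_primary(g, list(p = c(1, 0), tie = FALSE, mode = "U"), cfg)
  expect_identical(sure$chosen, 1L)
})

test_that("identical sequences can be placed at different primaries (per read)", {
  # 100 copies of one two-site read; vicinity weights 4:1 -> both sites used
  fur <- unique_reads_at("u", "chr1", c(1001L, 1002L, 1003L, 1004L, 5001L))
  copies <- data.frame(read_id = sprintf("c%03d", 1:100),
                       sequence = strrep("G", 21L), n = 2L, overflow = FALSE,
                       stringsAsFactors = FALSE)
  csites <- data.frame(read_id = rep(copies$read_id, each = 2L),
                       reference = "chr1", pos = rep(c(1000L, 5000L), 100L),
                       strand = "+", length = 21L, stringsAsFactors = FALSE)
  aln <- make_alignments(rbind(fur$reads, copies), rbind(fur$sites, csites),
                         c(chr1 = 10000L))
  pl <- place_library(aln, placement_config(mode = "U", rng_seed = 7L))
  placed <- pl$decisions[pl$decisions$read_id %in% copies$read_id, ]
  expect_true(all(placed$status == "P"))
  tab <- table(placed$chosen_pos)
  expect_equal(sort(as.integer(names(tab))), c(1000L, 5000L))
  expect_lt(abs(sum(placed$chosen_pos == 1000L) - 80L), 16L)  # 4 SE of 80
})

test_that("place_library conserves reads and normalises probabilities", {
  fix <- tiny_sim(seed = 81L, n_reads = 3000L)
  idx <- genome_index(fix$genome)
  aln <- align_reads(fix$library$reads, idx)
  for (m in c("N", "R", "U", "F")) {
    pl <- place_library(aln, placement_config(mode = m, rng_seed = 9L))
    dec <- pl$decisions
    expect_equal(nrow(dec), nrow(aln$reads))
    placed <- dec$status == "P"
    expect_equal(sum(placed) + sum(!placed), nrow(aln$reads))
    expect_true(all(dec$probability[placed] > 0 &
                      dec$probability[placed] <= 1 + 1e-9))
    expect_true(all(is.na(dec$probability[!placed])))
    if (m == "N")
      expect_true(all(dec$status[dec$n > 1L] %in% c("N", "O")))
    if (m == "R")
      expect_true(all(dec$status[dec$n >= 1L & !dec$overflow] == "P"))
  }
})

test_that("placement output is byte-identical under a fixed seed", {
  fix <- tiny_sim(seed = 91L, n_reads = 1500L)
  idx <- genome_index(fix$genome)
  aln <- align_reads(fix$library$reads, idx)
  cfg <- placement_config(mode = "U", rng_seed = 33L)
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_placed_sam(place_library(aln, cfg), f1)
  write_placed_sam(place_library(aln, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("U and F agree when every read in every vicinity is unique", {
  # no MMAP furniture anywhere: u and f tallies coincide
  ex <- worked_example(unique_near_A = 5L, unique_near_B = 2L)
  tlU <- build_tallies(ex$aln, placement_config(mode = "U"))
  ppU <- placement_probabilities(ex$group, tlU, placement_config(mode = "U"))
  ppF <- placement_probabilities(ex$group, tlU, placement_config(mode = "F"))
  expect_equal(ppU$p, ppF$p)
})
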