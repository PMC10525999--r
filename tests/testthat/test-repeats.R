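# Repeat detection, conformation enumeration, junction support,
# copy-number segmentation, taper detection.

test_that("planted direct and inverted repeat pairs are found exactly", {
  set.seed(11)
  R <- random_seq(1200)
  # boundary bases fixed so the maximal match is exactly the planted copy
  mol <- paste0(random_seq(2999), "A", R, "G", random_seq(3998), "C", R, "T",
                random_seq(1999))
  reps <- find_long_repeats(c(M = mol), min_len = 1000)
  expect_equal(nrow(reps), 1L)
  expect_equal(reps$start1, 3001L)
  expect_equal(reps$start2, 8201L)
  expect_equal(reps$length, 1200L)
  expect_equal(reps$orientation, "direct")

  # inverted: extension happens when a flank base pairs with the complement
  # of the opposite flank, so those are fixed to non-complementary bases
  mol2 <- paste0(random_seq(2500), "A", R, "G", random_seq(3000), "A",
                 revcomp(R), "G", random_seq(1500))
  reps2 <- find_long_repeats(c(M = mol2), min_len = 1000)
  expect_equal(nrow(reps2), 1L)
  expect_equal(reps2$orientation, "inverted")
  expect_equal(reps2$start1, 2502L)
  expect_equal(reps2$start2, 6704L)
  expect_equal(reps2$length, 1200L)
})

test_that("random sequence yields no long repeats", {
  set.seed(13)
  expect_equal(nrow(find_long_repeats(c(M = random_seq(50000)),
                                      min_len = 1000)), 0L)
})

test_that("repeat finding agrees with a brute-force oracle on short inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    R <- random_seq(120)
    mol <- paste0(random_seq(800), R, random_seq(1200), R,
                  random_seq(400), revcomp(R), random_seq(300))
    got <- find_long_repeats(c(M = mol), min_len = 60, k = 31)
    want <- brute_force_repeats(c(M = mol), min_len = 60)
    got <- got[order(got$orientation, got$start1, got$start2), ]
    want <- want[order(want$orientation, want$start1, want$start2), ]
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    expect_equal(got$start1, want$start1, info = paste("seed", seed))
    expect_equal(got$start2, want$start2, info = paste("seed", seed))
    expect_equal(got$length, want$length, info = paste("seed", seed))
    expect_equal(got$orientation, want$orientation,
                 info = paste("seed", seed))
  }
})

test_that("direct-pair split conserves length (two-circle worked example)", {
  set.seed(17)
  R <- random_seq(2000)
  # arcs chosen so the products measure 135 and 83 length units (kb)
  g <- mito_genome(c(CH = paste0(R, random_seq(133000), R, random_seq(81000))),
                   c(CH = "circular"))
  reps <- tibble::tibble(molecule1 = "CH", start1 = 1L, end1 = 2000L,
                         molecule2 = "CH", start2 = 135001L, end2 = 137000L,
                         orientation = "direct", length = 2000L)
  confs <- enumerate_conformations(g, reps)
  expect_length(confs, 1L)
  lens <- sort(nchar(confs[[1]]$molecules))
  expect_equal(unname(lens), c(83000L, 135000L))
  expect_equal(sum(lens), nchar(g$molecules[["CH"]]))
  # each product retains exactly one repeat copy
  n_copies <- vapply(confs[[1]]$molecules, function(s) {
    lengths(regmatches(s, gregexpr(R, s, fixed = TRUE)))
  }, integer(1))
  expect_equal(unname(n_copies), c(1L, 1L))
})

test_that("a direct pair across two circles fuses them", {
  set.seed(19)
  R <- random_seq(1100)
  g <- mito_genome(c(A = paste0(random_seq(5000), R, random_seq(3000)),
                     B = paste0(random_seq(2000), R, random_seq(4000))),
                   c(A = "circular", B = "circular"))
  reps <- tibble::tibble(molecule1 = "A", start1 = 5001L, end1 = 6100L,
                         molecule2 = "B", start2 = 2001L, end2 = 3100L,
                         orientation = "direct", length = 1100L)
  confs <- enumerate_conformations(g, reps)
  expect_length(confs, 1L)
  expect_equal(unname(nchar(confs[[1]]$molecules)),
               sum(nchar(g$molecules)))
})

test_that("inverted-pair recombination reverse-complements the middle and is an involution", {
  set.seed(23)
  R <- random_seq(1500)
  mid <- random_seq(12846)
  parent <- paste0(random_seq(4000), R, mid, revcomp(R), random_seq(3000))
  g <- mito_genome(c(M = parent), c(M = "circular"))
  reps <- tibble::tibble(molecule1 = "M", start1 = 4001L, end1 = 5500L,
                         molecule2 = "M", start2 = 4001L + 1500L + 12846L,
                         end2 = 4000L + 1500L + 12846L + 1500L,
                         orientation = "inverted", length = 1500L)
  confs <- enumerate_conformations(g, reps)
  prod <- confs[[1]]$molecules[[1]]
  expect_equal(nchar(prod), nchar(parent))          # exact length conservation
  expect_identical(substr(prod, 5501L, 5500L + 12846L), revcomp(mid))
  # applying the event again restores the parent exactly
  g2 <- mito_genome(stats::setNames(prod, "M"), c(M = "circular"))
  back <- enumerate_conformations(g2, reps)[[1]]$molecules[[1]]
  expect_identical(back, parent)
})

test_that("an empty repeat set yields no conformations and overlaps error", {
  g <- mito_genome(c(M = strrep("ACGT", 1000)), c(M = "circular"))
  expect_length(enumerate_conformations(g, tibble::tibble(
    molecule1 = character(0), start1 = integer(0), end1 = integer(0),
    molecule2 = character(0), start2 = integer(0), end2 = integer(0),
    orientation = character(0), length = integer(0))), 0L)
  reps <- tibble::tibble(molecule1 = "M", start1 = 1L, end1 = 200L,
                         molecule2 = "M", start2 = 100L, end2 = 299L,
                         orientation = "direct", length = 200L)
  expect_error(enumerate_conformations(g, reps), "overlap")
})

test_that("junction support separates conformations and abstains with no reads", {
  set.seed(29)
  r35 <- random_seq(35)
  parent <- paste0(r35, random_seq(8000), r35, random_seq(6000))
  g <- mito_genome(c(P = parent), c(P = "circular"))
  reps <- tibble::tibble(molecule1 = "P", start1 = 1L, end1 = 35L,
                         molecule2 = "P", start2 = 8036L, end2 = 8070L,
                         orientation = "direct", length = 35L)
  conf <- enumerate_conformations(g, reps)[[1]]
  juncs <- rbind(conf$junctions, parent_junctions(g, reps))
  cfg <- forge_config(seed = 30, coverage = 40,
                      n_samples_per_type = c(1L, 1L),
                      locus_plan = locus_plan_simple(10),
                      background_positions = 0L)
  truth <- forge_population(cfg)
  mix <- c(g$molecules, conf$molecules)
  topo <- c(g$topology, conf$topology)
  reads <- simulate_reads(truth, "T1_01", molecules = mix, topology = topo)
  js <- junction_support(reads, juncs, genome_seqs = mix)
  expect_true(all(js$unique))
  expect_true(all(js$support > 0))
  # 50/50 parent/product mixture: the two product junctions together take
  # about half the support; binomial 99% CI at the observed total
  tot <- sum(js$support)
  prod_frac <- sum(js$frequency[1:2])
  expect_lt(abs(prod_frac - 0.5), 2.58 * sqrt(0.25 / tot) + 0.02)
  # no reads: frequency is a no-call
  js0 <- junction_support(character(0), juncs)
  expect_true(all(js0$support == 0L))
  expect_true(all(is.na(js0$frequency)))
})

test_that("copy-number segmentation recovers planted multicopy regions", {
  prof <- simulate_depth_profile(
    60000, 100,
    copy_segments = tibble::tibble(start = c(20001L, 40001L),
                                   end = c(24000L, 44000L), copy = c(2L, 3L)),
    seed = 55)
  seg <- copy_number_segments(prof, baseline = 100)
  expect_equal(seg$copy, c(1L, 2L, 1L, 3L, 1L))
  # boundaries within the smoothing window of the planted bounds
  expect_lt(abs(seg$start[2] - 20001L), 501L)
  expect_lt(abs(seg$end[2] - 24000L), 501L)
  expect_lt(abs(seg$start[4] - 40001L), 501L)
  # flat profile: a single copy-1 segment
  flat <- copy_number_segments(simulate_depth_profile(20000, 80, seed = 56),
                               baseline = 80)
  expect_equal(nrow(flat), 1L)
  expect_equal(flat$copy, 1L)
  # all-zero profile is an error
  expect_error(copy_number_segments(rep(0, 5000)), "zero")
  # half-integer ratios round away from zero (1.5x flags copy 2)
  seg15 <- copy_number_segments(rep(150, 10000), baseline = 100)
  expect_equal(seg15$copy, 2L)
})

test_that("linear-end taper is detected and measured within 20 %", {
  prof <- simulate_depth_profile(97120, 100, topology = "linear",
                                 taper_max = 18000, seed = 57)
  tp <- detect_linear_taper(prof)
  expect_true(all(tp$is_tapered))
  expect_lt(abs(tp$taper_length[1] - 18000) / 18000, 0.2)
  expect_lt(abs(tp$taper_length[2] - 18000) / 18000, 0.2)
  # a circular molecule cut at an arbitrary coordinate shows no taper
  circ <- simulate_depth_profile(97120, 100, topology = "circular", seed = 58)
  expect_false(any(detect_linear_taper(circ)$is_tapered))
  # flat noiseless profile: not tapered
  expect_false(any(detect_linear_taper(rep(100, 80000))$is_tapered))
})
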