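# Synthetic-population forge: determinism, planted structure, and the
# statistical behavior of simulated sequencing summaries.

small_config <- function(seed = 1L, ...) {
  base <- list(
    seed = seed,
    molecule_specs = list(LS1 = list(length = 40000L, topology = "circular"),
                          LS2 = list(length = 30000L, topology = "circular")),
    repeat_specs = list(list(length = 1200L, orientation = "direct",
                             molecule = c("LS1", "LS1"),
                             start = c(2001L, 12001L))),
    type2_linear = NULL,
    marker_pos = 20000L,
    cp_insert_length = 3000L,
    cp_insert_pos = 5001L,
    plastome_length = 20000L,
    cp_insert_plastome_pos = 4001L,
    locus_plan = locus_plan_simple(24),
    n_samples_per_type = c(4L, 4L),
    coverage = 100,
    background_positions = 20L,
    decoy_length = 2000L)
  do.call(forge_config, utils::modifyList(base, list(...)))
}

test_that("forging is deterministic under a fixed seed", {
  t1 <- forge_population(small_config(seed = 5))
  t2 <- forge_population(small_config(seed = 5))
  expect_identical(t1$genomes, t2$genomes)
  expect_identical(t1$loci, t2$loci)
  expect_identical(t1$cp_insert$variants, t2$cp_insert$variants)
  t3 <- forge_population(small_config(seed = 6))
  expect_false(identical(t1$genomes$type1$molecules,
                         t3$genomes$type1$molecules))
  # per-sample sub-streams: identical draws for the same sample either way
  p1 <- simulate_allele_counts(t1, "T1_02")
  p2 <- simulate_allele_counts(t2, "T1_02")
  expect_identical(p1, p2)
})

test_that("the differential-locus plan is honored (counts and classes)", {
  truth <- forge_population(forge_config(
    seed = 2, locus_plan = locus_plan_default()))
  expect_equal(nrow(truth$loci), 254L)
  expect_equal(sum(truth$loci$class == "SNP"), 143L)
  expect_equal(sum(truth$loci$class == "INS"), 52L)
  expect_equal(sum(truth$loci$class == "DEL"), 59L)
  # loci avoid planted repeats
  for (k in seq_len(nrow(truth$repeat_registry))) {
    rr <- truth$repeat_registry[k, ]
    on1 <- truth$loci$molecule == rr$molecule1 &
      truth$loci$pos >= rr$start1 & truth$loci$pos <= rr$end1
    on2 <- truth$loci$molecule == rr$molecule2 &
      truth$loci$pos >= rr$start2 & truth$loci$pos <= rr$end2
    expect_false(any(on1 | on2))
  }
})

test_that("with no differential loci the genomes differ only by marker and insert", {
  cfg <- small_config(seed = 3)
  cfg$locus_plan <- NULL
  truth <- forge_population(cfg)
  expect_equal(nrow(truth$loci), 0L)
  t1 <- truth$genomes$type1$molecules
  t2 <- truth$genomes$type2$molecules
  expect_identical(t1[["LS1"]], t2[["LS1"]])
  # LS2 differs by the inserted marker and the insert's mito version
  expect_equal(nchar(t2[["LS2"]]) - nchar(t1[["LS2"]]),
               truth$config$marker_length +
                 nchar(truth$cp_insert$versions$mito_t2) -
                 nchar(truth$cp_insert$versions$mito_t1))
  # the marker fragment is embedded in type 2 only
  expect_true(grepl(truth$marker$seq, t2[["LS2"]], fixed = TRUE))
  expect_false(grepl(truth$marker$seq, t1[["LS2"]], fixed = TRUE))
})

test_that("overlapping planted repeat copies are rejected", {
  expect_error(forge_config(repeat_specs = list(
    list(length = 2000L, orientation = "direct",
         molecule = c("LS1", "LS1"), start = c(1000L, 2500L)))),
    "overlap")
})

test_that("simulated allele counts recover the heteroplasmy fraction", {
  cfg <- small_config(seed = 9, heteroplasmy_fraction = 0.04, coverage = 500)
  truth <- forge_population(cfg)
  pu <- simulate_allele_counts(truth, "T1_01")  # the heteroplasmic sample
  loci <- truth$loci
  fr <- vapply(seq_len(nrow(loci)), function(j) {
    sel <- pu$molecule == loci$molecule[j] & pu$pos == loci$pos[j]
    n <- pu$fwd[sel] + pu$rev[sel]
    minor <- pu$allele[sel] == loci$type2_allele[j]
    sum(n[minor]) / sum(n)
  }, numeric(1))
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.04), 3 * se + 1e-6)
  # non-heteroplasmic type 1 sample with zero error: reference alleles only
  cfg0 <- small_config(seed = 9, heteroplasmy_fraction = 0.04, coverage = 500,
                       error_rate = 0)
  truth0 <- forge_population(cfg0)
  pu0 <- simulate_allele_counts(truth0, "T1_03")
  ref_of <- c(stats::setNames(truth0$loci$ref_allele,
                              paste(truth0$loci$molecule, truth0$loci$pos)),
              stats::setNames(truth0$background$ref_allele,
                              paste(truth0$background$molecule,
                                    truth0$background$pos)))
  expect_identical(pu0$allele,
                   unname(ref_of[paste(pu0$molecule, pu0$pos)]))
})

test_that("zero heteroplasmy and zero error give pure reference pileups", {
  cfg <- small_config(seed = 12, heteroplasmy_fraction = 0, error_rate = 0,
                      n_het_samples = 0L)
  cfg$locus_plan <- NULL
  truth <- forge_population(cfg)
  pu <- simulate_allele_counts(truth, "T1_01")
  m <- match(paste(pu$molecule, pu$pos),
             paste(truth$background$molecule, truth$background$pos))
  expect_true(all(!is.na(m)))
  expect_identical(pu$allele, truth$background$ref_allele[m])
})

test_that("mean simulated depth tracks the configured coverage within 1 %", {
  cfg <- small_config(seed = 21, coverage = 200, error_rate = 0)
  truth <- forge_population(cfg)
  pos <- tibble::tibble(molecule = "LS1", pos = 1:20000,
                        ref_allele = substring(
                          truth$genomes$type1$molecules[["LS1"]],
                          1:20000, 1:20000))
  cfg2 <- cfg; cfg2$locus_plan <- NULL
  truth2 <- forge_population(cfg2)
  pu <- simulate_allele_counts(truth2, "T2_01", positions = pos)
  depth <- pileup_depth(pu)
  expect_lt(abs(mean(depth$depth) - 200) / 200, 0.01)
})

test_that("simulated reads have full length and wrap circular origins", {
  cfg <- small_config(seed = 31, coverage = 40)
  truth <- forge_population(cfg)
  reads <- simulate_reads(truth, "T1_01",
                          molecules = c(M = truth$genomes$type1$molecules[["LS2"]]),
                          topology = c(M = "circular"))
  rl <- cfg$read_length
  expect_true(all(nchar(reads$seq) == rl))       # depth conservation
  L <- nchar(truth$genomes$type1$molecules[["LS2"]])
  prof <- depth_from_reads(reads, L, rl, circular = TRUE)
  expect_true(all(prof$depth > 0))                # origin covered
  expect_lt(abs(mean(prof$depth) - 40) / 40, 0.05)
  # error: read longer than shortest molecule
  cfg_bad <- cfg; cfg_bad$read_length <- 50000L
  expect_error(simulate_reads(truth, "T1_01", config = cfg_bad,
                              molecules = c(M = truth$genomes$type1$molecules[["LS2"]]),
                              topology = c(M = "circular")),
               "read_length")
})

test_that("linear-end truncation produces the closed-form depth ramp", {
  cfg <- forge_config(seed = 41, coverage = 60,
                      n_samples_per_type = c(1L, 1L),
                      locus_plan = locus_plan_simple(10),
                      background_positions = 0L)
  truth <- forge_population(cfg)
  m3 <- truth$genomes$type2$molecules[["M3"]]
  reads <- simulate_reads(truth, "T2_01", molecules = c(M3 = m3),
                          topology = c(M3 = "linear"), with_seq = FALSE)
  prof <- depth_from_reads(reads, nchar(m3), cfg$read_length)
  # expected depth at distance x from the end: coverage * x / taper_max
  for (x in c(4500, 9000, 13500)) {
    obs <- mean(prof$depth[(x - 400):(x + 400)])
    expect_lt(abs(obs - 60 * x / 18000) / (60 * x / 18000), 0.2)
  }
  interior <- mean(prof$depth[30000:60000])
  expect_lt(abs(interior - 60) / 60, 0.1)
})
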