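# Heteroplasmy filters, variant calling, homology masking, typing,
# population aggregation.

pu_row <- function(molecule, pos, allele, fwd, rev) {
  data.frame(molecule = molecule, pos = pos, allele = allele,
             fwd = fwd, rev = rev)
}

test_that("the heteroplasmy recording rule is enforced exactly", {
  params <- het_filter_params()
  # 4 of 100 reads, both strands: recorded at frequency 0.04
  pu <- as_pileup(rbind(pu_row("LS1", 100L, "C", 48L, 48L),
                        pu_row("LS1", 100L, "T", 2L, 2L)))
  rec <- call_heteroplasmy(pu, params)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$minor_allele, "T")
  expect_equal(rec$minor_freq, 0.04)
  # 1 of 100 (1 %): below the 2 % floor, not recorded
  pu <- as_pileup(rbind(pu_row("LS1", 100L, "C", 50L, 49L),
                        pu_row("LS1", 100L, "T", 1L, 0L)))
  expect_equal(nrow(call_heteroplasmy(pu, params)), 0L)
  # 10 of 100 but single-strand: rejected by the both-strands rule
  pu <- as_pileup(rbind(pu_row("LS1", 100L, "C", 45L, 45L),
                        pu_row("LS1", 100L, "T", 10L, 0L)))
  expect_equal(nrow(call_heteroplasmy(pu, params)), 0L)
  # ... unless the both-strands rule is relaxed
  params_relaxed <- het_filter_params(require_both_strands = FALSE)
  expect_equal(nrow(call_heteroplasmy(pu, params_relaxed)), 1L)
  # 5 of 100 inside a masked interval: excluded
  params_mask <- het_filter_params(
    mask = tibble::tibble(molecule = "LS1", start = 90L, end = 110L))
  pu <- as_pileup(rbind(pu_row("LS1", 100L, "C", 48L, 47L),
                        pu_row("LS1", 100L, "T", 3L, 2L)))
  expect_equal(nrow(call_heteroplasmy(pu, params_mask)), 0L)
  expect_equal(nrow(call_heteroplasmy(pu, params)), 1L)
})

test_that("heteroplasmy calling equals the row-wise filter oracle on random tables", {
  for (seed in 1:20) {
    set.seed(seed)
    n_loci <- sample(3:12, 1)
    rows <- list()
    for (i in seq_len(n_loci)) {
      alleles <- sample(c("A", "C", "G", "T", "+AT", "-G"),
                        sample(1:4, 1))
      for (a in alleles) {
        rows[[length(rows) + 1]] <- pu_row("M", i * 10L, a,
                                           sample(0:60, 1), sample(0:60, 1))
      }
    }
    pu <- do.call(rbind, rows)
    pu <- pu[!(pu$fwd == 0 & pu$rev == 0), ]
    pu <- as_pileup(pu[!duplicated(paste(pu$molecule, pu$pos, pu$allele)), ])
    mask <- tibble::tibble(molecule = "M", start = 35L, end = 55L)
    params <- het_filter_params(min_minor_freq = 0.05, mask = mask)
    got <- call_heteroplasmy(pu, params)
    want <- brute_force_het(pu, min_minor_freq = 0.05, mask = mask)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(got)) {
      expect_equal(got$minor_freq, want$minor_freq,
                   info = paste("seed", seed))
      expect_equal(got$minor_allele, want$minor_allele,
                   info = paste("seed", seed))
    }
  }
})

test_that("raising the minor-frequency threshold never adds records", {
  set.seed(99)
  rows <- list()
  for (i in 1:30) {
    for (a in sample(c("A", "C", "G", "T"), sample(2:3, 1))) {
      rows[[length(rows) + 1]] <- pu_row("M", i * 7L, a,
                                         sample(0:40, 1), sample(0:40, 1))
    }
  }
  pu <- do.call(rbind, rows)
  pu <- pu[!(pu$fwd == 0 & pu$rev == 0), ]
  pu <- as_pileup(pu[!duplicated(paste(pu$molecule, pu$pos, pu$allele)), ])
  thresholds <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.4)
  n_rec <- vapply(thresholds, function(t)
    nrow(call_heteroplasmy(pu, het_filter_params(min_minor_freq = t))),
    integer(1))
  expect_true(all(diff(n_rec) <= 0))
})

test_that("variant calling distinguishes variants, reference and no-calls", {
  ref <- tibble::tibble(molecule = "M", pos = c(10L, 20L, 30L, 40L),
                        ref = c("C", "A", "G", "T"))
  pu <- as_pileup(rbind(
    pu_row("M", 10L, "T", 50L, 50L),                 # clean SNP
    pu_row("M", 20L, "-AG", 30L, 30L),               # deletion majority
    pu_row("M", 20L, "A", 20L, 20L),
    pu_row("M", 30L, "G", 2L, 3L)))                  # below min_depth
  calls <- call_variants(pu, ref, min_depth = 10L)
  expect_equal(calls$call, c("variant", "variant", "no_call", "no_call"))
  expect_equal(calls$class[1:2], c("SNP", "DEL"))
  expect_equal(calls$allele[1:2], c("T", "-AG"))
  # zero-depth locus (absent row) is a no-call, distinct from reference
  expect_equal(calls$depth[4], 0L)
})

test_that("homology masking covers decoys, spares the insertion", {
  cfg <- forge_config(seed = 61,
                      molecule_specs = list(
                        LS1 = list(length = 120000L, topology = "circular"),
                        LS2 = list(length = 60000L, topology = "circular")),
                      repeat_specs = list(),
                      type2_linear = NULL,
                      marker_pos = 30000L,
                      cp_insert_length = 5000L, cp_insert_pos = 10001L,
                      plastome_length = 40000L,
                      cp_insert_plastome_pos = 8001L,
                      locus_plan = locus_plan_simple(12),
                      n_samples_per_type = c(2L, 2L),
                      decoy_length = 5000L)
  truth <- forge_population(cfg)
  exclude <- tibble::tibble(molecule = truth$cp_insert$molecule,
                            start = truth$cp_insert$start,
                            end = truth$cp_insert$end)
  mask <- build_homology_mask(truth$genomes$type1$molecules,
                              truth$plastomes$type1, truth$decoys,
                              exclude = exclude)
  # the decoy's source interval is masked
  dt <- truth$decoy_truth
  hit <- mask[mask$molecule == dt$molecule &
                mask$start <= dt$start & mask$end >= dt$end, ]
  expect_equal(nrow(hit), 1L)
  # the insertion interval is never masked
  expect_false(any(mask$molecule == exclude$molecule &
                     mask$start <= exclude$end & mask$end >= exclude$start))
  # with no plastome or decoys the mask is empty
  expect_equal(nrow(build_homology_mask(truth$genomes$type1$molecules)), 0L)
})

test_that("typing votes correctly, reports heteroplasmy, and flags discordance", {
  loci <- tibble::tibble(molecule = "M", pos = c(10L, 20L, 30L),
                         ref = c("A", "C", "G"))
  ta <- tibble::tibble(molecule = "M", pos = c(10L, 20L, 30L),
                       type1_allele = c("A", "C", "G"),
                       type2_allele = c("T", "G", "C"))
  alle <- rbind(pure2 = c("T", "G", "C"),
                pure1 = c("A", "C", "G"),
                uncovered = c(NA, NA, NA))
  vm <- structure(list(loci = loci, alleles = alle), class = "variant_matrix")
  md <- c(pure2 = 100, pure1 = 2, uncovered = 90)
  ty <- type_samples(vm, ta, md, genome_median_depth = 100)
  expect_equal(ty$type, c(2L, 1L, NA))
  expect_equal(ty$frac_type2[1:2], c(1, 0))
  expect_false(any(ty$discordant[1:2]))
  expect_true(is.na(ty$type[3]))
  # marker says type 2 but alleles vote type 1: discordance is surfaced
  md_bad <- c(pure2 = 100, pure1 = 100, uncovered = 0)
  ty2 <- type_samples(vm, ta, md_bad, genome_median_depth = 100)
  expect_true(ty2$discordant[2])
})

test_that("aggregation is empty-safe and counts exclusivity per allele", {
  loci <- tibble::tibble(molecule = "LS1", pos = c(10L, 20L),
                         ref = c("A", "C"))
  # locus 10: type-2-exclusive SNP; locus 20: same allele in both types
  alle <- rbind(a = c("T", "G"), b = c("A", "G"))
  vm <- structure(list(loci = loci, alleles = alle), class = "variant_matrix")
  types <- c(a = 2L, b = 1L)
  ag <- aggregate_counts(vm, types)
  snp <- ag[ag$chromosome == "LS1" & ag$class == "SNP", ]
  expect_equal(snp$total, 2L)
  expect_equal(snp$type2_n, 2L)
  expect_equal(snp$type2_exclusive, 1L)
  expect_equal(snp$type1_n, 1L)
  expect_equal(snp$type1_exclusive, 0L)
  # all-reference matrix: zero everywhere
  alle0 <- rbind(a = c("A", "C"), b = c("A", "C"))
  vm0 <- structure(list(loci = loci, alleles = alle0),
                   class = "variant_matrix")
  ag0 <- aggregate_counts(vm0, types)
  expect_true(all(ag0$total == 0L))
})
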