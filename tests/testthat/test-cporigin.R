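# Plastid-insertion detection and quartet-parsimony origin assignment.

test_that("single- and triple-Alt patterns resolve to terminal branches", {
  # one derived state on a terminal branch
  expect_equal(assign_origin(quad_pattern("Ref", "Alt", "Ref", "Ref"))$organelle,
               "Mito")
  expect_equal(assign_origin(quad_pattern("Ref", "Alt", "Ref", "Ref"))$branch,
               "mito_t1")
  expect_equal(assign_origin(quad_pattern("Ref", "Ref", "Alt", "Ref"))$organelle,
               "Chloro")
  expect_equal(assign_origin(quad_pattern("Ref", "Ref", "Alt", "Ref"))$branch,
               "chloro_t2")
  # three Alt: the lone Ref terminal carries the single change
  call <- assign_origin(quad_pattern("Ref", "Alt", "Alt", "Alt"))
  expect_equal(call$organelle, "Chloro")
  expect_equal(call$branch, "chloro_t1")
  expect_equal(call$parsimony_score, 1L)
  # pair split along the tree: internal change, undecidable organelle
  expect_equal(assign_origin(quad_pattern("Ref", "Alt", "Ref", "Alt"))$organelle,
               "Ambiguous")
  # all-Ref: no variant
  expect_equal(assign_origin(quad_pattern("Ref", "Ref", "Ref", "Ref"))$organelle,
               "NoVariant")
  # pair split across the tree: two changes required
  conflict <- assign_origin(quad_pattern("Alt", "Alt", "Ref", "Ref"))
  expect_equal(conflict$organelle, "Conflict")
  expect_equal(conflict$parsimony_score, 2L)
  # non-binary input rejected
  expect_error(quad_pattern("Ref", "X", "Ref", "Ref"), "Ref")
})

test_that("assign_origin equals the exhaustive branch-placement oracle on all 16 patterns", {
  states <- c("Ref", "Alt")
  grid <- expand.grid(c1 = states, m1 = states, c2 = states, m2 = states,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    p <- quad_pattern(grid$c1[i], grid$m1[i], grid$c2[i], grid$m2[i])
    got <- assign_origin(p)
    want <- oracle_origin(c(chloro_t1 = grid$c1[i], mito_t1 = grid$m1[i],
                            chloro_t2 = grid$c2[i], mito_t2 = grid$m2[i]))
    expect_equal(got$organelle, want$organelle,
                 info = paste(unlist(grid[i, ]), collapse = ","))
    expect_equal(got$parsimony_score, want$score,
                 info = paste(unlist(grid[i, ]), collapse = ","))
    if (want$organelle %in% c("Mito", "Chloro")) {
      expect_equal(got$branch, want$branch)
    }
  }
})

test_that("swapping the type columns never flips Mito and Chloro", {
  states <- c("Ref", "Alt")
  grid <- expand.grid(c1 = states, m1 = states, c2 = states, m2 = states,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    a <- assign_origin(quad_pattern(grid$c1[i], grid$m1[i],
                                    grid$c2[i], grid$m2[i]))
    b <- assign_origin(quad_pattern(grid$c2[i], grid$m2[i],
                                    grid$c1[i], grid$m1[i]))
    expect_equal(a$organelle, b$organelle)
    if (!is.na(a$branch) && a$branch != "internal") {
      swap <- c(chloro_t1 = "chloro_t2", chloro_t2 = "chloro_t1",
                mito_t1 = "mito_t2", mito_t2 = "mito_t1")
      expect_equal(b$branch, unname(swap[a$branch]))
    }
  }
})

test_that("origin tallies cover all categories and empty input", {
  empty <- summarize_origins(tibble::tibble(organelle = character(0)))
  expect_equal(sum(empty$n), 0L)
  calls <- do.call(rbind, lapply(
    list(c("Ref", "Alt", "Ref", "Ref"), c("Ref", "Ref", "Alt", "Ref"),
         c("Ref", "Alt", "Ref", "Alt")),
    function(s) assign_origin(quad_pattern(s[1], s[2], s[3], s[4]))))
  tal <- summarize_origins(calls)
  expect_equal(tal$n[tal$organelle == "Mito"], 1L)
  expect_equal(tal$n[tal$organelle == "Chloro"], 1L)
  expect_equal(tal$n[tal$organelle == "Ambiguous"], 1L)
})

test_that("a planted insertion is found with its length, position and orientation", {
  set.seed(71)
  insert <- random_seq(9798)
  plast <- paste0(random_seq(12000), insert, random_seq(15000))
  mito <- c(LS2 = paste0(random_seq(20000), insert, random_seq(18000)))
  segs <- find_cp_insertions(mito, plast, min_len = 1000)
  expect_equal(nrow(segs), 1L)
  expect_lt(abs(segs$length - 9798L), 50L)
  expect_lt(abs(segs$m_start - 20001L), 25L)
  expect_equal(segs$orientation, "direct")
  expect_gt(segs$identity, 0.95)
  # reverse-complemented insert found with inverted orientation
  mito_rc <- c(LS2 = paste0(random_seq(20000), revcomp(insert),
                            random_seq(18000)))
  segs_rc <- find_cp_insertions(mito_rc, plast, min_len = 1000)
  expect_equal(segs_rc$orientation, "inverted")
  expect_lt(abs(segs_rc$length - 9798L), 50L)
  expect_lt(abs(segs_rc$p_start - 12001L), 25L)
  # unrelated sequences: nothing
  expect_equal(nrow(find_cp_insertions(c(M = random_seq(30000)),
                                       random_seq(30000), min_len = 1000)), 0L)
})

test_that("a diverged insertion is still chained into one segment with lower identity", {
  set.seed(73)
  insert <- random_seq(6000)
  ch <- strsplit(insert, "")[[1]]
  idx <- sort(sample(6000, 60))
  for (p in idx) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  diverged <- paste(ch, collapse = "")
  plast <- paste0(random_seq(8000), insert, random_seq(8000))
  mito <- c(LS2 = paste0(random_seq(9000), diverged, random_seq(7000)))
  segs <- find_cp_insertions(mito, plast, min_len = 1000)
  expect_equal(nrow(segs), 1L)
  expect_lt(abs(segs$length - 6000L), 120L)
  expect_lt(segs$identity, 1)
  expect_gt(segs$identity, 0.5)
})

test_that("planted branch mutations are recovered through the frequency split", {
  truth <- forge_population(forge_config(seed = 81))
  ids <- truth$samples$sample[c(2, 3, 4, 46, 47, 48)]  # 3 per type, no het
  types <- stats::setNames(truth$samples$type, truth$samples$sample)[ids]
  calls <- lapply(stats::setNames(ids, ids), function(s)
    split_insert_alleles(simulate_insert_counts(truth, s)))
  cls <- stats::setNames(truth$cp_insert$variants$class,
                         as.character(truth$cp_insert$variants$offset))
  quads <- quad_patterns_from_calls(calls, types, classes = cls)
  org <- do.call(rbind, lapply(quads, assign_origin))
  tq <- forge_quad_truth(truth)
  m <- merge(org, tq, by.x = "locus", by.y = "offset")
  # resolvable loci: planted on a fixed branch (the within-type-polymorphic
  # chloroplast variant has no type consensus and is excluded)
  resolvable <- m$branch.y != "chloro_t1_poly"
  acc <- mean(m$organelle[resolvable] == m$expected_origin[resolvable])
  expect_gte(acc, 0.95)
  expect_equal(nrow(m), nrow(tq))
})
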