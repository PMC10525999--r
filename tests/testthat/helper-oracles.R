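# Independent oracles and shared fixtures for the test suite.

# ---- brute-force maximal exact repeat oracle (sequences <= ~5 kb) ----------
# Diagonal-by-diagonal character comparison; independent of the k-mer seeded
# implementation under test.
brute_force_repeats <- function(seqs, min_len) {
  out <- list()
  nm <- names(seqs)
  runs_between <- function(ca, cb) {
    # all maximal runs ca[i..] == cb[i+d..] over every diagonal d (both signs)
    na <- length(ca); nb <- length(cb)
    res <- list()
    for (d in (-(na - 1)):(nb - 1)) {
      ia <- max(1, 1 - d):min(na, nb - d)
      if (length(ia) < min_len) next
      eq <- ca[ia] == cb[ia + d]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- c(1, utils::head(ends, -1) + 1)
      for (t in which(r$values & r$lengths >= min_len)) {
        res[[length(res) + 1]] <- c(a = ia[starts[t]], b = ia[starts[t]] + d,
                                    len = r$lengths[t])
      }
    }
    res
  }
  for (i in seq_along(nm)) {
    for (j in i:length(nm)) {
      ca <- strsplit(seqs[[nm[i]]], "")[[1]]
      cb <- strsplit(seqs[[nm[j]]], "")[[1]]
      for (r in runs_between(ca, cb)) {
        if (i == j && r["a"] >= r["b"]) next  # identity/mirror
        out[[length(out) + 1]] <- data.frame(
          molecule1 = nm[i], start1 = unname(r["a"]),
          molecule2 = nm[j], start2 = unname(r["b"]),
          orientation = "direct", length = unname(r["len"]))
      }
      cbr <- rev(chartr("ACGT", "TGCA", cb))
      Lb <- length(cb)
      for (r in runs_between(ca, cbr)) {
        fwd_b <- Lb - (r["b"] + r["len"] - 1) + 1
        if (i == j) {
          if (r["a"] > fwd_b) next                      # mirrored duplicate
          if (r["a"] <= fwd_b + r["len"] - 1 &&
              fwd_b <= r["a"] + r["len"] - 1) next      # palindromic overlap
        }
        out[[length(out) + 1]] <- data.frame(
          molecule1 = nm[i], start1 = unname(r["a"]),
          molecule2 = nm[j], start2 = unname(fwd_b),
          orientation = "inverted", length = unname(r["len"]))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(molecule1 = character(0), start1 = integer(0),
                      molecule2 = character(0), start2 = integer(0),
                      orientation = character(0), length = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$molecule1, res$start1, res$length), ]
}

# ---- row-wise heteroplasmy filter oracle -----------------------------------
brute_force_het <- function(pileup, min_minor_freq = 0.02,
                            require_both_strands = TRUE, mask = NULL) {
  recs <- list()
  key <- paste(pileup$molecule, pileup$pos)
  for (kk in unique(key)) {
    rows <- pileup[key == kk, ]
    depth <- sum(rows$fwd + rows$rev)
    if (depth == 0) next
    masked <- FALSE
    if (!is.null(mask) && nrow(mask) > 0) {
      for (mi in seq_len(nrow(mask))) {
        if (rows$molecule[1] == mask$molecule[mi] &&
            rows$pos[1] >= mask$start[mi] && rows$pos[1] <= mask$end[mi]) {
          masked <- TRUE
        }
      }
    }
    if (masked) next
    n <- rows$fwd + rows$rev
    top <- which.max(n)
    for (j in seq_len(nrow(rows))) {
      if (j == top) next
      if (n[j] / depth < min_minor_freq) next
      if (require_both_strands && (rows$fwd[j] < 1 || rows$rev[j] < 1)) next
      recs[[length(recs) + 1]] <- data.frame(
        molecule = rows$molecule[1], pos = rows$pos[1],
        minor_allele = rows$allele[j], minor_freq = n[j] / depth)
    }
  }
  if (!length(recs)) {
    return(data.frame(molecule = character(0), pos = integer(0),
                      minor_allele = character(0), minor_freq = numeric(0)))
  }
  do.call(rbind, recs)
}

# ---- exhaustive branch-placement parsimony oracle --------------------------
# Enumerates every assignment of changes to the quartet's five branches and
# every ancestral state, keeping minimum-change explanations of the pattern.
oracle_origin <- function(states) {
  # states: named c(chloro_t1, mito_t1, chloro_t2, mito_t2) of "Ref"/"Alt"
  branches <- c("chloro_t1", "mito_t1", "chloro_t2", "mito_t2", "internal")
  flip <- function(s) if (s == "Ref") "Alt" else "Ref"
  best <- Inf; best_sets <- list()
  for (anc in c("Ref", "Alt")) {
    for (mask in 0:31) {
      on <- branches[bitwAnd(mask, 2^(0:4)) > 0]
      # node X subtends the chloro pair, node Y the mito pair; root at X
      xa <- anc
      ya <- if ("internal" %in% on) flip(xa) else xa
      tip <- c(
        chloro_t1 = if ("chloro_t1" %in% on) flip(xa) else xa,
        chloro_t2 = if ("chloro_t2" %in% on) flip(xa) else xa,
        mito_t1 = if ("mito_t1" %in% on) flip(ya) else ya,
        mito_t2 = if ("mito_t2" %in% on) flip(ya) else ya)
      if (all(tip[names(states)] == states)) {
        k <- length(on)
        if (k < best) { best <- k; best_sets <- list(on) }
        else if (k == best) best_sets <- c(best_sets, list(on))
      }
    }
  }
  best_sets <- unique(best_sets)
  if (best == 0) return(list(organelle = "NoVariant", score = 0))
  if (best >= 2) return(list(organelle = "Conflict", score = best))
  br <- unique(unlist(best_sets))
  if (length(br) > 1) return(list(organelle = "Conflict", score = best))
  org <- if (br == "internal") "Ambiguous"
         else if (startsWith(br, "mito")) "Mito" else "Chloro"
  list(organelle = org, score = 1, branch = br)
}

# ---- brute-force SSR oracle (regex based) ----------------------------------
brute_force_ssrs <- function(sequence, min_repeats = c(10, 6, 5, 5, 5, 5)) {
  cands <- list()
  for (m in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1+", m)
    hits <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    if (hits[1] == -1) next
    lens <- attr(hits, "match.length")
    n <- nchar(sequence)
    ch <- strsplit(sequence, "")[[1]]
    for (h in seq_along(hits)) {
      # expand to the maximal period-m region around the regex hit (a
      # preceding overlapping match may have consumed this run's true start)
      rs <- hits[h]; re <- hits[h] + lens[h] - 1
      while (rs > 1 && ch[rs - 1] == ch[rs - 1 + m]) rs <- rs - 1
      while (re < n && ch[re + 1] == ch[re + 1 - m]) re <- re + 1
      count <- (re - rs + 1) %/% m
      motif <- substr(sequence, rs, rs + m - 1)
      prim <- TRUE
      for (d in seq_len(m - 1)) {
        if (m %% d == 0 && strrep(substr(motif, 1, d), m / d) == motif)
          prim <- FALSE
      }
      if (!prim) next
      if (count < min_repeats[m]) next
      cands[[length(cands) + 1]] <- data.frame(
        start = rs, end = rs + count * m - 1, motif = motif,
        motif_length = m, repeats = count, length = count * m)
    }
  }
  if (!length(cands)) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), motif_length = integer(0),
                      repeats = integer(0), length = integer(0)))
  }
  out <- unique(do.call(rbind, cands))
  out <- out[order(-out$length, out$start, out$motif_length), ]
  kept <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!kept[i]) next
    later <- which(kept & seq_len(nrow(out)) > i)
    ov <- out$start[later] <= out$end[i] & out$end[later] >= out$start[i]
    kept[later[ov]] <- FALSE
  }
  out <- out[kept, ]
  out[order(out$start), ]
}

# ---- least-squares quartet topology oracle ---------------------------------
# Fits branch lengths of each of the three quartet topologies by least squares
# and returns the sister pair of the best-fitting (zero-residual on additive
# input) topology.
oracle_quartet <- function(dm) {
  taxa <- rownames(dm)
  pairings <- list(c(1, 2), c(1, 3), c(1, 4))
  best <- NULL; best_rss <- Inf
  for (p in pairings) {
    i <- p[1]; j <- p[2]
    rest <- setdiff(1:4, c(i, j))
    k <- rest[1]; l <- rest[2]
    # topology ((i,j),(k,l)): d = X b with b = (bi, bj, bk, bl, bm)
    X <- rbind(
      c(1, 1, 0, 0, 0),  # d(i,j)
      c(1, 0, 1, 0, 1),  # d(i,k)
      c(1, 0, 0, 1, 1),  # d(i,l)
      c(0, 1, 1, 0, 1),  # d(j,k)
      c(0, 1, 0, 1, 1),  # d(j,l)
      c(0, 0, 1, 1, 0))  # d(k,l)
    y <- c(dm[i, j], dm[i, k], dm[i, l], dm[j, k], dm[j, l], dm[k, l])
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- canonical_pair(taxa[c(i, j)], taxa)
    }
  }
  best
}

# canonical form of a quartet split: the sister pair containing the
# alphabetically first taxon (a split and its complement are the same split)
canonical_pair <- function(pair, taxa) {
  first <- sort(taxa)[1]
  if (first %in% pair) sort(pair) else sort(setdiff(taxa, pair))
}

# sister pair of a quartet tree, canonicalized
tree_quartet_split <- function(tree) {
  pairs <- combn(tree$tip.label, 2, simplify = FALSE)
  for (p in pairs) {
    if (ape::is.monophyletic(tree, p)) {
      return(canonical_pair(p, tree$tip.label))
    }
  }
  NULL
}

# ---- shared default-scale population run (built once) ----------------------
forge_cache <- new.env(parent = emptyenv())

default_population_run <- function() {
  if (!is.null(forge_cache$run)) return(forge_cache$run)
  config <- forge_config(seed = 101L)
  truth <- forge_population(config)
  samples <- truth$samples$sample
  types <- stats::setNames(truth$samples$type, samples)
  ref_alleles <- tibble::tibble(molecule = truth$loci$molecule,
                                pos = truth$loci$pos,
                                ref = truth$loci$ref_allele)
  calls <- list(); het <- list(); marker_depth <- numeric(0)
  params <- het_filter_params()
  for (s in samples) {
    pu <- simulate_allele_counts(truth, s)
    calls[[s]] <- call_variants(pu, ref_alleles)
    het[[s]] <- call_heteroplasmy(pu, params)
    marker_depth[[s]] <- simulate_marker_depth(truth, s)
  }
  vm <- build_variant_matrix(calls, ref_alleles)
  type_alleles <- tibble::tibble(molecule = truth$loci$molecule,
                                 pos = truth$loci$pos,
                                 type1_allele = truth$loci$type1_allele,
                                 type2_allele = truth$loci$type2_allele)
  typing <- type_samples(vm, type_alleles, marker_depth,
                         genome_median_depth = config$coverage,
                         het_by_sample = het)
  forge_cache$run <- list(config = config, truth = truth, types = types,
                          ref_alleles = ref_alleles, calls = calls, het = het,
                          vm = vm, typing = typing,
                          marker_depth = marker_depth)
  forge_cache$run
}
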