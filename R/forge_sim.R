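# Sequencing-summary simulation from a forged truth object.
#
# Per-sample randomness is drawn from a sub-stream seeded by (config seed,
# sample index, stream offset), so regenerating one sample never disturbs
# another and adding samples does not shift earlier draws.

sample_index <- function(truth, sample_id) {
  i <- match(sample_id, truth$samples$sample)
  if (is.na(i)) stop("unknown sample: ", sample_id)
  i
}

# the allele the sample itself carries (its major mitogenome) at one locus row
own_allele <- function(row, sample_id, type) {
  carriers <- row$carriers[[1]]
  switch(row$segregation,
    t2_fixed = if (type == 2L) row$type2_allele else row$ref_allele,
    t2_subset = if (type == 2L && sample_id %in% carriers)
      row$type2_allele else row$ref_allele,
    t1_subset = if (type == 1L && sample_id %in% carriers)
      row$type2_allele else row$ref_allele,
    shared = if (type == 2L || sample_id %in% carriers)
      row$type2_allele else row$ref_allele,
    dual = if (type == 2L) row$type2_allele
      else if (sample_id %in% carriers) row$alt1_allele else row$ref_allele,
    row$ref_allele)
}

# the minor allele contributed by a coexisting second mitogenome, or NA
het_minor_allele <- function(row, type) {
  if (!row$segregation %in% c("t2_fixed", "shared", "dual")) return(NA_character_)
  if (type == 1L) row$type2_allele else row$ref_allele
}

#' Simulate a per-sample allele-count (pileup) table
#'
#' Emits rows at every differential locus plus the forge's background
#' positions (or at `positions`, when given). Per-locus depth is
#' Poisson(coverage); at differential loci the minor-genome allele count is
#' Binomial(depth, sample heteroplasmy fraction); substitution errors move
#' reads to a random other base with probability `error_rate`; each read's
#' strand is a fair coin.
#'
#' @param truth A `forge_truth`.
#' @param sample_id Sample identifier from `truth$samples`.
#' @param config Forge configuration (defaults to the truth's).
#' @param positions Optional tibble (`molecule`, `pos`, `ref_allele`) of extra
#'   invariant positions to emit instead of the stored background set.
#' @return A `pileup` tibble.
#' @export
simulate_allele_counts <- function(truth, sample_id, config = truth$config,
                                   positions = NULL) {
  i <- sample_index(truth, sample_id)
  srow <- truth$samples[i, ]
  with_seed(sub_seed(config$seed, i * 13L + 1L), {
    loci <- truth$loci
    h <- srow$het_fraction
    out <- vector("list", nrow(loci) + 1L)
    for (j in seq_len(nrow(loci))) {
      row <- loci[j, ]
      major <- own_allele(row, sample_id, srow$type)
      minor <- het_minor_allele(row, srow$type)
      if (!is.na(minor) && minor == major) minor <- NA_character_
      out[[j]] <- simulate_locus_counts(row$molecule, row$pos, major, minor,
                                        h, config)
    }
    bg <- if (is.null(positions)) truth$background else positions
    if (nrow(bg) > 0) {
      depth <- stats::rpois(nrow(bg), config$coverage)
      err <- stats::rbinom(nrow(bg), depth, config$error_rate)
      rows <- list()
      for (jj in which(depth > 0)) {
        alle <- bg$ref_allele[jj]
        cnt <- depth[jj] - err[jj]
        r <- data.frame(molecule = bg$molecule[jj], pos = bg$pos[jj],
                        allele = alle, n = cnt)
        if (err[jj] > 0) {
          eb <- sample(setdiff(DNA_BASES, alle), 1)
          r <- rbind(r, data.frame(molecule = bg$molecule[jj], pos = bg$pos[jj],
                                   allele = eb, n = err[jj]))
        }
        rows[[length(rows) + 1L]] <- r
      }
      if (length(rows)) {
        r <- do.call(rbind, rows)
        r <- r[r$n > 0, ]
        fwd <- stats::rbinom(nrow(r), r$n, 0.5)
        out[[nrow(loci) + 1L]] <- data.frame(
          molecule = r$molecule, pos = r$pos, allele = r$allele,
          fwd = fwd, rev = r$n - fwd)
      }
    }
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    as_pileup(res)
  })
}

simulate_locus_counts <- function(molecule, pos, major, minor, h, config) {
  depth <- stats::rpois(1L, config$coverage)
  if (depth == 0) return(NULL)
  n_minor <- if (!is.na(minor) && h > 0) stats::rbinom(1L, depth, h) else 0L
  n_major <- depth - n_minor
  # substitution errors only; drawn from the major pool
  n_err <- stats::rbinom(1L, n_major, config$error_rate)
  n_major <- n_major - n_err
  alle <- c(major, if (n_minor > 0) minor,
            if (n_err > 0) sample(setdiff(DNA_BASES,
              c(substr(major, 1, 1), if (!is.na(minor)) substr(minor, 1, 1))), 1))
  n <- c(n_major, if (n_minor > 0) n_minor, if (n_err > 0) n_err)
  keep <- n > 0
  alle <- alle[keep]; n <- n[keep]
  if (length(n) == 0) return(NULL)
  fwd <- stats::rbinom(length(n), n, 0.5)
  data.frame(molecule = molecule, pos = pos, allele = alle,
             fwd = fwd, rev = n - fwd)
}

#' Simulate mean read depth over the type-2 marker fragment
#'
#' Samples carrying the marker draw Poisson(coverage); others draw a small
#' cross-mapping background (1 % of coverage).
#'
#' @inheritParams simulate_allele_counts
#' @return A single numeric depth.
#' @export
simulate_marker_depth <- function(truth, sample_id, config = truth$config) {
  i <- sample_index(truth, sample_id)
  with_seed(sub_seed(config$seed, i * 13L + 2L), {
    lambda <- if (truth$samples$type[i] == 2L) config$coverage
              else 0.01 * config$coverage
    stats::rpois(1L, lambda)
  })
}

#' Simulate reads from a sample's genome (or an explicit molecule mixture)
#'
#' Reads are drawn uniformly along each molecule, in numbers proportional to
#' molecule length times weight, at the configured coverage. Circular
#' molecules wrap across the origin. Linear molecule copies lose an
#' independent Uniform(0, taper_max) stretch from each end before sampling
#' (reads falling outside the surviving span are discarded), so the expected
#' depth at distance x from an end is coverage * x / taper_max for
#' x < taper_max and the interior keeps full coverage. Reads carry the name
#' of the molecule (or conformation) of origin as a truth tag.
#'
#' @inheritParams simulate_allele_counts
#' @param molecules Named character vector of template sequences; defaults to
#'   the sample's genome molecules.
#' @param topology Named vector ("circular"/"linear") matching `molecules`.
#' @param weights Named nonnegative weights (default 1 per molecule).
#' @param with_seq Emit read sequences (set FALSE for depth-only studies).
#' @return Tibble with `read`, `tag`, `start`, `strand` and optionally `seq`;
#'   `start` is the 1-based leftmost template coordinate.
#' @export
simulate_reads <- function(truth, sample_id, config = truth$config,
                           molecules = NULL, topology = NULL, weights = NULL,
                           with_seq = TRUE) {
  i <- sample_index(truth, sample_id)
  gtype <- if (truth$samples$type[i] == 2L) "type2" else "type1"
  if (is.null(molecules)) {
    molecules <- truth$genomes[[gtype]]$molecules
    topology <- truth$genomes[[gtype]]$topology
  }
  if (is.null(topology)) stop("topology required with explicit molecules")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(molecules)),
                                                   names(molecules))
  rl <- config$read_length
  if (any(nchar(molecules) < rl)) {
    stop("read_length exceeds the shortest molecule")
  }
  with_seed(sub_seed(config$seed, i * 13L + 3L), {
    out <- list()
    for (m in names(molecules)) {
      L <- nchar(molecules[[m]])
      n_reads <- round(config$coverage * weights[[m]] * L / rl)
      if (n_reads == 0) next
      if (topology[[m]] == "circular") {
        start <- sample.int(L, n_reads, replace = TRUE)
        template <- paste0(molecules[[m]], substr(molecules[[m]], 1L, rl))
      } else {
        # each read comes from a molecule copy whose ends were truncated by
        # independent Uniform(0, taper_max) amounts; a uniformly placed read
        # is kept only if it lies inside the surviving span, which yields the
        # expected-depth ramp coverage * x / taper_max near the ends
        a <- stats::runif(n_reads, 0, config$taper_max)
        b <- stats::runif(n_reads, 0, config$taper_max)
        start <- 1L + floor(stats::runif(n_reads) * (L - rl + 1))
        keep <- start >= 1 + a & start <= L - b - rl + 1
        start <- start[keep]
        template <- molecules[[m]]
      }
      if (length(start) == 0) next
      strand <- ifelse(stats::runif(length(start)) < 0.5, "+", "-")
      df <- tibble::tibble(
        read = sprintf("%s_%s_r%06d", sample_id, m, seq_along(start)),
        tag = m, start = as.integer(start), strand = strand)
      if (with_seq) {
        s <- substr(rep(template, length(start)), start, start + rl - 1L)
        s[strand == "-"] <- revcomp(s[strand == "-"])
        df$seq <- s
      }
      out[[m]] <- df
    }
    if (length(out) == 0) {
      return(tibble::tibble(read = character(0), tag = character(0),
                            start = integer(0), strand = character(0),
                            seq = character(0)))
    }
    do.call(rbind, out)
  })
}

#' Depth profile of a molecule from simulated reads
#'
#' @param reads Tibble from [simulate_reads()] (single template).
#' @param length Template length.
#' @param read_length Read length used in the simulation.
#' @param circular Whether coverage wraps at the origin.
#' @param molecule Molecule id recorded on the profile.
#' @return A `depth_profile`: list with `molecule`, `depth` (length `length`),
#'   `topology`.
#' @export
depth_from_reads <- function(reads, length, read_length,
                             circular = FALSE, molecule = "molecule") {
  cov <- numeric(length + read_length)
  if (nrow(reads) > 0) {
    add <- tabulate(reads$start, nbins = length + read_length)
    ends <- pmin(reads$start + read_length, length + read_length)
    sub <- tabulate(ends, nbins = length + read_length)
    cov <- cumsum(add - sub)
  }
  depth <- cov[seq_len(length)]
  if (circular) {
    over <- cov[seq.int(length + 1L, length + read_length)]
    depth[seq_len(read_length)] <- depth[seq_len(read_length)] + over
  }
  structure(list(molecule = molecule, depth = depth,
                 topology = if (circular) "circular" else "linear"),
            class = "depth_profile")
}

#' Simulate a per-position depth profile directly
#'
#' Pileup-summary-level emulation of coverage structure: per-position depth is
#' Poisson(coverage x copy multiplier x end-taper factor). The taper factor
#' min(1, x / taper_max) from each end is the expected-depth ramp under
#' independent Uniform(0, taper_max) end truncation of linear molecule copies.
#'
#' @param length Molecule length (bp).
#' @param coverage Baseline reads-per-base.
#' @param copy_segments Optional tibble (`start`, `end`, `copy`) of planted
#'   multicopy regions (copy >= 2).
#' @param topology "circular" or "linear".
#' @param taper_max Maximum end truncation (bp) applied when linear.
#' @param molecule Molecule id.
#' @param seed Optional seed for reproducibility.
#' @return A `depth_profile`.
#' @export
simulate_depth_profile <- function(length, coverage, copy_segments = NULL,
                                   topology = "circular", taper_max = 0,
                                   molecule = "molecule", seed = NULL) {
  run <- function() {
    mult <- rep(1, length)
    if (!is.null(copy_segments)) {
      for (k in seq_len(nrow(copy_segments))) {
        mult[copy_segments$start[k]:copy_segments$end[k]] <-
          copy_segments$copy[k]
      }
    }
    lambda <- coverage * mult
    if (topology == "linear" && taper_max > 0) {
      x <- seq_len(length)
      ramp <- pmin(1, x / taper_max) * pmin(1, (length - x + 1) / taper_max)
      lambda <- lambda * ramp
    }
    structure(list(molecule = molecule,
                   depth = stats::rpois(length, lambda),
                   topology = topology),
              class = "depth_profile")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate read evidence over the shared plastid insertion
#'
#' At each planted insertion variant the sample contributes plastome-derived
#' reads at `coverage * cp_coverage_ratio` carrying its chloroplast allele and
#' mitogenome-derived reads at `coverage` carrying its mitochondrial allele --
#' the depth imbalance that lets the two organelle states be separated by
#' allele frequency.
#'
#' @inheritParams simulate_allele_counts
#' @return Tibble with `offset` (position in ancestral insert coordinates),
#'   `allele`, `fwd`, `rev`.
#' @export
simulate_insert_counts <- function(truth, sample_id, config = truth$config) {
  i <- sample_index(truth, sample_id)
  type <- truth$samples$type[i]
  cpv <- truth$cp_insert$variants
  with_seed(sub_seed(config$seed, i * 13L + 4L), {
    out <- list()
    for (j in seq_len(nrow(cpv))) {
      v <- cpv[j, ]
      chloro <- insert_state_allele(v, type, "chloro", sample_id)
      mito <- insert_state_allele(v, type, "mito", sample_id)
      n_c <- stats::rpois(1L, config$coverage * config$cp_coverage_ratio)
      n_m <- stats::rpois(1L, config$coverage)
      df <- data.frame(allele = c(chloro, mito), n = c(n_c, n_m))
      df <- stats::aggregate(n ~ allele, df, sum)
      # substitution noise
      err <- stats::rbinom(nrow(df), df$n, config$error_rate)
      df$n <- df$n - err
      if (sum(err) > 0) {
        eb <- sample(setdiff(DNA_BASES, substr(df$allele, 1, 1)), 1)
        df <- rbind(df, data.frame(allele = eb, n = sum(err)))
        df <- stats::aggregate(n ~ allele, df, sum)
      }
      df <- df[df$n > 0, ]
      fwd <- stats::rbinom(nrow(df), df$n, 0.5)
      out[[j]] <- data.frame(offset = v$offset, allele = df$allele,
                             fwd = fwd, rev = df$n - fwd)
    }
    tibble::as_tibble(do.call(rbind, out))
  })
}

# realized allele of one organelle copy at one planted insert variant;
# states are relative to the ancestral insert with the variant's edit applied
# on the branches it affects
insert_state_allele <- function(v, type, organelle, sample_id) {
  alt <- v$allele
  ref <- v$ref
  carries <- switch(v$branch,
    mito_anc = organelle == "mito",
    mito_t1 = organelle == "mito" && type == 1L,
    mito_t2 = organelle == "mito" && type == 2L,
    chloro_t1 = organelle == "chloro" && type == 1L,
    chloro_t1_poly = organelle == "chloro" && type == 1L &&
      substr(sample_id, nchar(sample_id), nchar(sample_id)) %in% c("1", "3"),
    chloro_t2 = organelle == "chloro" && type == 2L,
    FALSE)
  if (carries) alt else ref
}

#' Ground-truth quad patterns for the forged insertion variants
#'
#' States are Ref/Alt relative to the type 1 chloroplast sequence, as a
#' downstream caller would tabulate them; `branch` and `expected_origin` give
#' the planted truth.
#'
#' @param truth A `forge_truth`.
#' @return Tibble with `offset`, `class`, `branch`, the four state columns and
#'   `expected_origin`.
#' @export
forge_quad_truth <- function(truth) {
  cpv <- truth$cp_insert$variants
  pat <- t(vapply(cpv$branch, function(b) {
    switch(b,
      mito_anc =       c("Ref", "Alt", "Ref", "Alt"),
      mito_t1 =        c("Ref", "Alt", "Ref", "Ref"),
      mito_t2 =        c("Ref", "Ref", "Ref", "Alt"),
      chloro_t2 =      c("Ref", "Ref", "Alt", "Ref"),
      chloro_t1 =      c("Ref", "Alt", "Alt", "Alt"),
      chloro_t1_poly = c("Alt", "Ref", "Ref", "Ref"))
  }, character(4)))
  expected <- vapply(cpv$branch, function(b) {
    switch(b,
      mito_anc = "Ambiguous",
      mito_t1 = "Mito", mito_t2 = "Mito",
      chloro_t1 = "Chloro", chloro_t1_poly = "Chloro", chloro_t2 = "Chloro")
  }, character(1))
  tibble::tibble(offset = cpv$offset, class = cpv$class, branch = cpv$branch,
                 chloro_t1 = pat[, 1], mito_t1 = pat[, 2],
                 chloro_t2 = pat[, 3], mito_t2 = pat[, 4],
                 expected_origin = expected)
}
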