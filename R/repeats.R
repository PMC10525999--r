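# Long-repeat detection, recombination-conformation enumeration, junction
# support, copy-number segmentation and linear-end taper detection.

#' Construct a genome object
#'
#' @param molecules Named character vector of molecule sequences.
#' @param topology Named character vector, "circular" or "linear" per molecule.
#' @param type Optional genome type label.
#' @return A `mito_genome` list.
#' @export
mito_genome <- function(molecules, topology, type = NA_character_) {
  stopifnot(length(molecules) > 0, !is.null(names(molecules)),
            identical(sort(names(molecules)), sort(names(topology))),
            all(topology %in% c("circular", "linear")))
  structure(list(molecules = molecules, topology = topology[names(molecules)],
                 type = type), class = "mito_genome")
}

#' Find long exact repeat pairs
#'
#' All maximal exact repeated pairs of length >= `min_len`, within and between
#' molecules, in direct and inverted orientation. Matching is exact (100 %
#' identity), seeded with `k`-mers and extended along alignment diagonals;
#' maximality means the pair can be extended in neither direction. Molecules
#' are scanned linearly (no wrap across circular origins).
#'
#' @param molecules Named character vector of sequences (or a `mito_genome`).
#' @param min_len Minimum repeat length in bp (>= 20).
#' @param k Seed length; must be <= `min_len` (default 31).
#' @return Tibble with `molecule1`, `start1`, `end1`, `molecule2`, `start2`,
#'   `end2`, `orientation` ("direct"/"inverted"), `length`. Coordinates are
#'   1-based inclusive on the forward strand of each molecule.
#' @export
find_long_repeats <- function(molecules, min_len = 1000L, k = 31L) {
  if (inherits(molecules, "mito_genome")) molecules <- molecules$molecules
  stopifnot(min_len >= 20L, k <= min_len)
  out <- list()
  nm <- names(molecules)
  emit <- function(m1, s1, m2, s2, len, orientation) {
    out[[length(out) + 1L]] <<- data.frame(
      molecule1 = m1, start1 = s1, end1 = s1 + len - 1L,
      molecule2 = m2, start2 = s2, end2 = s2 + len - 1L,
      orientation = orientation, length = len)
  }
  for (i in seq_along(nm)) {
    for (j in i:length(nm)) {
      a <- molecules[[nm[i]]]; b <- molecules[[nm[j]]]
      self <- i == j
      runs <- seed_match_runs(a, b, k = k, self = self)
      runs <- runs[runs$length >= min_len, , drop = FALSE]
      for (r in seq_len(nrow(runs))) {
        emit(nm[i], runs$start_a[r], nm[j], runs$start_b[r], runs$length[r],
             "direct")
      }
      # inverted: match a against reverse complement of b
      rb <- revcomp(b)
      Lb <- nchar(b)
      runs <- seed_match_runs(a, rb, k = k, self = FALSE)
      runs <- runs[runs$length >= min_len, , drop = FALSE]
      if (nrow(runs) > 0) {
        # map rc coordinates back to the forward strand of b
        runs$fwd_start_b <- Lb - (runs$start_b + runs$length - 1L) + 1L
        if (self) {
          # each inverted pair appears twice (mirrored); keep one canonical
          # copy and drop self-overlapping (palindromic) hits
          keep <- runs$start_a < runs$fwd_start_b |
            (runs$start_a == runs$fwd_start_b & FALSE)
          ov <- runs$start_a <= runs$fwd_start_b + runs$length - 1L &
            runs$fwd_start_b <= runs$start_a + runs$length - 1L
          runs <- runs[keep & !ov, , drop = FALSE]
        }
        for (r in seq_len(nrow(runs))) {
          emit(nm[i], runs$start_a[r], nm[j], runs$fwd_start_b[r],
               runs$length[r], "inverted")
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(molecule1 = character(0), start1 = integer(0),
                          end1 = integer(0), molecule2 = character(0),
                          start2 = integer(0), end2 = integer(0),
                          orientation = character(0), length = integer(0)))
  }
  res <- tibble::as_tibble(do.call(rbind, out))
  res[order(-res$length, res$molecule1, res$start1), ]
}

#' Enumerate single-event recombination conformations
#'
#' Applies each repeat pair as one homologous-recombination event (depth-1
#' enumeration): a direct pair on one circle splits it into two circles whose
#' lengths sum to the parent's, each retaining one repeat copy; a direct pair
#' across two circles fuses them into one circle of summed length; an inverted
#' pair on one circle reverse-complements the intervening segment. Events on
#' linear molecules or mixed placements are skipped with a message.
#'
#' @param genome A [mito_genome()].
#' @param repeats Tibble as returned by [find_long_repeats()] (or a planted
#'   repeat registry with the same columns).
#' @param anchor Flank length (bp) on each side of the retained repeat copy in
#'   junction signatures (default 30).
#' @return List of `conformation` objects: each has `event` (split/fuse/
#'   invert), `repeat_pair` (the input row), `molecules`, `topology`, and
#'   `junctions` (tibble of junction signatures diagnostic of the product).
#' @export
enumerate_conformations <- function(genome, repeats, anchor = 30L) {
  stopifnot(inherits(genome, "mito_genome"))
  out <- list()
  for (r in seq_len(nrow(repeats))) {
    rp <- repeats[r, ]
    m1 <- rp$molecule1; m2 <- rp$molecule2
    if (!all(c(m1, m2) %in% names(genome$molecules))) {
      stop("repeat pair names molecules absent from the genome")
    }
    if (m1 == m2 && rp$start1 <= rp$end2 && rp$start2 <= rp$end1) {
      stop("repeat copies overlap each other")
    }
    same <- m1 == m2
    circ1 <- genome$topology[[m1]] == "circular"
    circ2 <- genome$topology[[m2]] == "circular"
    conf <- NULL
    if (rp$orientation == "direct" && same && circ1) {
      conf <- conf_split(genome, rp, anchor)
    } else if (rp$orientation == "direct" && !same && circ1 && circ2) {
      conf <- conf_fuse(genome, rp, anchor)
    } else if (rp$orientation == "inverted" && same && circ1) {
      conf <- conf_invert(genome, rp, anchor)
    } else {
      message("skipping unsupported event for repeat pair ", r,
              " (", rp$orientation, " on ", m1, "/", m2, ")")
    }
    if (!is.null(conf)) out[[length(out) + 1L]] <- conf
  }
  out
}

junction_row <- function(id, group, signature) {
  tibble::tibble(junction = id, group = group, signature = signature)
}

# circular substring with wrap
circ_at <- function(s, start, end) {
  L <- nchar(s)
  idx <- ((seq.int(start, end) - 1L) %% L) + 1L
  paste(strsplit(s, "")[[1]][idx], collapse = "")
}

conf_split <- function(genome, rp, anchor) {
  s <- genome$molecules[[rp$molecule1]]
  s1 <- rp$start1; e1 <- rp$end1; s2 <- rp$start2; e2 <- rp$end2
  if (s1 > s2) { tmp <- c(s1, e1); s1 <- s2; e1 <- e2; s2 <- tmp[1]; e2 <- tmp[2] }
  prodA <- str_at(s, s1, s2 - 1L)                       # copy1 + inner arc
  prodB <- paste0(str_at(s, s2, nchar(s)), str_at(s, 1L, s1 - 1L))
  nameA <- paste0(rp$molecule1, "_splitA"); nameB <- paste0(rp$molecule1, "_splitB")
  # product junctions: flank preceding the *other* copy, the retained copy,
  # and the retained copy's own right flank
  sigA <- paste0(circ_at(s, s2 - anchor, s2 - 1L), str_at(s, s1, e1),
                 circ_at(s, e1 + 1L, e1 + anchor))
  sigB <- paste0(circ_at(s, s1 - anchor, s1 - 1L), str_at(s, s2, e2),
                 circ_at(s, e2 + 1L, e2 + anchor))
  structure(list(
    event = "split", repeat_pair = rp,
    molecules = stats::setNames(c(prodA, prodB), c(nameA, nameB)),
    topology = stats::setNames(c("circular", "circular"), c(nameA, nameB)),
    junctions = rbind(
      junction_row(paste0(nameA, "_j"), paste0(rp$molecule1, ":", s1), sigA),
      junction_row(paste0(nameB, "_j"), paste0(rp$molecule1, ":", s1), sigB))),
    class = "conformation")
}

conf_fuse <- function(genome, rp, anchor) {
  a <- genome$molecules[[rp$molecule1]]; b <- genome$molecules[[rp$molecule2]]
  rotA <- rotate_seq(a, rp$start1)   # starts with copy 1
  rotB <- rotate_seq(b, rp$start2)   # starts with copy 2
  fused <- paste0(rotA, rotB)
  name <- paste0(rp$molecule1, "_", rp$molecule2, "_fused")
  lenr <- rp$length
  sig1 <- paste0(circ_at(a, rp$start1 - anchor, rp$start1 - 1L),
                 str_at(a, rp$start1, rp$end1),
                 circ_at(b, rp$end2 + 1L, rp$end2 + anchor))
  sig2 <- paste0(circ_at(b, rp$start2 - anchor, rp$start2 - 1L),
                 str_at(b, rp$start2, rp$end2),
                 circ_at(a, rp$end1 + 1L, rp$end1 + anchor))
  structure(list(
    event = "fuse", repeat_pair = rp,
    molecules = stats::setNames(fused, name),
    topology = stats::setNames("circular", name),
    junctions = rbind(
      junction_row(paste0(name, "_j1"),
                   paste0(rp$molecule1, ":", rp$start1), sig1),
      junction_row(paste0(name, "_j2"),
                   paste0(rp$molecule1, ":", rp$start1), sig2))),
    class = "conformation")
}

conf_invert <- function(genome, rp, anchor) {
  s <- genome$molecules[[rp$molecule1]]
  s1 <- rp$start1; e1 <- rp$end1; s2 <- rp$start2; e2 <- rp$end2
  if (s1 > s2) { tmp <- c(s1, e1); s1 <- s2; e1 <- e2; s2 <- tmp[1]; e2 <- tmp[2] }
  inverted <- paste0(str_at(s, 1L, e1),
                     revcomp(str_at(s, e1 + 1L, s2 - 1L)),
                     str_at(s, s2, nchar(s)))
  name <- paste0(rp$molecule1, "_inv")
  mid_rc <- revcomp(str_at(s, e1 + 1L, s2 - 1L))
  sig1 <- paste0(circ_at(s, s1 - anchor, s1 - 1L), str_at(s, s1, e1),
                 substr(mid_rc, 1L, anchor))
  sig2 <- paste0(substr(mid_rc, nchar(mid_rc) - anchor + 1L, nchar(mid_rc)),
                 str_at(s, s2, e2), circ_at(s, e2 + 1L, e2 + anchor))
  structure(list(
    event = "invert", repeat_pair = rp,
    molecules = stats::setNames(inverted, name),
    topology = stats::setNames(genome$topology[[rp$molecule1]], name),
    junctions = rbind(
      junction_row(paste0(name, "_j1"), paste0(rp$molecule1, ":", s1), sig1),
      junction_row(paste0(name, "_j2"), paste0(rp$molecule1, ":", s1), sig2))),
    class = "conformation")
}

#' Parent-arrangement junction signatures for a repeat pair
#'
#' The alternative at each locus against which product junctions compete:
#' each repeat copy with its own parent flanks.
#'
#' @inheritParams enumerate_conformations
#' @param rp One row of a repeat table.
#' @return Tibble of junction signatures (group shared with the products').
#' @export
parent_junctions <- function(genome, rp, anchor = 30L) {
  a <- genome$molecules[[rp$molecule1]]; b <- genome$molecules[[rp$molecule2]]
  group <- paste0(rp$molecule1, ":", min(rp$start1, rp$start2))
  sig1 <- paste0(circ_at(a, rp$start1 - anchor, rp$start1 - 1L),
                 str_at(a, rp$start1, rp$end1),
                 circ_at(a, rp$end1 + 1L, rp$end1 + anchor))
  sig2 <- paste0(circ_at(b, rp$start2 - anchor, rp$start2 - 1L),
                 str_at(b, rp$start2, rp$end2),
                 circ_at(b, rp$end2 + 1L, rp$end2 + anchor))
  rbind(junction_row(paste0(rp$molecule1, "_parent_j1"), group, sig1),
        junction_row(paste0(rp$molecule2, "_parent_j2"), group, sig2))
}

#' Count read support for junction signatures
#'
#' A read supports a junction iff it exactly contains the junction signature
#' (on either strand). Within each signature group the frequency of a
#' junction is its support divided by the total support of all junctions in
#' the group; with zero total support the frequency is NA (no-call).
#' Signatures occurring more than once in `genome_seqs` (when provided) are
#' flagged non-unique and excluded from frequencies.
#'
#' @param reads Character vector of read sequences, or a tibble with a `seq`
#'   column (as from [simulate_reads()]).
#' @param junctions Tibble with `junction`, `group`, `signature` columns
#'   (product and parent junctions combined).
#' @param genome_seqs Optional character vector of template sequences for the
#'   uniqueness check.
#' @return The `junctions` tibble with `support`, `unique`, `frequency` added.
#' @export
junction_support <- function(reads, junctions, genome_seqs = NULL) {
  if (is.data.frame(reads)) reads <- reads$seq
  stopifnot(is.character(reads))
  haystack <- paste(c(reads, revcomp(reads)), collapse = "\n")
  count_hits <- function(sig) {
    m <- gregexpr(sig, haystack, fixed = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }
  junctions$support <- vapply(junctions$signature, count_hits, integer(1))
  junctions$unique <- TRUE
  if (!is.null(genome_seqs)) {
    hay2 <- paste(c(genome_seqs, revcomp(genome_seqs)), collapse = "\n")
    occ <- vapply(junctions$signature, function(sig) {
      m <- gregexpr(sig, hay2, fixed = TRUE)[[1]]
      if (m[1] == -1) 0L else length(m)
    }, integer(1))
    junctions$unique <- occ <= 1L
  }
  junctions$frequency <- NA_real_
  for (g in unique(junctions$group)) {
    sel <- junctions$group == g & junctions$unique
    tot <- sum(junctions$support[sel])
    if (tot > 0) junctions$frequency[sel] <- junctions$support[sel] / tot
  }
  tibble::as_tibble(junctions)
}

#' Segment a depth profile into integer copy-number intervals
#'
#' The per-position ratio depth/baseline is smoothed by a running median of
#' window `w`, rounded to the nearest positive integer (halves away from
#' zero, so a ratio of exactly 1.5 flags copy 2), and merged into maximal
#' constant-copy intervals; intervals shorter than `min_seg` are absorbed
#' into their longer neighbor.
#'
#' @param profile A `depth_profile` (list with `depth`), or a numeric vector.
#' @param baseline Single-copy depth; default the profile's global median.
#' @param w Running-median window (odd; default 501).
#' @param min_seg Minimum reported segment length (default 1000).
#' @return Tibble with `start`, `end`, `copy`, `mean_depth`.
#' @export
copy_number_segments <- function(profile, baseline = NULL, w = 501L,
                                 min_seg = 1000L) {
  depth <- if (inherits(profile, "depth_profile")) profile$depth else profile
  if (all(depth == 0)) stop("all-zero depth profile")
  if (w %% 2L == 0L) w <- w + 1L
  sm <- stats::runmed(depth, k = min(w, 2L * (length(depth) %/% 2L) - 1L))
  if (is.null(baseline)) baseline <- stats::median(depth)
  stopifnot(baseline > 0)
  ratio <- sm / baseline
  copy <- pmax(1L, as.integer(floor(ratio + 0.5)))  # halves away from zero
  r <- rle(copy)
  # absorb short segments into the previous (or next) run, then re-merge
  while (any(r$lengths < min_seg) && length(r$lengths) > 1L) {
    i <- which.min(ifelse(r$lengths < min_seg, r$lengths, Inf))
    j <- if (i == 1L) 2L else i - 1L
    r$values[i] <- r$values[j]
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  tibble::tibble(start = starts, end = ends, copy = r$values,
                 mean_depth = vapply(seq_along(starts), function(i)
                   mean(depth[starts[i]:ends[i]]), numeric(1)))
}

#' Detect progressive coverage decay at linear-molecule ends
#'
#' For each end, an isotonic (monotone non-decreasing inward) fit over the
#' outermost quarter of the molecule locates the point where depth first
#' reaches `plateau_frac` of the interior median; dividing by `plateau_frac`
#' debiases the estimate under a linear expected-depth ramp (the uniform
#' end-truncation model). An end is called tapered when the estimated taper
#' length is at least `min_taper` and the outermost depth is below half the
#' interior median.
#'
#' @param profile A `depth_profile` or numeric depth vector.
#' @param min_taper Minimum taper length to call (bp, default 1000).
#' @param plateau_frac Fraction of the interior median treated as "arrived at
#'   the plateau" (default 0.9).
#' @param edge_bp Width of the outermost window whose mean depth is compared
#'   to half the interior median (default 500).
#' @return Tibble with one row per end: `end` ("left"/"right"), `is_tapered`,
#'   `taper_length`, `end_depth`, `interior_median`, `fit_rmse`.
#' @export
detect_linear_taper <- function(profile, min_taper = 1000L,
                                plateau_frac = 0.9, edge_bp = 500L) {
  depth <- if (inherits(profile, "depth_profile")) profile$depth else profile
  L <- length(depth)
  scan <- max(min_taper * 2L, L %/% 4L)
  scan <- min(scan, L %/% 2L)
  interior <- stats::median(depth[(scan + 1L):(L - scan)])
  one_end <- function(d, label) {
    iso <- stats::isoreg(seq_along(d), d)
    fit <- iso$yf
    target <- plateau_frac * interior
    at <- which(fit >= target)
    taper <- if (length(at) == 0) NA_integer_
             else as.integer(round(min(at) / plateau_frac))
    end_depth <- mean(d[seq_len(min(edge_bp, length(d)))])
    rmse <- sqrt(mean((d - fit)^2))
    tibble::tibble(end = label,
                   is_tapered = !is.na(taper) && taper >= min_taper &&
                     end_depth < 0.5 * interior,
                   taper_length = taper, end_depth = end_depth,
                   interior_median = interior, fit_rmse = rmse)
  }
  rbind(one_end(depth[seq_len(scan)], "left"),
        one_end(rev(depth[seq.int(L - scan + 1L, L)]), "right"))
}
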