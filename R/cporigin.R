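# Plastid-derived insertions in the mitogenome and parsimony assignment of
# the organelle lineage in which each insertion variant arose.
#
# The model: a single ancestral chloroplast-to-mitochondrion transfer predates
# the split of the two germplasm types, fixing the unrooted quartet topology
# ((chloro_type1, chloro_type2), (mito_type1, mito_type2)). At each variant
# locus within the shared insertion, the four observed states (Ref/Alt
# relative to the type 1 chloroplast reference) admit a minimum-change
# placement on the quartet's five branches; a unique most-parsimonious change
# on a terminal branch names the organelle lineage of the mutation.

#' Find plastid-derived insertions in mitogenome molecules
#'
#' k-mer seeded, diagonal-chained, gap-merged local homology segments between
#' each mitogenome molecule and the plastome, in both orientations, with an
#' identity estimate (fraction of segment covered by exact seed matches).
#'
#' @param mito Named character vector of mitogenome molecule sequences.
#' @param plastome Plastome sequence (string).
#' @param min_len Minimum segment length (>= 100; default 500).
#' @param k Seed length (default 21).
#' @param gap Maximum gap bridged when chaining matches (default 500 bp).
#' @param band Diagonal drift tolerated within one chain (default 50 bp).
#' @return Tibble with `molecule`, `m_start`, `m_end`, `p_start`, `p_end`,
#'   `orientation`, `length`, `identity`.
#' @export
find_cp_insertions <- function(mito, plastome, min_len = 500L, k = 21L,
                               gap = 500L, band = 50L) {
  stopifnot(min_len >= 100L)
  out <- list()
  Lp <- nchar(plastome)
  for (m in names(mito)) {
    for (orient in c("direct", "inverted")) {
      subj <- if (orient == "direct") plastome else revcomp(plastome)
      runs <- seed_match_runs(mito[[m]], subj, k = k)
      if (nrow(runs) == 0) next
      segs <- chain_runs(runs, gap = gap, band = band)
      segs <- segs[segs$m_end - segs$m_start + 1L >= min_len, , drop = FALSE]
      for (i in seq_len(nrow(segs))) {
        ps <- segs$p_start[i]; pe <- segs$p_end[i]
        if (orient == "inverted") {
          tmp <- ps
          ps <- Lp - pe + 1L
          pe <- Lp - tmp + 1L
        }
        out[[length(out) + 1L]] <- tibble::tibble(
          molecule = m, m_start = segs$m_start[i], m_end = segs$m_end[i],
          p_start = ps, p_end = pe, orientation = orient,
          length = segs$m_end[i] - segs$m_start[i] + 1L,
          identity = segs$identity[i])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(molecule = character(0), m_start = integer(0),
                          m_end = integer(0), p_start = integer(0),
                          p_end = integer(0), orientation = character(0),
                          length = integer(0), identity = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(-res$length), ]
}

# chain seed runs whose diagonals differ by <= band and whose gaps are <= gap
chain_runs <- function(runs, gap, band) {
  runs$diag <- runs$start_b - runs$start_a
  runs <- runs[order(runs$start_a), ]
  chain_id <- integer(nrow(runs))
  chains <- list()  # per open chain: list(end_a, diag, id)
  next_id <- 0L
  for (i in seq_len(nrow(runs))) {
    assigned <- FALSE
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      if (abs(runs$diag[i] - ch$diag) <= band &&
          runs$start_a[i] - ch$end_a <= gap) {
        chain_id[i] <- ch$id
        chains[[ci]]$end_a <- max(ch$end_a, runs$start_a[i] + runs$length[i] - 1L)
        chains[[ci]]$diag <- runs$diag[i]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      next_id <- next_id + 1L
      chain_id[i] <- next_id
      chains[[length(chains) + 1L]] <- list(
        end_a = runs$start_a[i] + runs$length[i] - 1L,
        diag = runs$diag[i], id = next_id)
    }
  }
  segs <- list()
  for (id in unique(chain_id)) {
    rr <- runs[chain_id == id, ]
    m_start <- min(rr$start_a); m_end <- max(rr$start_a + rr$length - 1L)
    cov <- merge_intervals(rr$start_a, rr$start_a + rr$length - 1L)
    covered <- sum(cov$end - cov$start + 1L)
    segs[[length(segs) + 1L]] <- data.frame(
      m_start = m_start, m_end = m_end,
      p_start = min(rr$start_b), p_end = max(rr$start_b + rr$length - 1L),
      identity = covered / (m_end - m_start + 1L))
  }
  do.call(rbind, segs)
}

#' Construct a quad pattern
#'
#' The four observed allele states at one locus of the shared insertion,
#' ordered (type1-chloro, type1-mito, type2-chloro, type2-mito), each "Ref"
#' (identical to the type 1 chloroplast reference) or "Alt".
#'
#' @param chloro_t1,mito_t1,chloro_t2,mito_t2 "Ref" or "Alt".
#' @param locus Optional locus label.
#' @param class Variant class ("SNP", "INS", "DEL").
#' @param polymorphic Whether any state is polymorphic within its type (the
#'   majority state should then be supplied, with this flag set).
#' @return A `quad_pattern` list.
#' @export
quad_pattern <- function(chloro_t1, mito_t1, chloro_t2, mito_t2,
                         locus = NA, class = "SNP", polymorphic = FALSE) {
  states <- c(chloro_t1 = chloro_t1, mito_t1 = mito_t1,
              chloro_t2 = chloro_t2, mito_t2 = mito_t2)
  if (!all(states %in% c("Ref", "Alt"))) {
    stop("quad pattern states must be 'Ref' or 'Alt'")
  }
  structure(list(locus = locus, class = class, states = states,
                 polymorphic = polymorphic),
            class = "quad_pattern")
}

#' Assign the organelle lineage in which an insertion variant arose
#'
#' Fitch parsimony on the fixed unrooted quartet
#' ((chloro_t1, chloro_t2), (mito_t1, mito_t2)). With a single
#' most-parsimonious change on a terminal branch, the call names that
#' lineage's organelle ("Mito"/"Chloro") and the branch; a change on the
#' internal branch is "Ambiguous" (the mutation predates the type split and
#' its organelle of origin is undecidable from the pattern); two required
#' changes is "Conflict"; an all-equal pattern is "NoVariant".
#'
#' @param pattern A [quad_pattern()].
#' @return Tibble with `locus`, `class`, `organelle`, `branch`,
#'   `parsimony_score`, `polymorphic`.
#' @export
assign_origin <- function(pattern) {
  stopifnot(inherits(pattern, "quad_pattern"))
  st <- pattern$states
  alt <- names(st)[st == "Alt"]
  n_alt <- length(alt)
  if (n_alt %in% c(0L, 4L)) {
    org <- "NoVariant"; branch <- NA_character_; score <- 0L
  } else if (n_alt %in% c(1L, 3L)) {
    # the odd state sits on one terminal branch
    odd <- if (n_alt == 1L) alt else names(st)[st == "Ref"]
    branch <- odd
    org <- if (startsWith(odd, "mito")) "Mito" else "Chloro"
    score <- 1L
  } else {
    # two Alt: along the tree split -> one internal change; across -> two
    if (setequal(alt, c("chloro_t1", "chloro_t2")) ||
        setequal(alt, c("mito_t1", "mito_t2"))) {
      org <- "Ambiguous"; branch <- "internal"; score <- 1L
    } else {
      org <- "Conflict"; branch <- NA_character_; score <- 2L
    }
  }
  tibble::tibble(locus = pattern$locus, class = pattern$class,
                 organelle = org, branch = branch, parsimony_score = score,
                 polymorphic = pattern$polymorphic)
}

#' Tally origin calls
#'
#' @param calls Tibble of [assign_origin()] rows (rbind'ed).
#' @return Tibble with `organelle`, `n` covering Mito, Chloro, Ambiguous,
#'   Conflict, NoVariant (zeros included).
#' @export
summarize_origins <- function(calls) {
  cats <- c("Mito", "Chloro", "Ambiguous", "Conflict", "NoVariant")
  n <- vapply(cats, function(cc)
    if (nrow(calls) == 0) 0L else sum(calls$organelle == cc), integer(1))
  tibble::tibble(organelle = cats, n = unname(n))
}

#' Separate chloroplast- and mitochondrion-borne alleles by frequency
#'
#' Over a shared insertion the plastome copy vastly outnumbers the mitogenome
#' copy in read depth; at each locus the majority allele is attributed to the
#' chloroplast and the strongest minor allele above `min_minor_freq` (if any)
#' to the mitochondrion. With no qualifying minor allele both organelles are
#' assigned the majority allele.
#'
#' @param counts Tibble with `offset` (locus), `allele`, `fwd`, `rev` (as from
#'   [simulate_insert_counts()]).
#' @param min_minor_freq Minimum minor-allele frequency (default 0.02).
#' @return Tibble with `offset`, `chloro_allele`, `mito_allele`,
#'   `mito_freq`.
#' @export
split_insert_alleles <- function(counts, min_minor_freq = 0.02) {
  out <- list()
  for (off in unique(counts$offset)) {
    sel <- counts[counts$offset == off, ]
    n <- sel$fwd + sel$rev
    depth <- sum(n)
    o <- order(-n)
    chloro <- sel$allele[o[1]]
    mito <- chloro
    freq <- 0
    if (length(o) > 1L) {
      f2 <- n[o[2]] / depth
      if (f2 >= min_minor_freq) {
        mito <- sel$allele[o[2]]
        freq <- f2
      }
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      offset = off, chloro_allele = chloro, mito_allele = mito,
      mito_freq = freq)
  }
  do.call(rbind, out)
}

#' Build quad patterns from per-type organelle allele calls
#'
#' Takes per-sample chloro/mito allele calls over insertion loci (from
#' [split_insert_alleles()]), forms the per-type consensus for each organelle,
#' and encodes states relative to the type 1 chloroplast consensus.
#'
#' @param calls_by_sample Named list of [split_insert_alleles()] outputs.
#' @param types Named integer vector (1/2) of sample types.
#' @param classes Optional named character vector mapping locus offset to
#'   variant class (default "SNP").
#' @return List of [quad_pattern()] objects (loci with more than two distinct
#'   states across the four consensuses are dropped with a warning).
#' @export
quad_patterns_from_calls <- function(calls_by_sample, types, classes = NULL) {
  all_off <- sort(unique(unlist(lapply(calls_by_sample, function(x) x$offset))))
  consensus <- function(v) names(sort(table(v), decreasing = TRUE))[1]
  pats <- list()
  dropped <- 0L
  for (off in all_off) {
    g <- list(chloro_t1 = character(0), mito_t1 = character(0),
              chloro_t2 = character(0), mito_t2 = character(0))
    poly <- FALSE
    for (s in names(calls_by_sample)) {
      row <- calls_by_sample[[s]][calls_by_sample[[s]]$offset == off, ]
      if (nrow(row) == 0) next
      tt <- if (types[[s]] == 1L) "t1" else "t2"
      g[[paste0("chloro_", tt)]] <- c(g[[paste0("chloro_", tt)]],
                                      row$chloro_allele)
      g[[paste0("mito_", tt)]] <- c(g[[paste0("mito_", tt)]], row$mito_allele)
    }
    cons <- vapply(g, consensus, character(1))
    poly <- any(vapply(g, function(v) length(unique(v)) > 1L, logical(1)))
    ref <- cons[["chloro_t1"]]
    alleles <- unique(cons)
    if (length(alleles) > 2L) {
      dropped <- dropped + 1L
      next
    }
    states <- ifelse(cons == ref, "Ref", "Alt")
    cls <- if (!is.null(classes) && as.character(off) %in% names(classes))
      classes[[as.character(off)]] else "SNP"
    pats[[length(pats) + 1L]] <- quad_pattern(
      states[["chloro_t1"]], states[["mito_t1"]],
      states[["chloro_t2"]], states[["mito_t2"]],
      locus = off, class = cls, polymorphic = poly)
  }
  if (dropped > 0) warning(dropped, " loci with >2 states dropped")
  pats
}
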