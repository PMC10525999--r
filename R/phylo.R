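# Marker-window concatenation, Jukes-Cantor distances, neighbor joining.

#' Build concatenated marker chromosomes from a variant matrix
#'
#' For every differential locus a window of `window` bp of reference sequence
#' centered on the locus anchor (positions anchor-19 ... anchor+20 for the
#' default 40) is extracted and the sample's allele substituted: SNPs replace
#' the anchor base, insertions lengthen the window's yield, deletions shorten
#' it. Windows are clipped at molecule ends; overlapping windows are merged
#' once with a warning. For cross-sample comparability each locus block is
#' right-padded with "-" to the block's maximum width.
#'
#' @param vm A `variant_matrix` (loci must carry `molecule`, `pos`, `ref`).
#' @param reference Named character vector of reference molecule sequences.
#' @param window Window width in bp (default 40).
#' @param pad Pad locus blocks to equal width with gaps (default TRUE).
#' @return List with `sequences` (named character vector, one per sample),
#'   `provenance` (tibble: `molecule`, `pos`, `win_start`, `win_end`,
#'   `block_start`, `block_end` in concatenated coordinates), and
#'   `aligned` (TRUE when padded).
#' @export
build_marker_chromosomes <- function(vm, reference, window = 40L, pad = TRUE) {
  loci <- vm$loci[order(vm$loci$molecule, vm$loci$pos), ]
  half_l <- window %/% 2L - 1L  # 19 for window 40
  half_r <- window - half_l - 1L  # 20
  n_loci <- nrow(loci)
  wins <- data.frame(molecule = loci$molecule,
                     start = pmax(1L, loci$pos - half_l),
                     end = loci$pos + half_r)
  for (m in unique(wins$molecule)) {
    wins$end[wins$molecule == m] <- pmin(wins$end[wins$molecule == m],
                                         nchar(reference[[m]]))
  }
  # merge overlapping windows (same molecule)
  drop <- rep(FALSE, n_loci)
  if (n_loci > 1) {
    for (i in 2:n_loci) {
      if (wins$molecule[i] == wins$molecule[i - 1L] &&
          wins$start[i] <= wins$end[i - 1L] && !drop[i - 1L]) {
        warning("overlapping marker windows at ", loci$molecule[i], ":",
                loci$pos[i], " merged")
        wins$end[i - 1L] <- max(wins$end[i - 1L], wins$end[i])
        drop[i] <- TRUE
      }
    }
  }
  samples <- rownames(vm$alleles)
  blocks <- vector("list", n_loci)
  for (j in which(!drop)) {
    ref_win <- str_at(reference[[loci$molecule[j]]], wins$start[j],
                      wins$end[j])
    anchor_off <- loci$pos[j] - wins$start[j] + 1L
    cells <- vm$alleles[, j]
    blk <- vapply(seq_along(samples), function(si) {
      a <- cells[si]
      if (is.na(a) || a == loci$ref[j]) return(ref_win)
      if (startsWith(a, "+")) {
        ins <- sub("^\\+", "", a)
        return(paste0(substr(ref_win, 1L, anchor_off), ins,
                      substr(ref_win, anchor_off + 1L, nchar(ref_win))))
      }
      if (startsWith(a, "-")) {
        dl <- nchar(sub("^-", "", a))
        return(paste0(substr(ref_win, 1L, anchor_off - 1L),
                      substr(ref_win, anchor_off + dl, nchar(ref_win))))
      }
      paste0(substr(ref_win, 1L, anchor_off - 1L), a,
             substr(ref_win, anchor_off + 1L, nchar(ref_win)))
    }, character(1))
    if (pad) {
      wmax <- max(nchar(blk))
      blk <- vapply(blk, function(s)
        paste0(s, strrep("-", wmax - nchar(s))), character(1))
    }
    blocks[[j]] <- blk
  }
  keep <- which(!drop)
  seqs <- stats::setNames(rep("", length(samples)), samples)
  prov <- list()
  at <- 1L
  for (j in keep) {
    blk <- blocks[[j]]
    wlen <- nchar(blk[1])
    seqs <- paste0(seqs, blk)
    prov[[length(prov) + 1L]] <- tibble::tibble(
      molecule = loci$molecule[j], pos = loci$pos[j],
      win_start = wins$start[j], win_end = wins$end[j],
      block_start = at, block_end = at + wlen - 1L)
    at <- at + wlen
  }
  names(seqs) <- samples
  list(sequences = seqs, provenance = do.call(rbind, prov), aligned = pad)
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' d = -(3/4) ln(1 - (4/3) p) with p the mismatch proportion over sites where
#' neither sequence has a gap. Undefined (error) when p >= 0.75 or no sites
#' remain.
#'
#' @param a,b Aligned sequences of equal length ("-" = gap).
#' @return The distance (numeric).
#' @export
jc_distance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("no comparable (gap-free) sites")
  p <- mean(ca[keep] != cb[keep])
  if (p >= 0.75) stop("mismatch proportion ", signif(p, 3),
                      " >= 0.75: Jukes-Cantor distance undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance matrix
#'
#' @param seqs Named character vector of aligned sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
jc_distance_matrix <- function(seqs) {
  n <- length(seqs)
  stopifnot(length(unique(nchar(seqs))) == 1L)
  ch <- do.call(rbind, strsplit(unname(seqs), ""))
  gap <- ch == "-"
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- !gap[i, ] & !gap[j, ]
      if (!any(keep)) stop("no comparable (gap-free) sites")
      p <- mean(ch[i, keep] != ch[j, keep])
      if (p >= 0.75) stop("mismatch proportion >= 0.75 between ",
                          names(seqs)[i], " and ", names(seqs)[j])
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei agglomeration on the Q-criterion with a deterministic
#' tie-break (the pair with the lowest taxon indices, in input order, among
#' Q-minimal pairs). Exact on additive distance matrices. Branch lengths may
#' be negative on non-additive input (left as computed).
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An [ape::phylo] unrooted tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  stopifnot(n >= 3)
  if (max(abs(dm - t(dm))) > 1e-9) stop("distance matrix is not symmetric")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.12g", x)
  sub <- labels          # newick substring per active node
  ids <- seq_len(n)      # original taxon index carried for tie-breaks
  D <- dm
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(pmin(ids[cand[, 1]], ids[cand[, 2]]),
                       pmax(ids[cand[, 1]], ids[cand[, 2]])), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    merged <- paste0("(", sub[i], ":", fmt(li), ",", sub[j], ":", fmt(lj), ")")
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    sub <- c(sub[keep], merged)
    ids <- c(ids[keep], min(ids[c(i, j)]))
  }
  # close with the unresolved central node joining the last three lineages
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", sub[1], ":", fmt(l1), ",", sub[2], ":", fmt(l2), ",",
                sub[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

#' Concatenate aligned sequence blocks
#'
#' @param blocks Named list of blocks; each block a named character vector of
#'   equal-length aligned sequences. Taxa missing from a block are gap-filled
#'   with a warning; duplicated taxa within a block are an error.
#' @return List with `alignment` (named character vector over the taxon
#'   union) and `map` (tibble: `block`, `start`, `end` in concatenated
#'   coordinates).
#' @export
concatenate_alignments <- function(blocks) {
  stopifnot(length(blocks) > 0, !is.null(names(blocks)))
  taxa <- character(0)
  for (b in names(blocks)) {
    if (anyDuplicated(names(blocks[[b]]))) {
      stop("duplicated taxon names in block ", b)
    }
    w <- nchar(blocks[[b]])
    if (length(unique(w)) != 1L) {
      stop("unequal sequence lengths within block ", b)
    }
    taxa <- union(taxa, names(blocks[[b]]))
  }
  out <- stats::setNames(rep("", length(taxa)), taxa)
  map <- list()
  at <- 1L
  for (b in names(blocks)) {
    blk <- blocks[[b]]
    w <- nchar(blk[[1]])
    missing <- setdiff(taxa, names(blk))
    if (length(missing)) {
      warning("block ", b, ": taxa gap-filled: ",
              paste(missing, collapse = ", "))
      blk[missing] <- strrep("-", w)
    }
    out <- paste0(out, blk[taxa])
    names(out) <- taxa
    map[[length(map) + 1L]] <- tibble::tibble(block = b, start = at,
                                              end = at + w - 1L)
    at <- at + w
  }
  list(alignment = out, map = do.call(rbind, map))
}
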