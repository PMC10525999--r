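# MISA-style perfect microsatellite (SSR) detection.

#' SSR repeat-count thresholds
#'
#' Minimum number of repetitions per motif length 1-6. The defaults (10, 6,
#' 5, 5, 5, 5 for mono- through hexanucleotide motifs) are the thresholds
#' used for the reference mitogenome SSR survey.
#'
#' @param min_repeats Integer vector of length 6.
#' @return An `ssr_thresholds` integer vector.
#' @export
ssr_thresholds <- function(min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  stopifnot(length(min_repeats) == 6, all(min_repeats >= 2))
  structure(as.integer(min_repeats), class = "ssr_thresholds")
}

is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L)) {
    if (m %% d == 0L && strrep(substr(motif, 1L, d), m %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical motif group label
#'
#' Merges a motif with all its rotations and its reverse complement's
#' rotations. Mononucleotide groups are labelled "A/T" and "G/C"; longer
#' motifs by the lexicographically smallest rotation over both strands
#' (joined with "/" when the two strands differ).
#'
#' @param motif Motif string.
#' @return Group label.
#' @export
canonical_motif <- function(motif) {
  if (nchar(motif) == 1L) {
    return(if (motif %in% c("A", "T")) "A/T" else "G/C")
  }
  rots <- function(s) {
    m <- nchar(s)
    vapply(seq_len(m), function(i) paste0(substr(s, i, m),
                                          substr(s, 1, i - 1)), character(1))
  }
  fwd <- min(rots(motif))
  rev <- min(rots(revcomp(motif)))
  if (fwd == rev) fwd else paste(sort(c(fwd, rev))[1],
                                 sort(c(fwd, rev))[2], sep = "/")
}

#' Find perfect microsatellites
#'
#' All maximal perfect tandem runs of primitive motifs 1-6 bp whose full
#' repeat count meets the class minimum. A run is reported once, under its
#' primitive motif, truncated to whole motif units. When qualifying runs
#' overlap, the longer one wins (tie: earlier start). Scanning is linear (no
#' wrap across circular origins).
#'
#' @param sequence Nucleotide string.
#' @param thresholds An [ssr_thresholds()].
#' @param molecule Molecule id recorded on the records.
#' @return Tibble with `molecule`, `start`, `end` (1-based inclusive),
#'   `motif`, `motif_length`, `repeats`, `length`, `group`.
#' @export
find_ssrs <- function(sequence, thresholds = ssr_thresholds(),
                      molecule = "molecule") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  ch <- strsplit(sequence, "")[[1]]
  recs <- list()
  for (m in 1:6) {
    if (n < m * 2L) next
    eq <- ch[seq_len(n - m)] == ch[seq.int(m + 1L, n)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (t in which(r$values)) {
      run_start <- starts[t]
      region_len <- r$lengths[t] + m          # length of the repeated region
      count <- region_len %/% m
      if (count < thresholds[m]) next
      motif <- substr(sequence, run_start, run_start + m - 1L)
      if (!is_primitive_motif(motif)) next
      recs[[length(recs) + 1L]] <- data.frame(
        molecule = molecule, start = run_start,
        end = run_start + count * m - 1L, motif = motif,
        motif_length = m, repeats = count, length = count * m)
    }
  }
  if (length(recs) == 0) {
    return(tibble::tibble(molecule = character(0), start = integer(0),
                          end = integer(0), motif = character(0),
                          motif_length = integer(0), repeats = integer(0),
                          length = integer(0), group = character(0)))
  }
  out <- do.call(rbind, recs)
  # overlap resolution: longer run wins; tie -> earlier start
  out <- out[order(-out$length, out$start, out$motif_length), ]
  kept <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!kept[i]) next
    later <- which(kept & seq_len(nrow(out)) > i)
    if (length(later)) {
      ov <- out$start[later] <= out$end[i] & out$end[later] >= out$start[i]
      kept[later[ov]] <- FALSE
    }
  }
  out <- out[kept, ]
  out <- out[order(out$start), ]
  out$group <- vapply(out$motif, canonical_motif, character(1))
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Summarize SSR records
#'
#' @param records Tibble from [find_ssrs()].
#' @return List with `by_motif_length` (tibble `motif_length`, `n`, lengths
#'   1-6 always present) and `by_group` (tibble `group`, `motif_length`, `n`).
#' @export
summarize_ssrs <- function(records) {
  by_len <- tibble::tibble(motif_length = 1:6, n = vapply(1:6, function(m)
    sum(records$motif_length == m), integer(1)))
  if (nrow(records) == 0) {
    by_group <- tibble::tibble(group = character(0), motif_length = integer(0),
                               n = integer(0))
  } else {
    tab <- stats::aggregate(start ~ group + motif_length, data = records,
                            FUN = length)
    names(tab)[3] <- "n"
    by_group <- tibble::as_tibble(tab[order(tab$motif_length, -tab$n), ])
  }
  list(by_motif_length = by_len, by_group = by_group)
}
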