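# Low-level sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_CODES <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of nucleotide sequences (A/C/G/T plus IUPAC codes).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random nucleotide sequence
#'
#' Bases drawn independently with the given GC content; uses the current RNG
#' state.
#'
#' @param n Sequence length in bp.
#' @param gc GC content in (0, 1); default 0.5 (uniform composition).
#' @return A single string of length `n`.
#' @export
random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. Used to give every forge sample its own sub-stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-sample sub-seed below 2^31.
sub_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + index * 16807) %% 2147483647
}

str_at <- function(s, start, end) substr(s, start, end)

# Replace s[start..end] by `repl` (may differ in length).
str_splice <- function(s, start, end, repl) {
  paste0(substr(s, 1L, start - 1L), repl, substr(s, end + 1L, nchar(s)))
}

# Rotate a circular sequence so that position `start` becomes position 1.
rotate_seq <- function(s, start) {
  if (start == 1L) return(s)
  paste0(substr(s, start, nchar(s)), substr(s, 1L, start - 1L))
}

#' Exact k-mer seed matches between two sequences
#'
#' Returns all maximal exact match runs of length >= k between `a` and `b`,
#' found by hashing k-mer starts and merging runs of seeds that lie on the
#' same alignment diagonal. Each run is a maximal exact match: it cannot be
#' extended in either direction (or it abuts a sequence end).
#'
#' @param a,b Nucleotide strings.
#' @param k Seed length (default 31).
#' @param self Logical; when TRUE, `a` and `b` are the same string and the
#'   identity diagonal plus mirror duplicates are suppressed.
#' @return A data.frame with columns `start_a`, `start_b`, `length`.
#' @keywords internal
seed_match_runs <- function(a, b, k = 31L, self = FALSE) {
  na <- nchar(a); nb <- nchar(b)
  empty <- data.frame(start_a = integer(0), start_b = integer(0),
                      length = integer(0))
  if (na < k || nb < k) return(empty)
  ka <- substring(a, 1:(na - k + 1L), k:na)
  kb <- if (self) ka else substring(b, 1:(nb - k + 1L), k:nb)
  common <- intersect(unique(ka), unique(kb))
  if (length(common) == 0) return(empty)
  ia <- which(ka %in% common)
  ib <- which(kb %in% common)
  pa <- split(ia, ka[ia])
  pb <- if (self) pa else split(ib, kb[ib])
  pb <- pb[names(pa)]
  # full cross join of positions per shared k-mer
  la <- lengths(pa); lb <- lengths(pb)
  sa <- unlist(mapply(function(x, nrep) rep(x, each = nrep), pa, lb,
                      SIMPLIFY = FALSE), use.names = FALSE)
  sb <- unlist(mapply(function(x, ntimes) rep.int(x, ntimes), pb, la,
                      SIMPLIFY = FALSE), use.names = FALSE)
  if (self) {
    keep <- sa < sb  # drop identity diagonal and mirror pairs
    sa <- sa[keep]; sb <- sb[keep]
  }
  if (length(sa) == 0) return(empty)
  d <- sb - sa
  ord <- order(d, sa)
  sa <- sa[ord]; sb <- sb[ord]; d <- d[ord]
  new_run <- c(TRUE, diff(sa) != 1L | diff(d) != 0L)
  run_id <- cumsum(new_run)
  first <- which(new_run)
  run_len <- diff(c(first, length(sa) + 1L))
  data.frame(start_a = sa[first], start_b = sb[first],
             length = run_len + k - 1L)
}

# Merge overlapping/nearby integer intervals (1-based inclusive) given as a
# two-column matrix/data.frame; gap = maximum separation to bridge.
merge_intervals <- function(starts, ends, gap = 0L) {
  if (length(starts) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  r <- IRanges::reduce(IRanges::IRanges(starts, ends), min.gapwidth = gap + 1L)
  data.frame(start = IRanges::start(r), end = IRanges::end(r))
}
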