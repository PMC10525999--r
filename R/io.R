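# Readers/writers for the formats the pipeline touches, plus in-silico PCR.
#
# Coordinates are 1-based inclusive everywhere at the interface.
#
# Allele string conventions (used by pileup tables and the variant matrix):
#   "A"/"C"/"G"/"T"  a (possibly reference-matching) base or SNP allele
#   "+SEQ"           insertion of SEQ after the anchor base
#   "-SEQ"           deletion of SEQ starting at the anchor base
# In rendered matrices insertions show their first two inserted bases and
# deletions show "D", with reference-matching cells collapsed to "-".

#' Read a FASTA file
#'
#' Sequences are uppercased; characters outside the IUPAC nucleotide alphabet
#' are rejected, as are duplicate identifiers and empty files.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  # readDNAStringSet drops invalid one-letter codes with a warning; reject
  # them outright instead
  lines <- readLines(path)
  body <- toupper(paste(gsub("\\s", "", lines[!startsWith(lines, ">")]),
                        collapse = ""))
  codes <- unique(strsplit(body, "")[[1]])
  bad <- setdiff(codes, c(IUPAC_CODES, "-"))
  if (length(bad)) {
    stop("non-IUPAC nucleotide codes in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector of nucleotide sequences.
#' @param path Output path.
#' @param width Line width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(length(records) > 0, !is.null(names(records)))
  bad <- vapply(records, function(s) {
    any(!strsplit(s, "")[[1]] %in% c(IUPAC_CODES, "-"))
  }, logical(1))
  if (any(bad)) stop("non-IUPAC characters in records: ",
                     paste(names(records)[bad], collapse = ", "))
  set <- Biostrings::DNAStringSet(toupper(records))
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a pileup allele-count table
#'
#' The pipeline's lingua franca: a TSV with header columns `molecule`, `pos`,
#' `allele`, `fwd`, `rev` giving per-(molecule, position, allele) read counts
#' split by strand, after any base-quality floor was applied upstream.
#'
#' @param path Path to the TSV.
#' @param molecule_lengths Optional named vector; positions outside the
#'   declared molecule length are rejected.
#' @return A tibble of class `pileup` with the five columns above.
#' @export
read_pileup_tsv <- function(path, molecule_lengths = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "character",
                                        "integer", "integer"))
  if (!identical(names(x), c("molecule", "pos", "allele", "fwd", "rev"))) {
    stop("pileup TSV must have header: molecule, pos, allele, fwd, rev")
  }
  as_pileup(x, molecule_lengths = molecule_lengths)
}

#' Validate and class a pileup table
#'
#' @param x Data frame with columns `molecule`, `pos`, `allele`, `fwd`, `rev`.
#' @inheritParams read_pileup_tsv
#' @return A tibble of class `pileup`.
#' @export
as_pileup <- function(x, molecule_lengths = NULL) {
  stopifnot(all(c("molecule", "pos", "allele", "fwd", "rev") %in% names(x)))
  if (any(x$fwd < 0 | x$rev < 0)) stop("negative allele counts")
  if (any(x$pos < 1)) stop("positions must be >= 1")
  key <- paste(x$molecule, x$pos, x$allele)
  if (anyDuplicated(key)) {
    stop("duplicate (molecule, pos, allele) rows: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  if (!is.null(molecule_lengths)) {
    lim <- molecule_lengths[x$molecule]
    if (any(is.na(lim))) stop("rows for undeclared molecules")
    if (any(x$pos > lim)) stop("positions beyond declared molecule length")
  }
  out <- tibble::as_tibble(x[, c("molecule", "pos", "allele", "fwd", "rev")])
  class(out) <- c("pileup", class(out))
  out
}

#' Write a pileup table
#'
#' @param x A `pileup` table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pileup_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("molecule", "pos", "allele",
                                          "fwd", "rev")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-locus depth of a pileup table
#'
#' @param x A `pileup` table.
#' @return Tibble with `molecule`, `pos`, `depth` (sum of all allele counts).
#' @export
pileup_depth <- function(x) {
  agg <- stats::aggregate(fwd + rev ~ molecule + pos, data = x, FUN = sum)
  names(agg)[3] <- "depth"
  tibble::as_tibble(agg[order(agg$molecule, agg$pos), ])
}

#' Render a variant matrix as text
#'
#' First row shows the reference alleles; from the second row on, cells equal
#' to the reference are shown as "-", insertion alleles by their first two
#' inserted bases, and deletion alleles by "D".
#'
#' @param vm A `variant_matrix` (see [build_variant_matrix()]): a list with a
#'   `loci` tibble (columns `molecule`, `pos`, `ref`) and an `alleles`
#'   character matrix (samples x loci, full allele strings).
#' @return Character matrix with a leading `Reference` row; column names are
#'   `molecule:pos`.
#' @export
render_variant_matrix <- function(vm) {
  loci <- vm$loci
  alle <- vm$alleles
  render_allele <- function(a) {
    ifelse(is.na(a), ".",
    ifelse(startsWith(a, "+"), substr(sub("^\\+", "", a), 1, 2),
    ifelse(startsWith(a, "-"), "D", a)))
  }
  out <- matrix("-", nrow = nrow(alle), ncol = ncol(alle),
                dimnames = dimnames(alle))
  differs <- !is.na(alle) & alle != rep(loci$ref, each = nrow(alle))
  out[differs] <- render_allele(alle)[differs]
  out[is.na(alle)] <- "."
  ref_row <- matrix(render_allele(loci$ref), nrow = 1,
                    dimnames = list("Reference", colnames(alle)))
  res <- rbind(ref_row, out)
  colnames(res) <- paste0(loci$molecule, ":", loci$pos)
  res
}

#' In-silico PCR
#'
#' Exact-match search of the forward primer and the reverse complement of the
#' reverse primer on both strands of the template; a product spans both primer
#' footprints inclusively. Circular templates are searched across the origin.
#'
#' @param template A single nucleotide string.
#' @param fwd,rev Primer sequences, 5'->3', each >= 15 nt.
#' @param circular Is the template circular?
#' @param max_product Maximum product size in bp (default 20000).
#' @param template_id Identifier recorded in the output.
#' @return Tibble with columns `template`, `start`, `end`, `length`, `strand`
#'   (strand carrying the forward primer). Coordinates are 1-based inclusive
#'   on the input template (products crossing a circular origin have
#'   `end` = `start` + `length` - 1 > template length). Empty when no product.
#' @export
insilico_pcr <- function(template, fwd, rev, circular = FALSE,
                         max_product = 20000L, template_id = "template") {
  stopifnot(nchar(fwd) >= 15, nchar(rev) >= 15)
  template <- toupper(template)
  fwd <- toupper(fwd); rev <- toupper(rev)
  L <- nchar(template)
  search <- if (circular) paste0(template, template) else template
  find_all <- function(pat) {
    m <- gregexpr(pat, search, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  pair_up <- function(left_pat, right_pat, strand) {
    ls <- find_all(left_pat); rs <- find_all(right_pat)
    if (length(ls) == 0 || length(rs) == 0) return(NULL)
    wl <- nchar(left_pat); wr <- nchar(right_pat)
    grid <- expand.grid(a = ls, b = rs)
    grid$end <- grid$b + wr - 1L
    grid$len <- grid$end - grid$a + 1L
    keep <- grid$b >= grid$a + wl & grid$len <= max_product
    if (circular) keep <- keep & grid$a <= L & grid$len <= L
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid) == 0) return(NULL)
    data.frame(template = template_id, start = grid$a, end = grid$end,
               length = grid$len, strand = strand)
  }
  out <- rbind(pair_up(fwd, revcomp(rev), "+"),
               pair_up(rev, revcomp(fwd), "-"))
  if (is.null(out)) {
    return(tibble::tibble(template = character(0), start = integer(0),
                          end = integer(0), length = integer(0),
                          strand = character(0)))
  }
  out <- out[order(out$start, out$length, out$strand), ]
  out <- out[!duplicated(paste(out$start, out$end, out$strand)), , drop = FALSE]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}
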