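# Variant and heteroplasmy calling from allele-count tables, population
# variant matrix, germplasm typing, and population summary aggregation.

#' Heteroplasmy filter parameters
#'
#' The recording rule for minor alleles: frequency at least `min_minor_freq`
#' of the quality-passing depth at the locus, at least one supporting read on
#' each strand (when `require_both_strands`), and the locus outside `mask`.
#' `min_phred` documents the per-base quality floor assumed to have been
#' applied upstream when the counts were made.
#'
#' @param min_minor_freq Minimum minor-allele frequency (default 0.02).
#' @param min_phred Base-quality floor (default 20; metadata only here).
#' @param require_both_strands Require >= 1 read in each orientation
#'   (default TRUE).
#' @param mask Optional tibble (`molecule`, `start`, `end`) of excluded
#'   intervals (1-based inclusive).
#' @return A `het_filter_params` list.
#' @export
het_filter_params <- function(min_minor_freq = 0.02, min_phred = 20L,
                              require_both_strands = TRUE, mask = NULL) {
  stopifnot(min_minor_freq > 0, min_minor_freq < 0.5)
  structure(list(min_minor_freq = min_minor_freq,
                 min_phred = as.integer(min_phred),
                 require_both_strands = isTRUE(require_both_strands),
                 mask = mask),
            class = "het_filter_params")
}

in_mask <- function(molecule, pos, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(mask))) {
    hit <- hit | (molecule == mask$molecule[i] &
                  pos >= mask$start[i] & pos <= mask$end[i])
  }
  hit
}

#' Mask mitogenome intervals homologous to the plastome or nuclear decoys
#'
#' Reads from plastome or nuclear copies of mitogenome sequence masquerade as
#' organelle heteroplasmy; intervals of the mitogenome with an exact seeded
#' match of at least `min_len` (merged within `gap`) in any of the other
#' sequences are excluded from heteroplasmy calling. The shared plastid-derived
#' insertion interval, when given, is carved out of the mask: it is analyzed,
#' not discarded.
#'
#' @param mito Named character vector of mitogenome molecule sequences.
#' @param plastome Plastome sequence (string), or NULL.
#' @param decoys Named character vector of nuclear decoy contigs, or NULL.
#' @param min_len Minimum homology length to mask (default 300 bp).
#' @param k Seed length (default 21).
#' @param gap Merge distance between neighboring matches (default 200 bp).
#' @param exclude Optional tibble (`molecule`, `start`, `end`): intervals
#'   removed from the mask (e.g. the insertion under study).
#' @return Tibble (`molecule`, `start`, `end`) of masked intervals.
#' @export
build_homology_mask <- function(mito, plastome = NULL, decoys = NULL,
                                min_len = 300L, k = 21L, gap = 200L,
                                exclude = NULL) {
  others <- c(if (!is.null(plastome)) list(plastome = plastome),
              as.list(decoys))
  out <- list()
  for (m in names(mito)) {
    ivs <- list()
    for (o in names(others)) {
      for (orient in c("fwd", "rc")) {
        subj <- if (orient == "fwd") others[[o]] else revcomp(others[[o]])
        runs <- seed_match_runs(mito[[m]], subj, k = k)
        if (nrow(runs)) {
          ivs[[length(ivs) + 1L]] <- data.frame(
            start = runs$start_a, end = runs$start_a + runs$length - 1L)
        }
      }
    }
    if (length(ivs) == 0) next
    iv <- do.call(rbind, ivs)
    merged <- merge_intervals(iv$start, iv$end, gap = gap)
    merged <- merged[merged$end - merged$start + 1L >= min_len, , drop = FALSE]
    if (nrow(merged)) {
      out[[m]] <- tibble::tibble(molecule = m, start = merged$start,
                                 end = merged$end)
    }
  }
  mask <- if (length(out)) do.call(rbind, out) else
    tibble::tibble(molecule = character(0), start = integer(0),
                   end = integer(0))
  if (!is.null(exclude) && nrow(mask) > 0) {
    kept <- list()
    for (i in seq_len(nrow(mask))) {
      r <- IRanges::IRanges(mask$start[i], mask$end[i])
      ex <- exclude[exclude$molecule == mask$molecule[i], , drop = FALSE]
      if (nrow(ex)) {
        r <- IRanges::setdiff(r, IRanges::IRanges(ex$start, ex$end))
      }
      if (length(r)) {
        kept[[length(kept) + 1L]] <- tibble::tibble(
          molecule = mask$molecule[i], start = IRanges::start(r),
          end = IRanges::end(r))
      }
    }
    mask <- if (length(kept)) do.call(rbind, kept) else mask[0, ]
  }
  mask
}

allele_class <- function(allele, ref) {
  ifelse(startsWith(allele, "+"), "INS",
  ifelse(startsWith(allele, "-"), "DEL",
  ifelse(allele == ref, "REF", "SNP")))
}

#' Call variants against reference alleles
#'
#' A variant is called at a locus when the sample's majority allele differs
#' from the reference allele; loci below `min_depth` are reported as no-calls,
#' distinct from reference matches.
#'
#' @param pileup A `pileup` table for one sample.
#' @param ref_alleles Tibble (`molecule`, `pos`, `ref`) of reference alleles
#'   at the loci of interest; loci absent from the pileup are zero-depth
#'   no-calls.
#' @param min_depth Minimum depth to make a call (default 10).
#' @return Tibble with `molecule`, `pos`, `ref`, `allele` (majority), `depth`,
#'   `call` ("variant", "reference" or "no_call") and `class`
#'   (SNP/INS/DEL/REF, NA for no-calls).
#' @export
call_variants <- function(pileup, ref_alleles, min_depth = 10L) {
  key <- paste(pileup$molecule, pileup$pos)
  out <- ref_alleles
  out$allele <- NA_character_
  out$depth <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- key == paste(out$molecule[i], out$pos[i])
    if (!any(sel)) next
    cnt <- pileup$fwd[sel] + pileup$rev[sel]
    out$depth[i] <- sum(cnt)
    top <- which.max(cnt)
    out$allele[i] <- pileup$allele[sel][top]
  }
  out$call <- ifelse(out$depth < min_depth, "no_call",
              ifelse(out$allele == out$ref, "reference", "variant"))
  out$call[is.na(out$allele)] <- "no_call"
  out$class <- ifelse(out$call == "variant",
                      allele_class(out$allele, out$ref), NA_character_)
  out$class[out$call == "reference"] <- "REF"
  tibble::as_tibble(out)
}

#' Call heteroplasmy from an allele-count table
#'
#' Automates minor-allele inspection: at each locus, every non-majority allele
#' whose frequency is at least `params$min_minor_freq`, with at least one
#' supporting read on each strand (when required), at a locus outside the
#' mask, is recorded together with the major allele and its frequency.
#'
#' @param pileup A `pileup` table for one sample (counts already restricted to
#'   bases passing the quality floor).
#' @param params A [het_filter_params()].
#' @return Tibble with `molecule`, `pos`, `depth`, `major_allele`,
#'   `major_freq`, `minor_allele`, `minor_freq`, `minor_fwd`, `minor_rev`.
#' @export
call_heteroplasmy <- function(pileup, params = het_filter_params()) {
  key <- paste(pileup$molecule, pileup$pos)
  cnt <- pileup$fwd + pileup$rev
  out <- list()
  for (kk in unique(key)) {
    sel <- which(key == kk)
    depth <- sum(cnt[sel])
    if (depth == 0) next
    top <- sel[which.max(cnt[sel])]
    if (in_mask(pileup$molecule[top], pileup$pos[top], params$mask)) next
    for (j in setdiff(sel, top)) {
      freq <- cnt[j] / depth
      if (freq < params$min_minor_freq) next
      if (params$require_both_strands &&
          (pileup$fwd[j] < 1L || pileup$rev[j] < 1L)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        molecule = pileup$molecule[top], pos = pileup$pos[top], depth = depth,
        major_allele = pileup$allele[top], major_freq = cnt[top] / depth,
        minor_allele = pileup$allele[j], minor_freq = freq,
        minor_fwd = pileup$fwd[j], minor_rev = pileup$rev[j])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(molecule = character(0), pos = integer(0),
                          depth = integer(0), major_allele = character(0),
                          major_freq = numeric(0), minor_allele = character(0),
                          minor_freq = numeric(0), minor_fwd = integer(0),
                          minor_rev = integer(0)))
  }
  do.call(rbind, out)
}

#' Build the population variant matrix
#'
#' @param calls_by_sample Named list of [call_variants()] outputs (one per
#'   sample, same loci).
#' @param loci Tibble (`molecule`, `pos`, `ref`) defining column order.
#' @return A `variant_matrix`: list with `loci` and an `alleles` character
#'   matrix (samples x loci; NA = no-call).
#' @export
build_variant_matrix <- function(calls_by_sample, loci) {
  loci <- loci[order(loci$molecule, loci$pos), ]
  key <- paste(loci$molecule, loci$pos)
  alle <- matrix(NA_character_, nrow = length(calls_by_sample),
                 ncol = nrow(loci),
                 dimnames = list(names(calls_by_sample), key))
  for (s in names(calls_by_sample)) {
    cs <- calls_by_sample[[s]]
    ck <- paste(cs$molecule, cs$pos)
    m <- match(key, ck)
    a <- cs$allele[m]
    a[cs$call[m] == "no_call"] <- NA_character_
    alle[s, ] <- a
  }
  structure(list(loci = loci, alleles = alle), class = "variant_matrix")
}

#' Assign samples to germplasm types
#'
#' Majority vote over differential loci: a sample's fraction of loci whose
#' major allele equals the type 2 allele decides the type. The marker flag is
#' independent evidence (mean marker depth at least half the genome median
#' depth); a vote/marker discordance is reported, never silently resolved.
#'
#' @param vm A `variant_matrix`.
#' @param type_alleles Tibble (`molecule`, `pos`, `type1_allele`,
#'   `type2_allele`) for the differential loci.
#' @param marker_depth Named numeric vector: mean depth over the marker
#'   fragment per sample.
#' @param genome_median_depth Named numeric vector (or scalar): median genome
#'   depth per sample.
#' @param het_by_sample Optional named list of [call_heteroplasmy()] outputs;
#'   the median minor-allele frequency at differential loci is reported.
#' @return Tibble with `sample`, `type` (1/2/NA), `frac_type2`, `n_loci`,
#'   `marker_present`, `discordant`, `het_median_minor_freq`.
#' @export
type_samples <- function(vm, type_alleles, marker_depth = NULL,
                         genome_median_depth = NULL, het_by_sample = NULL) {
  stopifnot(nrow(type_alleles) >= 1)
  key <- paste(vm$loci$molecule, vm$loci$pos)
  tkey <- paste(type_alleles$molecule, type_alleles$pos)
  cols <- match(tkey, key)
  ok <- !is.na(cols)
  t2 <- type_alleles$type2_allele[ok]
  cols <- cols[ok]
  dkey <- tkey[ok]
  out <- list()
  for (s in rownames(vm$alleles)) {
    a <- vm$alleles[s, cols]
    covered <- !is.na(a)
    n <- sum(covered)
    frac <- if (n > 0) mean(a[covered] == t2[covered]) else NA_real_
    type <- if (n == 0) NA_integer_ else if (frac > 0.5) 2L else 1L
    mp <- NA
    if (!is.null(marker_depth)) {
      gmd <- if (length(genome_median_depth) > 1)
        genome_median_depth[[s]] else genome_median_depth
      mp <- marker_depth[[s]] >= 0.5 * gmd
    }
    disc <- !is.na(mp) && !is.na(type) && ((type == 2L) != mp)
    hmed <- NA_real_
    if (!is.null(het_by_sample) && !is.null(het_by_sample[[s]])) {
      h <- het_by_sample[[s]]
      hk <- paste(h$molecule, h$pos)
      hv <- h$minor_freq[hk %in% dkey]
      if (length(hv)) hmed <- stats::median(hv)
    }
    out[[s]] <- tibble::tibble(sample = s, type = type, frac_type2 = frac,
                               n_loci = n, marker_present = mp,
                               discordant = disc,
                               het_median_minor_freq = hmed)
  }
  do.call(rbind, out)
}

#' Aggregate population variant counts per chromosome and class
#'
#' For each chromosome and variant class, counts loci at which at least one
#' sample of a type carries a non-reference major allele ("vs. Ref" columns),
#' with parenthetical exclusive counts: alternate alleles observed as the
#' major allele in at least one sample of exactly one type. `total` counts
#' distinct variant loci. A grand-total row is appended.
#'
#' @param vm A `variant_matrix` whose loci carry `molecule`, `pos`, `ref`.
#' @param types Named integer vector (1/2) of sample types.
#' @return Tibble with `chromosome`, `class`, `type2_n`, `type2_exclusive`,
#'   `type1_n`, `type1_exclusive`, `total`.
#' @export
aggregate_counts <- function(vm, types) {
  loci <- vm$loci
  alle <- vm$alleles
  types <- types[rownames(alle)]
  res <- list()
  classes <- c("DEL", "INS", "SNP")
  for (chrom in unique(loci$molecule)) {
    for (cl in classes) {
      t2n <- t2x <- t1n <- t1x <- tot <- 0L
      for (j in which(loci$molecule == chrom)) {
        ref <- loci$ref[j]
        a <- alle[, j]
        variant <- !is.na(a) & a != ref
        if (!any(variant)) next
        acl <- allele_class(a[variant], ref)
        keep <- acl == cl
        if (!any(keep)) next
        valle <- unique(a[variant][keep])
        who <- types[variant][keep]
        in2 <- any(who == 2L); in1 <- any(who == 1L)
        tot <- tot + 1L
        if (in2) t2n <- t2n + 1L
        if (in1) t1n <- t1n + 1L
        # exclusivity is per alternate allele
        for (v in valle) {
          w <- types[variant][keep][a[variant][keep] == v]
          if (any(w == 2L) && !any(w == 1L)) t2x <- t2x + 1L
          if (any(w == 1L) && !any(w == 2L)) t1x <- t1x + 1L
        }
      }
      res[[length(res) + 1L]] <- tibble::tibble(
        chromosome = chrom, class = cl, type2_n = t2n, type2_exclusive = t2x,
        type1_n = t1n, type1_exclusive = t1x, total = tot)
    }
  }
  out <- do.call(rbind, res)
  grand <- tibble::tibble(chromosome = "Total", class = "All",
                          type2_n = sum(out$type2_n),
                          type2_exclusive = sum(out$type2_exclusive),
                          type1_n = sum(out$type1_n),
                          type1_exclusive = sum(out$type1_exclusive),
                          total = sum(out$total))
  rbind(out, grand)
}
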