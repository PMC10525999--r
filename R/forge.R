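# Synthetic multipartite organelle genome / population forge.
#
# The forge builds a two-cytotype population with known ground truth:
#   * a type 1 reference mitogenome of two circular molecules (LS1, LS2)
#     totalling 399,572 bp, carrying planted long repeat pairs;
#   * a type 2 genome derived from it by 254 differential loci (SNP/INS/DEL
#     with a segregation structure mirroring the published population counts),
#     a 2,108 bp type-2-exclusive marker fragment with planted PCR primer
#     sites (990 bp / 289 bp junction products), and a 97,120 bp linear
#     chromosome whose halves copy LS1/LS2 segments (multicopy regions);
#   * a 9,798 bp plastid-derived insertion present in both organelle genomes,
#     with post-insertion variants planted on known branches of the fixed
#     quartet (type1-chloro, type1-mito, type2-chloro, type2-mito);
#   * one nuclear decoy contig carrying a diverged copy of a mitogenome
#     segment, to exercise homology masking;
#   * 45 type 1 + 39 type 2 samples, one of which is heteroplasmic at 4%.
#
# All randomness flows from `config$seed`; each sample draws from its own
# sub-stream so adding samples never shifts earlier samples' draws.

#' Default differential-locus plan
#'
#' Per-molecule, per-class locus counts with their segregation structure:
#' `t2_fixed` (all type 2 samples carry the alternate allele), `t2_subset` /
#' `t1_subset` (a within-type subset carries it), `shared` (all type 2 plus
#' one type 1 sample), and `dual` (type 2 carries one alternate allele while
#' a type 1 subset carries a different one). The default reproduces the
#' published population's per-chromosome variant-count cells: 254 loci in
#' total, 143 SNP / 52 INS / 59 DEL, 230 type-2-exclusive and 16
#' type-1-exclusive alternate alleles.
#'
#' @return Tibble with columns `molecule`, `class`, `segregation`, `count`.
#' @export
locus_plan_default <- function() {
  tibble::tribble(
    ~molecule, ~class, ~segregation, ~count,
    "LS1", "SNP", "t2_fixed", 75L,
    "LS1", "SNP", "t1_subset", 9L,
    "LS1", "SNP", "shared",    4L,
    "LS1", "INS", "t2_fixed", 34L,
    "LS1", "DEL", "t2_fixed", 29L,
    "LS1", "DEL", "t1_subset", 3L,
    "LS2", "SNP", "t2_fixed", 54L,
    "LS2", "SNP", "t1_subset", 1L,
    "LS2", "INS", "t2_fixed", 17L,
    "LS2", "INS", "shared",    1L,
    "LS2", "DEL", "t2_fixed", 16L,
    "LS2", "DEL", "t2_subset", 4L,
    "LS2", "DEL", "t1_subset", 2L,
    "LS2", "DEL", "shared",    4L,
    "LS2", "DEL", "dual",      1L)
}

#' Simple differential-locus plan
#'
#' All loci fixed between the types (type-2-exclusive), split across molecules
#' proportionally to length and across classes by `props`.
#'
#' @param n Total number of loci.
#' @param props Named class proportions (`SNP`, `INS`, `DEL`); default mirrors
#'   the 143/52/59 population split.
#' @param molecules Character vector of molecule names (default LS1, LS2).
#' @return Tibble as in [locus_plan_default()].
#' @export
locus_plan_simple <- function(n, props = c(SNP = 143, INS = 52, DEL = 59) / 254,
                              molecules = c("LS1", "LS2")) {
  stopifnot(abs(sum(props) - 1) < 1e-8)
  per_class <- round(n * props)
  per_class[1] <- n - sum(per_class[-1])
  out <- list()
  for (cl in names(per_class)) {
    k <- per_class[[cl]]
    if (k <= 0) next
    split_n <- diff(round(seq(0, k, length.out = length(molecules) + 1)))
    for (i in seq_along(molecules)) {
      if (split_n[i] > 0)
        out[[length(out) + 1]] <- tibble::tibble(
          molecule = molecules[i], class = cl,
          segregation = "t2_fixed", count = as.integer(split_n[i]))
    }
  }
  do.call(rbind, out)
}

#' Default plan of post-insertion variants inside the plastid-derived insert
#'
#' Branches of the fixed quartet on which mutations are planted, with class
#' counts mirroring the published insert-variant table: 20 type-differential
#' variants (15 SNP, 4 DEL, 1 INS across the four terminal branches, one of
#' them polymorphic within type 1 chloroplasts) plus 72 ancestral
#' mitochondrial-lineage variants (44 SNP, 6 INS, 22 DEL) shared by both
#' types, which cannot be localized beyond the internal branch.
#'
#' @return Tibble with columns `branch`, `class`, `count`.
#' @export
cp_variant_plan_default <- function() {
  tibble::tribble(
    ~branch, ~class, ~count,
    "mito_t1",        "SNP", 5L,
    "mito_t1",        "DEL", 2L,
    "mito_t2",        "SNP", 4L,
    "mito_t2",        "DEL", 2L,
    "chloro_t2",      "SNP", 3L,
    "chloro_t1",      "SNP", 2L,
    "chloro_t1",      "INS", 1L,
    "chloro_t1_poly", "SNP", 1L,
    "mito_anc",       "SNP", 44L,
    "mito_anc",       "INS", 6L,
    "mito_anc",       "DEL", 22L)
}

#' Forge configuration
#'
#' Parameters of the synthetic population. Defaults emulate the study
#' conditions: two circular reference molecules totalling 399,572 bp, a
#' 97,120 bp type-2 linear chromosome, a 2,108 bp marker fragment, a 9,798 bp
#' plastid insertion, 254 differential loci, 45 + 39 samples, 4 %
#' heteroplasmy in one sample, 100x coverage, 150 bp reads, 0.1 % substitution
#' error, and linear ends truncated by up to 18 kb.
#'
#' @param seed Integer seed; all forge randomness derives from it.
#' @param molecule_specs Named list of reference molecules, each
#'   `list(length =, topology = "circular"|"linear")`.
#' @param repeat_specs List of planted repeat pairs, each
#'   `list(length =, orientation = "direct"|"inverted", molecule = c(m1, m2),
#'   start = c(s1, s2))`.
#' @param type2_linear `list(name =, length =)` for the type-2-only linear
#'   chromosome built from copies of LS1/LS2 segments, or `NULL`.
#' @param marker_length,marker_molecule,marker_pos Type-2-exclusive marker
#'   fragment length and its insertion point (type 1 coordinates; the
#'   fragment is inserted after `marker_pos`).
#' @param cp_insert_length,cp_insert_molecule,cp_insert_pos Plastid-derived
#'   insertion length and the mitogenome interval it occupies (present in
#'   both types).
#' @param plastome_length,cp_insert_plastome_pos Plastome length and the
#'   position of the homologous segment within it.
#' @param cp_variant_plan Tibble from [cp_variant_plan_default()].
#' @param locus_plan Tibble from [locus_plan_default()] /
#'   [locus_plan_simple()]; optional `pos` column fixes locus positions.
#' @param n_samples_per_type Integer vector `c(type1, type2)`.
#' @param heteroplasmy_fraction Minor-genome fraction in heteroplasmic
#'   samples; must be < 0.5.
#' @param n_het_samples Number of type 1 samples carrying that fraction
#'   (the first ones); all others have fraction 0.
#' @param coverage Mean reads-per-base.
#' @param cp_coverage_ratio Plastome:mitogenome coverage ratio used when
#'   simulating read evidence over the shared insertion.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error probability.
#' @param taper_max Maximum end truncation of linear molecule copies (bp).
#' @param decoy_length,decoy_divergence Length and per-base divergence of the
#'   nuclear decoy copy of a mitogenome segment.
#' @param background_positions Number of invariant positions carried along in
#'   simulated pileups (specificity controls).
#' @param gc_content GC content of generated sequence (default 0.448, the
#'   genome-wide value of the emulated mitogenome).
#' @return A `forge_config` list.
#' @export
forge_config <- function(seed = 1L,
                         molecule_specs = list(
                           LS1 = list(length = 250000L, topology = "circular"),
                           LS2 = list(length = 149572L, topology = "circular")),
                         repeat_specs = list(
                           list(length = 2000L, orientation = "direct",
                                molecule = c("LS1", "LS1"),
                                start = c(20001L, 120001L)),
                           list(length = 1500L, orientation = "inverted",
                                molecule = c("LS1", "LS1"),
                                start = c(150001L, 164347L)),
                           list(length = 35L, orientation = "direct",
                                molecule = c("LS2", "LS2"),
                                start = c(100001L, 130001L))),
                         type2_linear = list(name = "M3", length = 97120L),
                         marker_length = 2108L,
                         marker_molecule = "LS2",
                         marker_pos = 120000L,
                         cp_insert_length = 9798L,
                         cp_insert_molecule = "LS2",
                         cp_insert_pos = 35001L,
                         plastome_length = 161537L,
                         cp_insert_plastome_pos = 30001L,
                         cp_variant_plan = cp_variant_plan_default(),
                         locus_plan = locus_plan_default(),
                         n_samples_per_type = c(45L, 39L),
                         heteroplasmy_fraction = 0.04,
                         n_het_samples = 1L,
                         coverage = 100,
                         cp_coverage_ratio = 10,
                         read_length = 150L,
                         error_rate = 0.001,
                         taper_max = 18000L,
                         decoy_length = 5000L,
                         decoy_divergence = 0.01,
                         background_positions = 200L,
                         gc_content = 0.448) {
  cfg <- list(seed = as.integer(seed), molecule_specs = molecule_specs,
              repeat_specs = repeat_specs, type2_linear = type2_linear,
              marker_length = as.integer(marker_length),
              marker_molecule = marker_molecule,
              marker_pos = as.integer(marker_pos),
              cp_insert_length = as.integer(cp_insert_length),
              cp_insert_molecule = cp_insert_molecule,
              cp_insert_pos = as.integer(cp_insert_pos),
              plastome_length = as.integer(plastome_length),
              cp_insert_plastome_pos = as.integer(cp_insert_plastome_pos),
              cp_variant_plan = cp_variant_plan, locus_plan = locus_plan,
              n_samples_per_type = as.integer(n_samples_per_type),
              heteroplasmy_fraction = heteroplasmy_fraction,
              n_het_samples = as.integer(n_het_samples),
              coverage = coverage, cp_coverage_ratio = cp_coverage_ratio,
              read_length = as.integer(read_length), error_rate = error_rate,
              taper_max = as.integer(taper_max),
              decoy_length = as.integer(decoy_length),
              decoy_divergence = decoy_divergence,
              background_positions = as.integer(background_positions),
              gc_content = gc_content)
  validate_forge_config(cfg)
  class(cfg) <- "forge_config"
  cfg
}

validate_forge_config <- function(cfg) {
  lens <- vapply(cfg$molecule_specs, function(m) m$length, numeric(1))
  if (any(lens <= 0)) stop("molecule lengths must be positive")
  if (!all(vapply(cfg$molecule_specs, function(m)
    m$topology %in% c("circular", "linear"), logical(1))))
    stop("topology must be 'circular' or 'linear'")
  if (cfg$heteroplasmy_fraction < 0 || cfg$heteroplasmy_fraction >= 0.5)
    stop("heteroplasmy_fraction must lie in [0, 0.5)")
  if (cfg$coverage <= 0) stop("coverage must be positive")
  if (is.null(cfg$gc_content) || cfg$gc_content <= 0 || cfg$gc_content >= 1)
    stop("gc_content must lie in (0, 1)")
  if (cfg$error_rate < 0 || cfg$error_rate > 0.2) stop("invalid error_rate")
  if (!is.null(cfg$locus_plan) && nrow(cfg$locus_plan) > 0) {
    if (!all(cfg$locus_plan$molecule %in% names(cfg$molecule_specs)))
      stop("locus plan names unknown molecules")
    if (!all(cfg$locus_plan$class %in% c("SNP", "INS", "DEL")))
      stop("locus classes must be SNP/INS/DEL")
  }
  for (rs in cfg$repeat_specs) {
    if (!all(rs$molecule %in% names(cfg$molecule_specs)))
      stop("repeat spec names unknown molecule")
    ends <- rs$start + rs$length - 1L
    lim <- lens[rs$molecule]
    if (any(ends > lim)) stop("repeat placement beyond molecule end")
    if (rs$molecule[1] == rs$molecule[2] &&
        rs$start[1] <= ends[2] && rs$start[2] <= ends[1])
      stop("repeat copies overlap each other")
  }
  invisible(cfg)
}

# intervals (per molecule) that differential loci must avoid
forge_exclusions <- function(cfg) {
  ex <- list()
  add <- function(mol, s, e) {
    ex[[length(ex) + 1]] <<- data.frame(molecule = mol, start = s, end = e)
  }
  for (rs in cfg$repeat_specs) {
    for (i in 1:2) add(rs$molecule[i], rs$start[i] - 10L,
                       rs$start[i] + rs$length - 1L + 10L)
  }
  add(cfg$cp_insert_molecule, cfg$cp_insert_pos - 50L,
      cfg$cp_insert_pos + cfg$cp_insert_length + 49L)
  add(cfg$marker_molecule, cfg$marker_pos - 800L, cfg$marker_pos + 300L)
  # decoy copies the start of the first molecule (see forge_population)
  add(names(cfg$molecule_specs)[1], 100001L - 100L,
      100000L + cfg$decoy_length + 100L)
  do.call(rbind, ex)
}

apply_edits <- function(seq, edits) {
  # edits: data.frame(pos, class, allele); applied at descending positions so
  # earlier coordinates stay valid. INS inserts after pos; DEL removes the
  # deleted bases starting at pos; SNP substitutes at pos.
  if (nrow(edits) == 0) return(seq)
  edits <- edits[order(-edits$pos), , drop = FALSE]
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]; a <- edits$allele[i]
    if (edits$class[i] == "SNP") {
      seq <- str_splice(seq, p, p, a)
    } else if (edits$class[i] == "INS") {
      seq <- str_splice(seq, p + 1L, p, sub("^\\+", "", a))
    } else {
      del <- sub("^-", "", a)
      seq <- str_splice(seq, p, p + nchar(del) - 1L, "")
    }
  }
  seq
}

#' Forge a synthetic two-type population with ground truth
#'
#' Deterministic for a fixed `config$seed`. See [forge_config()] for what is
#' generated. The returned truth object carries everything downstream stages
#' need: both genomes, plastomes, the decoy, the differential-locus table with
#' per-sample carrier sets, the repeat registry, the insertion's variant truth
#' (branch per variant), marker and primer coordinates, and the sample table.
#'
#' @param config A [forge_config()].
#' @return A `forge_truth` list.
#' @export
forge_population <- function(config = forge_config()) {
  validate_forge_config(config)
  with_seed(config$seed, forge_population_impl(config))
}

forge_population_impl <- function(cfg) {
  specs <- cfg$molecule_specs
  mols <- vapply(specs, function(m) random_seq(m$length, cfg$gc_content), character(1))
  topo <- vapply(specs, function(m) m$topology, character(1))

  # plant repeat pairs (copy 1 -> copy 2, reverse-complemented if inverted)
  rep_rows <- list()
  for (rs in cfg$repeat_specs) {
    src <- str_at(mols[[rs$molecule[1]]], rs$start[1],
                  rs$start[1] + rs$length - 1L)
    dst <- if (rs$orientation == "inverted") revcomp(src) else src
    mols[[rs$molecule[2]]] <- str_splice(mols[[rs$molecule[2]]], rs$start[2],
                                         rs$start[2] + rs$length - 1L, dst)
    rep_rows[[length(rep_rows) + 1]] <- tibble::tibble(
      molecule1 = rs$molecule[1], start1 = rs$start[1],
      end1 = rs$start[1] + rs$length - 1L,
      molecule2 = rs$molecule[2], start2 = rs$start[2],
      end2 = rs$start[2] + rs$length - 1L,
      orientation = rs$orientation, length = rs$length)
  }
  repeat_registry <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    tibble::tibble(molecule1 = character(0))

  # plastid-derived insertion: ancestral sequence + branch variants
  anc_insert <- random_seq(cfg$cp_insert_length, cfg$gc_content)
  cpv <- cp_variants_realize(cfg, anc_insert)
  cpv_edits <- function(sel) {
    d <- as.data.frame(cpv[sel, c("offset", "class", "allele")])
    names(d)[1] <- "pos"
    d
  }
  ins <- list(
    chloro_t1 = apply_edits(anc_insert, cpv_edits(cpv$branch == "chloro_t1")),
    chloro_t2 = apply_edits(anc_insert, cpv_edits(cpv$branch == "chloro_t2")),
    mito_t1 = apply_edits(anc_insert,
                          cpv_edits(cpv$branch %in% c("mito_anc", "mito_t1"))),
    mito_t2 = apply_edits(anc_insert,
                          cpv_edits(cpv$branch %in% c("mito_anc", "mito_t2"))))

  # embed the mito copy of the insert in the reference molecule
  imol <- cfg$cp_insert_molecule
  mols[[imol]] <- str_splice(mols[[imol]], cfg$cp_insert_pos,
                             cfg$cp_insert_pos + cfg$cp_insert_length - 1L,
                             ins$mito_t1)

  # plastomes
  plast_bb <- random_seq(cfg$plastome_length, cfg$gc_content)
  pp <- cfg$cp_insert_plastome_pos
  plastome_t1 <- str_splice(plast_bb, pp, pp + cfg$cp_insert_length - 1L,
                            ins$chloro_t1)
  plastome_t2 <- str_splice(plast_bb, pp, pp + cfg$cp_insert_length - 1L,
                            ins$chloro_t2)

  # marker fragment with planted primer sites
  marker <- forge_marker(cfg, mols)
  mols[[cfg$marker_molecule]] <- marker$flanked_reference

  # nuclear decoy: diverged copy of mitogenome segment [100001, 100000+len]
  d_src_mol <- names(specs)[1]
  d_start <- 100001L
  d_seq <- str_at(mols[[d_src_mol]], d_start, d_start + cfg$decoy_length - 1L)
  n_sub <- max(1L, round(cfg$decoy_length * cfg$decoy_divergence))
  sub_pos <- sort(sample.int(cfg$decoy_length, n_sub))
  d_chars <- strsplit(d_seq, "")[[1]]
  for (p in sub_pos) d_chars[p] <- sample(setdiff(DNA_BASES, d_chars[p]), 1)
  decoys <- c(NUC1 = paste(d_chars, collapse = ""))
  decoy_truth <- tibble::tibble(decoy = "NUC1", molecule = d_src_mol,
                                start = d_start,
                                end = d_start + cfg$decoy_length - 1L)

  # samples
  n1 <- cfg$n_samples_per_type[1]; n2 <- cfg$n_samples_per_type[2]
  samples <- tibble::tibble(
    sample = c(sprintf("T1_%02d", seq_len(n1)), sprintf("T2_%02d", seq_len(n2))),
    type = rep(c(1L, 2L), c(n1, n2)),
    het_fraction = 0)
  if (cfg$n_het_samples > 0 && n1 > 0) {
    samples$het_fraction[seq_len(min(cfg$n_het_samples, n1))] <-
      cfg$heteroplasmy_fraction
  }

  # differential loci
  loci <- forge_loci(cfg, mols, samples)

  # background (invariant) positions for specificity controls
  bg <- forge_background(cfg, mols, loci)

  # type 2 genome: apply type-2 consensus alleles, swap the insert's mito
  # version, insert the marker fragment
  mols2 <- mols
  cons2 <- loci[loci$segregation %in% c("t2_fixed", "shared", "dual"), ]
  for (m in unique(cons2$molecule)) {
    ed <- cons2[cons2$molecule == m,
                c("pos", "class", "type2_allele")]
    names(ed)[3] <- "allele"
    mols2[[m]] <- apply_edits(mols2[[m]], as.data.frame(ed))
  }
  # marker insertion: consensus edits upstream of marker_pos shift its actual
  # coordinate in the edited molecule
  mm <- cfg$marker_molecule
  mp2 <- cfg$marker_pos + edit_shift(cons2[cons2$molecule == mm, ],
                                     cfg$marker_pos)
  mols2[[mm]] <- str_splice(mols2[[mm]], mp2 + 1L, mp2, marker$seq)
  # swap insert version to the type-2 mito copy
  iv_len <- nchar(ins$mito_t1)
  ins_start2 <- cfg$cp_insert_pos  # below marker and below most edits? locate:
  # recompute the insert's current position in the edited molecule by offset
  # bookkeeping: edits below cp_insert_pos shift it.
  shift <- edit_shift(cons2[cons2$molecule == imol, ], cfg$cp_insert_pos)
  extra <- if (imol == mm && cfg$marker_pos < cfg$cp_insert_pos)
    cfg$marker_length else 0L
  ins_start2 <- cfg$cp_insert_pos + shift + extra
  mols2[[imol]] <- str_splice(mols2[[imol]], ins_start2,
                              ins_start2 + iv_len - 1L, ins$mito_t2)
  topo2 <- topo

  # type-2-only linear chromosome from copies of the first two molecules
  if (!is.null(cfg$type2_linear)) {
    tl <- cfg$type2_linear
    half <- tl$length %/% 2L
    src1 <- names(specs)[1]; src2 <- names(specs)[2]
    seg1 <- str_at(mols2[[src1]], 1L, half)
    seg2 <- str_at(mols2[[src2]], 1L, tl$length - half)
    mols2[[tl$name]] <- paste0(seg1, seg2)
    topo2[tl$name] <- "linear"
  }

  truth <- list(
    config = cfg,
    genomes = list(
      type1 = list(molecules = mols, topology = topo),
      type2 = list(molecules = mols2, topology = topo2)),
    plastomes = list(type1 = plastome_t1, type2 = plastome_t2),
    decoys = decoys,
    decoy_truth = decoy_truth,
    loci = loci,
    background = bg,
    repeat_registry = repeat_registry,
    cp_insert = list(
      molecule = imol,
      start = cfg$cp_insert_pos,
      end = cfg$cp_insert_pos + cfg$cp_insert_length - 1L,
      plastome_start = pp,
      plastome_end = pp + cfg$cp_insert_length - 1L,
      ancestral = anc_insert,
      versions = ins,
      variants = cpv),
    marker = marker$truth,
    samples = samples)
  class(truth) <- "forge_truth"
  truth
}

# net length shift contributed by edits at positions < at
edit_shift <- function(edits, at) {
  if (nrow(edits) == 0) return(0L)
  e <- edits[edits$pos < at, , drop = FALSE]
  if (nrow(e) == 0) return(0L)
  delta <- ifelse(e$class == "INS", nchar(sub("^\\+", "", e$type2_allele)),
           ifelse(e$class == "DEL", -nchar(sub("^-", "", e$type2_allele)), 0L))
  as.integer(sum(delta))
}

# realize the cp-variant plan as concrete edits in insert coordinates
cp_variants_realize <- function(cfg, anc_insert) {
  plan <- cfg$cp_variant_plan
  n <- sum(plan$count)
  len <- nchar(anc_insert)
  pos <- sample_spaced_positions(n, 50L, len - 50L, spacing = 12L)
  branch <- rep(plan$branch, plan$count)
  class <- rep(plan$class, plan$count)
  o <- sample.int(n)  # shuffle positions over (branch, class) slots
  pos <- pos[o]
  allele <- character(n)
  for (i in seq_len(n)) {
    b <- str_at(anc_insert, pos[i], pos[i])
    allele[i] <- switch(class[i],
      SNP = sample(setdiff(DNA_BASES, b), 1),
      INS = paste0("+", random_seq(sample(2:6, 1))),
      DEL = paste0("-", str_at(anc_insert, pos[i],
                               pos[i] + sample(1:3, 1) - 1L)))
  }
  out <- tibble::tibble(offset = pos, class = class, branch = branch,
                        ref = substring(anc_insert, pos, pos), allele = allele)
  out[order(out$offset), ]
}

# positions with pairwise spacing >= spacing, uniform-ish over [lo, hi]
sample_spaced_positions <- function(n, lo, hi, spacing = 12L) {
  got <- integer(0)
  for (tries in 1:200) {
    cand <- sort(unique(c(got, sample(seq.int(lo, hi), n * 2, replace = FALSE))))
    keep <- c(TRUE, diff(cand) >= spacing)
    # greedy left-to-right thinning
    sel <- integer(0); last <- -Inf
    for (p in cand) if (p - last >= spacing) { sel <- c(sel, p); last <- p }
    got <- sel
    if (length(got) >= n) return(sort(sample(got, n)))
  }
  stop("could not place ", n, " spaced positions in [", lo, ", ", hi, "]")
}

forge_marker <- function(cfg, mols) {
  # primers published for typing the marker fragment's two junctions
  lf <- "GAGACCGAGCGCAAGAACTA"; lr <- "TCAGATGGCTAAACAGGCGG"  # 990 bp product
  rf <- "CGCTCGTGACTCATTGAGGA"; rr <- "TTGGTAAGCGGATGCTCTGG"  # 289 bp product
  q <- random_seq(cfg$marker_length, cfg$gc_content)
  mp <- cfg$marker_pos
  ref <- mols[[cfg$marker_molecule]]
  # left product: fwd in the left flank, reverse site inside the fragment
  ref <- str_splice(ref, mp - 700L, mp - 681L, lf)
  q <- str_splice(q, 270L, 289L, revcomp(lr))
  # right product: fwd inside the fragment, reverse site in the right flank
  q <- str_splice(q, 1959L, 1978L, rf)
  ref <- str_splice(ref, mp + 120L, mp + 139L, revcomp(rr))
  list(flanked_reference = ref, seq = q,
       truth = list(molecule = cfg$marker_molecule, after = mp,
                    length = cfg$marker_length, seq = q,
                    primers = list(left = c(fwd = lf, rev = lr),
                                   right = c(fwd = rf, rev = rr)),
                    product_sizes = c(left = 990L, right = 289L)))
}

forge_loci <- function(cfg, mols, samples) {
  plan <- cfg$locus_plan
  if (is.null(plan) || nrow(plan) == 0) {
    return(tibble::tibble(locus = character(0), molecule = character(0),
                          pos = integer(0), class = character(0),
                          ref_allele = character(0), type1_allele = character(0),
                          type2_allele = character(0), alt1_allele = character(0),
                          segregation = character(0), carriers = list()))
  }
  excl <- forge_exclusions(cfg)
  t1_ids <- samples$sample[samples$type == 1L]
  t2_ids <- samples$sample[samples$type == 2L]
  rows <- list()
  for (m in unique(plan$molecule)) {
    pm <- plan[plan$molecule == m, ]
    n_m <- sum(pm$count)
    em <- excl[excl$molecule == m, ]
    ok <- rep(TRUE, nchar(mols[[m]]))
    ok[seq_len(min(100L, length(ok)))] <- FALSE
    ok[seq.int(max(1L, length(ok) - 100L), length(ok))] <- FALSE
    for (i in seq_len(nrow(em))) {
      s <- max(1L, em$start[i]); e <- min(length(ok), em$end[i])
      if (s <= e) ok[s:e] <- FALSE
    }
    cand <- which(ok)
    pos <- sort(sample(cand, n_m * 3))
    keep <- c(TRUE, diff(pos) >= 12L)
    sel <- integer(0); last <- -1e9
    for (p in pos) if (p - last >= 12L) { sel <- c(sel, p); last <- p }
    if (length(sel) < n_m) stop("not enough space for loci on ", m)
    pos <- sort(sample(sel, n_m))
    cls <- rep(pm$class, pm$count)
    seg <- rep(pm$segregation, pm$count)
    o <- sample.int(n_m)
    cls <- cls[o]; seg <- seg[o]
    for (i in seq_len(n_m)) {
      p <- pos[i]
      refb <- str_at(mols[[m]], p, p)
      del_len <- if (seg[i] == "dual") sample(2:5, 1) else sample(1:5, 1)
      alt2 <- switch(cls[i],
        SNP = sample(setdiff(DNA_BASES, refb), 1),
        INS = paste0("+", random_seq(sample(2:6, 1))),
        DEL = paste0("-", str_at(mols[[m]], p, p + del_len - 1L)))
      alt1 <- NA_character_
      carriers <- list(character(0))
      pick <- function(ids, kmax) {
        k <- min(length(ids), sample.int(kmax, 1))
        if (k == 0) character(0) else sample(ids, k)
      }
      if (seg[i] == "t1_subset") {
        carriers <- list(pick(t1_ids, 5L))
      } else if (seg[i] == "t2_subset") {
        carriers <- list(pick(t2_ids, 5L))
      } else if (seg[i] == "shared") {
        carriers <- list(pick(t1_ids, 1L))
      } else if (seg[i] == "dual") {
        # type 1 subset carries its own distinct alternate allele
        alt1 <- switch(cls[i],
          SNP = sample(setdiff(DNA_BASES, c(refb, alt2)), 1),
          INS = paste0("+", random_seq(sample(2:6, 1))),
          DEL = paste0("-", str_at(mols[[m]], p, p)))
        carriers <- list(pick(t1_ids, 3L))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        locus = sprintf("%s:%d", m, p), molecule = m, pos = p,
        class = cls[i], ref_allele = refb, type1_allele = refb,
        type2_allele = alt2, alt1_allele = alt1, segregation = seg[i],
        carriers = carriers)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$molecule, out$pos), ]
}

forge_background <- function(cfg, mols, loci) {
  n <- cfg$background_positions
  if (n <= 0) {
    return(tibble::tibble(molecule = character(0), pos = integer(0),
                          ref_allele = character(0)))
  }
  m1 <- names(mols)[1]
  taken <- loci$pos[loci$molecule == m1]
  cand <- setdiff(seq.int(200L, nchar(mols[[m1]]) - 200L), taken)
  pos <- sort(sample(cand, n))
  tibble::tibble(molecule = m1, pos = pos,
                 ref_allele = substring(mols[[m1]], pos, pos))
}
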