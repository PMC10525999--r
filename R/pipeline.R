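# End-to-end orchestration: forge -> counts -> calls -> typing -> insertion
# origins -> marker tree -> SSRs, with a versioned machine-readable report.

REPORT_SCHEMA_VERSION <- "1.0"

#' Run the full synthetic-population pipeline
#'
#' Forges a population, simulates per-sample allele counts, calls variants
#' and heteroplasmy under the configured filters, builds the variant matrix,
#' types every sample (variant vote plus marker-coverage flag), aggregates
#' population variant counts, recovers the insertion's quad patterns from
#' frequency-split allele evidence and assigns origins, builds the
#' neighbor-joining tree on concatenated marker windows, and scans the
#' reference genome for microsatellites. Artifacts are written as TSV/newick
#' under `out_dir` together with a JSON report echoing every threshold
#' applied. Deterministic for a fixed config seed.
#'
#' @param config A [forge_config()].
#' @param out_dir Output directory (created if needed); NULL skips writing.
#' @param het_params A [het_filter_params()]; the homology mask is built from
#'   the forged decoys/plastome and added automatically.
#' @param ssr_params An [ssr_thresholds()].
#' @param min_depth Minimum depth for variant calls.
#' @return Invisibly, a list with all stage results and `report`.
#' @export
run_pipeline <- function(config = forge_config(), out_dir = NULL,
                         het_params = het_filter_params(),
                         ssr_params = ssr_thresholds(), min_depth = 10L) {
  truth <- forge_population(config)
  samples <- truth$samples$sample
  types <- stats::setNames(truth$samples$type, samples)

  mask <- build_homology_mask(
    truth$genomes$type1$molecules, truth$plastomes$type1, truth$decoys,
    exclude = tibble::tibble(molecule = truth$cp_insert$molecule,
                             start = truth$cp_insert$start,
                             end = truth$cp_insert$end))
  het_params$mask <- mask

  ref_alleles <- tibble::tibble(molecule = truth$loci$molecule,
                                pos = truth$loci$pos,
                                ref = truth$loci$ref_allele)
  calls <- list(); het <- list(); marker_depth <- numeric(0)
  for (s in samples) {
    pu <- simulate_allele_counts(truth, s)
    calls[[s]] <- call_variants(pu, ref_alleles, min_depth = min_depth)
    het[[s]] <- call_heteroplasmy(pu, het_params)
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
  counts_table <- aggregate_counts(vm, types)

  # insertion origin assignment from frequency-split allele evidence
  insert_calls <- lapply(stats::setNames(samples, samples), function(s)
    split_insert_alleles(simulate_insert_counts(truth, s)))
  cls <- stats::setNames(truth$cp_insert$variants$class,
                         as.character(truth$cp_insert$variants$offset))
  quads <- quad_patterns_from_calls(insert_calls, types, classes = cls)
  origins <- do.call(rbind, lapply(quads, assign_origin))
  origin_summary <- summarize_origins(origins)

  # marker-window phylogeny
  markers <- build_marker_chromosomes(vm, truth$genomes$type1$molecules)
  dm <- jc_distance_matrix(markers$sequences)
  tree <- nj_tree(dm)

  # SSR scan of the reference molecules
  ssrs <- do.call(rbind, lapply(names(truth$genomes$type1$molecules),
    function(m) find_ssrs(truth$genomes$type1$molecules[[m]],
                          thresholds = ssr_params, molecule = m)))
  ssr_summary <- summarize_ssrs(ssrs)

  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    seed = config$seed,
    n_samples = length(samples),
    n_differential_loci = nrow(truth$loci),
    thresholds = list(
      min_minor_freq = het_params$min_minor_freq,
      min_phred = het_params$min_phred,
      require_both_strands = het_params$require_both_strands,
      min_depth = min_depth,
      ssr_min_repeats = as.integer(ssr_params),
      coverage = config$coverage,
      error_rate = config$error_rate),
    typing = list(
      n_type1 = sum(typing$type == 1L, na.rm = TRUE),
      n_type2 = sum(typing$type == 2L, na.rm = TRUE),
      n_unassigned = sum(is.na(typing$type)),
      n_discordant = sum(typing$discordant, na.rm = TRUE)),
    variants = list(
      total = counts_table$total[counts_table$chromosome == "Total"],
      type2_exclusive =
        counts_table$type2_exclusive[counts_table$chromosome == "Total"]),
    heteroplasmy = list(
      samples_with_records = sum(vapply(het, nrow, integer(1)) > 0),
      max_median_minor_freq = max(c(0, typing$het_median_minor_freq),
                                  na.rm = TRUE)),
    insertion_origins = stats::setNames(as.list(origin_summary$n),
                                        origin_summary$organelle),
    ssr = list(total = nrow(ssrs),
               mono = sum(ssrs$motif_length == 1L)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.table(
      as.data.frame(x), file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wr(render_variant_matrix(vm), "variant_matrix.tsv")
    wr(do.call(rbind, lapply(names(het), function(s)
      if (nrow(het[[s]])) cbind(sample = s, het[[s]]) else NULL)),
      "heteroplasmy.tsv")
    wr(typing, "typing.tsv")
    wr(counts_table, "variant_counts.tsv")
    wr(origins, "insertion_origins.tsv")
    wr(ssrs, "ssrs.tsv")
    ape::write.tree(tree, file.path(out_dir, "marker_nj.nwk"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(truth = truth, calls = calls, het = het, vm = vm,
                 typing = typing, counts_table = counts_table,
                 origins = origins, origin_summary = origin_summary,
                 tree = tree, ssrs = ssrs, ssr_summary = ssr_summary,
                 mask = mask, report = report))
}
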