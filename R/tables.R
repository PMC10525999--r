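# Observed survey tables bundled with the package (desk-scale inputs for the
# worked analyses), plus small helpers over them.
#
# The tables describe a two-cytotype marama (Tylosema esculentum) mitogenome
# population survey of 84 individuals mapped against the type 1 reference
# chromosomes (LS1, LS2): the allele-state patterns at the 20
# type-differential loci inside the shared 9,798 bp plastid-derived
# insertion, the per-chromosome variant-count cells, the base composition of
# the four type 2 chromosomes, and the variants falling in gene sequences.

extdata <- function(file) {
  system.file("extdata", file, package = "mitopartite", mustWork = TRUE)
}

#' Observed quad patterns over the shared plastid insertion
#'
#' The four allele states (type1-chloro, type1-mito, type2-chloro, type2-mito,
#' each Ref/Alt relative to the type 1 chloroplast sequence) at the 20 loci
#' of the shared insertion that differ between germplasm types, with the
#' reported lineage assignment for comparison. The state "AltSome" marks a
#' within-type polymorphism (treated as Alt, flagged polymorphic).
#'
#' @return Tibble with `position`, `class`, the four state columns,
#'   `in_gene`, `reported_origin`.
#' @export
load_insert_quad_patterns <- function() {
  tibble::as_tibble(utils::read.delim(extdata("mtpt_insert_quad_patterns.tsv"),
                                      stringsAsFactors = FALSE))
}

#' Convert the observed pattern table into quad-pattern objects
#'
#' @param tab Tibble from [load_insert_quad_patterns()].
#' @return List of [quad_pattern()] objects.
#' @export
as_quad_patterns <- function(tab = load_insert_quad_patterns()) {
  lapply(seq_len(nrow(tab)), function(i) {
    st <- unlist(tab[i, c("chloro_t1", "mito_t1", "chloro_t2", "mito_t2")])
    poly <- any(st == "AltSome")
    st[st == "AltSome"] <- "Alt"
    quad_pattern(st[[1]], st[[2]], st[[3]], st[[4]],
                 locus = tab$position[i], class = tab$class[i],
                 polymorphic = poly)
  })
}

#' Observed per-chromosome population variant counts
#'
#' Counts of variant loci per reference chromosome and class when the 84
#' individuals' reads were mapped to the type 1 reference, split into
#' type-2-vs-reference and type-1-vs-reference columns with exclusive-allele
#' counts.
#'
#' @return Tibble mirroring [aggregate_counts()] columns (without the grand
#'   total row).
#' @export
load_population_variant_counts <- function() {
  tibble::as_tibble(utils::read.delim(extdata("population_variant_counts.tsv"),
                                      stringsAsFactors = FALSE))
}

#' Observed chromosome base composition of the type 2 mitogenome
#'
#' @return Tibble with `molecule`, per-base percentages, `gc_pct`, `length`.
#' @export
load_chromosome_composition <- function() {
  tibble::as_tibble(utils::read.delim(extdata("chromosome_composition.tsv"),
                                      stringsAsFactors = FALSE))
}

#' Observed variants inside mitochondrial gene sequences
#'
#' @return Tibble with `chromosome`, `position`, `variant_type`, `gene`,
#'   `region`, `product`.
#' @export
load_gene_sequence_variants <- function() {
  tibble::as_tibble(utils::read.delim(extdata("gene_sequence_variants.tsv"),
                                      stringsAsFactors = FALSE))
}

#' Genome length and length-weighted GC content from a composition table
#'
#' @param comp Tibble from [load_chromosome_composition()] (or any table with
#'   `gc_pct` and `length`).
#' @return List with `total_length` (bp) and `weighted_gc_pct`.
#' @export
genome_composition_summary <- function(comp = load_chromosome_composition()) {
  list(total_length = sum(comp$length),
       weighted_gc_pct = sum(comp$gc_pct * comp$length) / sum(comp$length))
}
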