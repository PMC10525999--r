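#!/usr/bin/env Rscript
# Forge the synthetic two-cytotype population at study scale and write its
# ground truth: genomes, plastomes, decoy, differential-locus table,
# repeat registry, insertion-variant truth, and sample table.
#
# Downstream scripts (02-06) re-derive everything from the same seed.

suppressPackageStartupMessages(library(mitopartite))

seed <- 101L
out <- "results"
dir.create(out, showWarnings = FALSE)

config <- forge_config(seed = seed)
truth <- forge_population(config)

cat("Forged population (seed", seed, "):\n")
cat("  type 1 genome:",
    paste(sprintf("%s=%d bp", names(truth$genomes$type1$molecules),
                  nchar(truth$genomes$type1$molecules)), collapse = ", "),
    "\n")
cat("  type 2 genome:",
    paste(sprintf("%s=%d bp", names(truth$genomes$type2$molecules),
                  nchar(truth$genomes$type2$molecules)), collapse = ", "),
    "\n")
cat("  differential loci:", nrow(truth$loci), "(",
    sum(truth$loci$class == "SNP"), "SNP,",
    sum(truth$loci$class == "INS"), "INS,",
    sum(truth$loci$class == "DEL"), "DEL )\n")
cat("  samples:", sum(truth$samples$type == 1), "type 1 /",
    sum(truth$samples$type == 2), "type 2;",
    sum(truth$samples$het_fraction > 0), "heteroplasmic at",
    config$heteroplasmy_fraction, "\n")
cat("  insertion variants:", nrow(truth$cp_insert$variants),
    "on branches:", paste(names(table(truth$cp_insert$variants$branch)),
                          table(truth$cp_insert$variants$branch),
                          collapse = ", "), "\n")

write_fasta(truth$genomes$type1$molecules,
            file.path(out, "genome_type1.fasta"))
write_fasta(truth$genomes$type2$molecules,
            file.path(out, "genome_type2.fasta"))
write_fasta(c(plastome_type1 = truth$plastomes$type1,
              plastome_type2 = truth$plastomes$type2),
            file.path(out, "plastomes.fasta"))
write_fasta(truth$decoys, file.path(out, "nuclear_decoy.fasta"))

wr <- function(x, f) utils::write.table(
  as.data.frame(x), file.path(out, f), sep = "\t", quote = FALSE,
  row.names = FALSE)
loci_flat <- truth$loci
loci_flat$carriers <- vapply(loci_flat$carriers, paste, collapse = ",",
                             FUN.VALUE = character(1))
wr(loci_flat, "truth_differential_loci.tsv")
wr(truth$repeat_registry, "truth_repeats.tsv")
wr(truth$cp_insert$variants, "truth_insert_variants.tsv")
wr(truth$samples, "truth_samples.tsv")

cat("wrote ground truth under", out, "\n")
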