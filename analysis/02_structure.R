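#!/usr/bin/env Rscript
# Structural analysis of the forged genomes: long-repeat detection,
# enumeration of recombination conformations, junction support in simulated
# reads, copy-number segmentation, and linear-end taper detection.

suppressPackageStartupMessages(library(mitopartite))

seed <- 101L
out <- "results"
dir.create(out, showWarnings = FALSE)
config <- forge_config(seed = seed)
truth <- forge_population(config)
wr <- function(x, f) utils::write.table(
  as.data.frame(x), file.path(out, f), sep = "\t", quote = FALSE,
  row.names = FALSE)

# -- long repeats in the type 1 reference (the planted pairs should surface)
reps <- find_long_repeats(truth$genomes$type1$molecules, min_len = 1000)
cat("long repeats (>= 1 kb) in the type 1 genome:", nrow(reps), "\n")
print(as.data.frame(reps))
wr(reps, "repeats_type1.tsv")

# -- single-event conformations from the planted repeat registry
g1 <- mito_genome(truth$genomes$type1$molecules,
                  truth$genomes$type1$topology, type = "type1")
confs <- enumerate_conformations(g1, truth$repeat_registry)
ev <- do.call(rbind, lapply(confs, function(cf) data.frame(
  event = cf$event,
  repeat_molecule = cf$repeat_pair$molecule1,
  repeat_length = cf$repeat_pair$length,
  products = paste(names(cf$molecules), collapse = "+"),
  product_bp = paste(nchar(cf$molecules), collapse = "+"),
  parent_bp = sum(nchar(g1$molecules[unique(c(cf$repeat_pair$molecule1,
                                              cf$repeat_pair$molecule2))])))))
cat("\nconformations reachable by one recombination event:\n")
print(ev)
wr(ev, "conformations.tsv")

# -- junction support: parent vs split products of the 35 bp direct repeat,
#    mixed 1:1, read evidence from the forge
short <- truth$repeat_registry[truth$repeat_registry$length < 100, ][1, ]
conf <- enumerate_conformations(g1, short)[[1]]
juncs <- rbind(conf$junctions, parent_junctions(g1, short))
mix <- c(g1$molecules[short$molecule1], conf$molecules)
topo <- c(g1$topology[short$molecule1], conf$topology)
reads <- simulate_reads(truth, truth$samples$sample[1], molecules = mix,
                        topology = topo)
js <- junction_support(reads, juncs, genome_seqs = mix)
cat("\njunction support over", nrow(reads), "reads",
    "(parent and split conformation mixed 1:1):\n")
print(as.data.frame(js[, c("junction", "support", "unique", "frequency")]))
wr(js[, c("junction", "group", "support", "unique", "frequency")],
   "junction_support.tsv")

# -- copy-number segmentation and end taper on an M3-like linear chromosome:
#    two multicopy regions (2x, 3x) and 18 kb maximum end degradation
prof <- simulate_depth_profile(
  97120, config$coverage,
  copy_segments = tibble::tibble(start = c(20001L, 60001L),
                                 end = c(30000L, 64052L), copy = c(2L, 3L)),
  topology = "linear", taper_max = config$taper_max,
  molecule = "M3", seed = seed)
seg <- copy_number_segments(prof, baseline = config$coverage)
cat("\ncopy-number segments on the linear chromosome profile:\n")
print(as.data.frame(seg))
wr(seg, "copy_number_segments.tsv")

taper <- detect_linear_taper(prof)
cat("\nend taper (truth: up to", config$taper_max, "bp):\n")
print(as.data.frame(taper))
wr(taper, "linear_taper.tsv")
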