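#!/usr/bin/env Rscript
# Microsatellite scan of the forged type 1 reference genome with the survey
# thresholds (>= 10/6/5/5/5/5 repeats for motif lengths 1-6), plus the
# canonical-group summary.

suppressPackageStartupMessages(library(mitopartite))

seed <- 101L
out <- "results"
dir.create(out, showWarnings = FALSE)
truth <- forge_population(forge_config(seed = seed))

mols <- truth$genomes$type1$molecules
ssrs <- do.call(rbind, lapply(names(mols), function(m)
  find_ssrs(mols[[m]], molecule = m)))
utils::write.table(as.data.frame(ssrs), file.path(out, "ssrs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

sm <- summarize_ssrs(ssrs)
cat("SSRs in the forged reference genome (", sum(nchar(mols)), "bp ):",
    nrow(ssrs), "\n")
cat("by motif length:\n"); print(as.data.frame(sm$by_motif_length))
cat("by canonical group:\n"); print(as.data.frame(sm$by_group))
utils::write.table(as.data.frame(sm$by_group),
                   file.path(out, "ssr_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\n(a genome of independent random bases carries essentially no",
    "microsatellites -- real organellar SSRs arise from replication",
    "slippage, which the forge does not model)\n")

# -- synthetic demonstration chromosome: plant the survey's motif census
#    (37 A/T and 1 G/C mononucleotide, 8 dinucleotide, 2 trinucleotide
#    repeats = 48) and verify the scanner returns it exactly
set.seed(seed)
plant <- c(replicate(30, strrep("A", sample(10:14, 1))),
           replicate(7, strrep("T", sample(10:13, 1))),
           strrep("G", 11),
           replicate(5, strrep("AT", sample(6:8, 1))),
           replicate(3, strrep("GA", sample(6:7, 1))),
           strrep("CTG", 5), strrep("AAT", 6))
demo <- paste0("GC", paste(vapply(plant, function(m)
  paste0(m, "GC", random_seq(sample(120:200, 1)), "GC"), character(1)),
  collapse = ""))
demo_ssrs <- find_ssrs(demo, molecule = "demo")
demo_sm <- summarize_ssrs(demo_ssrs)
cat("\nplanted demonstration chromosome (", nchar(demo), "bp ):",
    nrow(demo_ssrs), "SSRs;",
    sum(demo_ssrs$motif_length == 1), "mononucleotide (",
    sum(demo_ssrs$group == "A/T"), "A/T,",
    sum(demo_ssrs$group == "G/C"), "G/C ),",
    sum(demo_ssrs$motif_length == 2), "dinucleotide,",
    sum(demo_ssrs$motif_length == 3), "trinucleotide\n")
stopifnot(nrow(demo_ssrs) == 48L,
          sum(demo_ssrs$motif_length == 1) == 38L)
utils::write.table(as.data.frame(demo_ssrs),
                   file.path(out, "ssr_demo_planted.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
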