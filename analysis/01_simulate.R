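#!/usr/bin/env Rscript
# Generate the synthetic study: a motif-planted transcriptome with four
# 3'UTR archetypes, crosslink tracks and peaks for signal and input
# samples across three CD8 T cell states, deamination pileups with and
# without METTL3 inhibition, metabolic-labelling decay time courses, and
# gene-module labels. Everything downstream reads these files.

suppressPackageStartupMessages(library(metadecay))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- default_config()
cfg$seed <- seed

sim <- generate_transcriptome(n_genes = cfg$simulate$n_genes, seed = seed)
write_fasta(sim$sequences, file.path(out, "transcriptome.fa"))
write_annotation(sim$annotation, file.path(out, "annotation.tsv"))
write.table(sim$manifest$genes, file.path(out, "manifest_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$manifest$sites, file.path(out, "manifest_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

xl <- simulate_crosslinks(sim, seed = seed + 1)
for (nm in names(xl$tracks)) {
  write_crosslink_bed(xl$tracks[[nm]], file.path(out, paste0(nm, ".bed")))
}
write_bed(xl$peaks, file.path(out, "peaks.bed"))

gl <- simulate_glori(sim, seed = seed + 2)
for (nm in names(gl)) {
  write_pileup(gl[[nm]], file.path(out, paste0("glori_", nm, ".tsv")))
}

sl <- simulate_slam(sim, seed = seed + 3)
write.table(sl$curves, file.path(out, "slam_curves.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sl$truth, file.path(out, "slam_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

modules <- assign_modules(sim, seed = seed + 4)
write.table(data.frame(gene = names(modules), module = modules),
            file.path(out, "modules.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

tab <- table(sim$manifest$genes$archetype)
message("generated ", cfg$simulate$n_genes, " genes (",
        paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
        length(xl$tracks), " crosslink tracks, ", length(gl),
        " pileup samples, ", length(unique(sl$curves$state)),
        " decay time-course states -> ", out)
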