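#!/usr/bin/env Rscript
# Conversion-based m6A calling: per-adenosine conversion ratios, the
# depth >= 15 / ratio >= 0.1 calling rule, motif and region annotation,
# and DMSO-versus-inhibitor metagenes around ARE centres.

suppressPackageStartupMessages(library(metadecay))

dat <- "results/data"; out <- "results"
annotation <- load_annotation(file.path(dat, "annotation.tsv"))
sequences <- load_fasta(file.path(dat, "transcriptome.fa"))

files <- list.files(dat, pattern = "^glori_.*\\.tsv$", full.names = TRUE)
called <- list()
for (p in files) {
  meta <- strsplit(sub("^glori_(.*)\\.tsv$", "\\1", basename(p)),
                   ".", fixed = TRUE)[[1]]
  pl <- load_pileup(p)
  sites <- call_glori_sites(conversion_ratio(pl, sequences))
  sites <- annotate_glori_sites(sites, annotation, sequences)
  if (nrow(sites) == 0) next
  sites$state <- meta[1]
  sites$condition <- meta[2]
  sites$replicate <- as.integer(sub("r", "", meta[3]))
  called[[p]] <- sites
}
called <- do.call(rbind, called)
rownames(called) <- NULL
write.table(called, file.path(out, "glori_called_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ares <- motif_sites_in_3utrs(annotation, sequences, "WWAWW")
centres <- data.frame(contig = ares$contig, centre = ares$centre,
                      strand = ares$strand)
prof <- glori_metagene(called, centres, flank = 10,
                       conditions = c("DMSO", "METTL3i"))
write.table(prof, file.path(out, "glori_are_metagene.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

dmso <- called[called$condition == "DMSO", ]
frac <- fraction_near_sites(dmso, centres, window = 4)
i_ratio <- sum(prof$value[prof$condition == "METTL3i"]) /
  sum(prof$value[prof$condition == "DMSO"])
message(sprintf(
  "called %d m6A site records (%d unique positions); %.1f%% of m6A counts lie within +/-4 nt of an ARE centre; inhibitor retains %.0f%% of the DMSO metagene signal",
  nrow(called), length(unique(called$position_id)), 100 * frac,
  100 * i_ratio))
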