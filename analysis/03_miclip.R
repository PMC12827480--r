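#!/usr/bin/env Rscript
# Crosslink-level analyses: threshold crosslinks inside peaks, score
# positional 5-mer enrichment around the thresholded sites against distal
# background, and profile the signal over motif centres and scaled
# metatranscript regions.

suppressPackageStartupMessages(library(metadecay))

dat <- "results/data"; out <- "results"
annotation <- load_annotation(file.path(dat, "annotation.tsv"))
sequences <- load_fasta(file.path(dat, "transcriptome.fa"))
peaks <- load_bed(file.path(dat, "peaks.bed"))

beds <- list.files(dat, pattern = "^(miCLIP|input)_.*\\.bed$",
                   full.names = TRUE)
tracks <- lapply(beds, function(p) {
  load_crosslink_bed(p, sample_id = sub("\\.bed$", "", basename(p)),
                     role = if (grepl("^input", basename(p))) "input"
                            else "miCLIP")
})
names(tracks) <- vapply(tracks, function(t) t$sample_id, character(1))

miclip <- tracks[vapply(tracks, function(t) t$role, character(1)) == "miCLIP"]
thr <- lapply(miclip, threshold_crosslinks, peaks = peaks)
pooled_thr <- do.call(rbind, lapply(thr, `[[`, "thresholded"))
pooled_bg <- do.call(rbind, lapply(thr, `[[`, "background"))
pk <- peka_scores(pooled_thr, pooled_bg, sequences, seed = 11)
write.table(pk$scores, file.path(out, "peka_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# metagene of miCLIP vs input signal around ARE motif centres
ares <- motif_sites_in_3utrs(annotation, sequences, "WWAWW")
centres <- data.frame(contig = ares$contig, centre = ares$centre,
                      strand = ares$strand, transcript = ares$transcript)
profiles <- list()
for (nm in names(tracks)) {
  p <- metagene_profile(tracks[[nm]], centres, flank = 20,
                        normalize_per_utr = TRUE, annotation = annotation)
  p$sample <- nm
  profiles[[nm]] <- p
}
write.table(do.call(rbind, profiles), file.path(out, "are_metagene.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

dens <- lapply(names(tracks), function(nm) {
  d <- scaled_region_density(tracks[[nm]], annotation, bins_per_region = 25)
  d$sample <- nm
  d
})
write.table(do.call(rbind, dens), file.path(out, "region_density.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

top <- pk$scores$kmer[1:10]
message("thresholded ", nrow(pooled_thr), " of ",
        nrow(pooled_thr) + nrow(pooled_bg),
        " crosslink positions across ", length(miclip), " signal samples; ",
        "top enriched 5-mers: ", paste(top, collapse = " "))
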