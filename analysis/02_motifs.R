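#!/usr/bin/env Rscript
# Map the three pentamer classes (RRACH, ARE/WWAWW, CRACH) across the
# 3'UTRs and call composite ARE-flanking m6A candidates by centre-to-centre
# proximity at the analysis windows.

suppressPackageStartupMessages(library(metadecay))

dat <- "results/data"; out <- "results"
annotation <- load_annotation(file.path(dat, "annotation.tsv"))
sequences <- load_fasta(file.path(dat, "transcriptome.fa"))

sites <- lapply(c(RRACH = "RRACH", WWAWW = "WWAWW", CRACH = "CRACH"),
                function(cl) motif_sites_in_3utrs(annotation, sequences, cl))
for (cl in names(sites)) {
  write_bed(data.frame(contig = sites[[cl]]$contig,
                       start = sites[[cl]]$centre,
                       end = sites[[cl]]$centre + 1L,
                       name = paste0(cl, ":", sites[[cl]]$pentamer),
                       score = 0, strand = sites[[cl]]$strand),
            file.path(out, paste0("motif_sites_", cl, ".bed")))
}

# per-transcript composite calls at the nested windows
utrs <- annotation_regions(annotation, "3UTR")
calls <- list()
for (w in c(3, 5, 15, 25, 50)) {
  for (i in seq_len(nrow(utrs))) {
    tx <- utrs$transcript[i]
    are <- sites$WWAWW[sites$WWAWW$transcript == tx, ]
    rr <- sites$RRACH[sites$RRACH$transcript == tx, ]
    if (nrow(are) == 0) next
    cc <- call_composites(data.frame(centre = are$tx_centre),
                          data.frame(centre = rr$tx_centre), window_nt = w)
    cc$transcript <- tx
    calls[[length(calls) + 1L]] <- cc
  }
}
calls <- do.call(rbind, calls)
write.table(calls, file.path(out, "composite_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

freqs <- do.call(rbind, lapply(seq_len(nrow(utrs)), function(i) {
  u <- utrs[i, ]
  s <- interval_sequence(sequences, u$contig, u$start, u$end, u$strand)
  data.frame(transcript = u$transcript,
             rrach_per_kb = motif_frequency(s, "RRACH")$per_kb,
             are_per_kb = motif_frequency(s, "WWAWW")$per_kb)
}))
write.table(freqs, file.path(out, "motif_frequencies.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

w50 <- calls[calls$window == 50, ]
message(sprintf(
  "scanned %d RRACH, %d ARE, %d CRACH 3'UTR sites; %.0f%% of AREs have a RRACH within 50 nt (median |distance| %.0f nt)",
  nrow(sites$RRACH), nrow(sites$WWAWW), nrow(sites$CRACH),
  100 * mean(w50$label == "composite"),
  median(abs(w50$distance), na.rm = TRUE)))
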