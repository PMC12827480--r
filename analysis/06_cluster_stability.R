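#!/usr/bin/env Rscript
# Motif-partitioned 3'UTR count matrices (thresholded crosslinks and called
# m6A counts), size-factor normalisation and clustering into the crosslink
# (c1-c4) and conversion (ci/cii) schemes, then half-life statistics:
# cluster-versus-no-signal KS tests, distance-binned KS against the
# no-signal reference, and the module x half-life-bin x cluster flow table.

suppressPackageStartupMessages(library(metadecay))

dat <- "results/data"; out <- "results"
annotation <- load_annotation(file.path(dat, "annotation.tsv"))
sequences <- load_fasta(file.path(dat, "transcriptome.fa"))
peaks <- load_bed(file.path(dat, "peaks.bed"))
sites <- list(RRACH = motif_sites_in_3utrs(annotation, sequences, "RRACH"),
              WWAWW = motif_sites_in_3utrs(annotation, sequences, "WWAWW"))

beds <- list.files(dat, pattern = "^(miCLIP|input)_.*\\.bed$",
                   full.names = TRUE)
tracks <- lapply(beds, function(p) {
  load_crosslink_bed(p, sample_id = sub("\\.bed$", "", basename(p)),
                     role = if (grepl("^input", basename(p))) "input"
                            else "miCLIP")
})
names(tracks) <- vapply(tracks, function(t) t$sample_id, character(1))
is_sig <- vapply(tracks, function(t) t$role, character(1)) == "miCLIP"
thr_tracks <- lapply(tracks[is_sig], function(t) {
  crosslink_track(threshold_crosslinks(t, peaks)$thresholded,
                  sample_id = t$sample_id, role = "miCLIP")
})

mat <- build_count_matrix(c(thr_tracks, tracks[!is_sig]), sites, annotation,
                          scheme = "miclip")
mat <- exclude_low_signal(mat)
sel <- suppressWarnings(normalize_and_select(mat, size_factors(mat)))
cl_mi <- hierarchical_cluster(sel$z, k = 4)
write.table(cl_mi, file.path(out, "clusters_miclip.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
nomiclip <- names(which(mat$low_signal))

glori <- read.table(file.path(out, "glori_called_sites.tsv"), header = TRUE,
                    sep = "\t")
dmso <- glori[glori$condition == "DMSO", ]
gtracks <- lapply(split(dmso, paste0(dmso$state, "_r", dmso$replicate)),
                  function(s) glori_track(s, s$state[1]))
gmat <- build_count_matrix(gtracks, sites, annotation, scheme = "glori")
gmat$low_signal <- rowMeans(gmat$counts) <= 2
gsel <- suppressWarnings(
  normalize_and_select(gmat, size_factors(gmat$counts + 1)))
cl_gl <- hierarchical_cluster(gsel$z, k = 2)
cl_gl$cluster <- c(c1 = "ci", c2 = "cii")[cl_gl$cluster]
write.table(cl_gl, file.path(out, "clusters_glori.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

est <- read.table(file.path(out, "half_lives.tsv"), header = TRUE,
                  sep = "\t")
day5 <- est[est$state == "Day5" & est$reliable, ]
hl <- setNames(day5$t_half, day5$transcript)

cl_map <- setNames(cl_mi$cluster, cl_mi$transcript)
ks_rows <- do.call(rbind, lapply(sort(unique(cl_map)), function(cc) {
  g <- hl[names(cl_map)[cl_map == cc]]
  ref <- hl[names(hl) %in% nomiclip]
  if (sum(!is.na(g)) < 2 || sum(!is.na(ref)) < 2) return(NULL)
  ks_compare(g[!is.na(g)], ref[!is.na(ref)], cc, "nomiCLIP")
}))
write.table(ks_rows, file.path(out, "ks_clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# distance-binned KS: called RRACH-context sites, nearest scanned ARE
rr_key <- paste(sites$RRACH$contig, sites$RRACH$centre, sites$RRACH$strand)
dm <- dmso[paste(dmso$contig, dmso$pos, dmso$strand) %in% rr_key, ]
dist_df <- do.call(rbind, lapply(seq_len(nrow(dm)), function(i) {
  ac <- sites$WWAWW$centre[sites$WWAWW$contig == dm$contig[i]]
  data.frame(transcript = dm$transcript[i],
             distance = if (length(ac)) min(abs(ac - dm$pos[i])) else Inf)
}))
dist_df <- dist_df[!is.na(dist_df$transcript), ]
reference <- setdiff(names(hl), unique(dist_df$transcript))
dks <- distance_binned_ks(dist_df, hl, reference)
write.table(dks, file.path(out, "distance_ks.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

modules <- with(read.table(file.path(dat, "modules.tsv"), header = TRUE,
                           sep = "\t"), setNames(module, gene))
bins <- summarize_half_lives(day5)$categories
flows <- flow_table(modules, bins, cl_map)
write.table(flows$flows, file.path(out, "flow_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

shell <- dks[dks$framing == "shell", ]
message(sprintf(
  "clusters sized %s; KS D vs no-signal by ARE distance shell: %s",
  paste(table(cl_mi$cluster), collapse = "/"),
  paste(sprintf("%s=%.2f", shell$bin, shell$D), collapse = ", ")))
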