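#!/usr/bin/env Rscript
# Classify unstable (< 3.0 h) versus stable (> 5.3 h) transcripts from the
# ten m6A-signature features with repeated cross-validation, class
# down-sampling, a held-out test set, and conditional permutation
# importance.

suppressPackageStartupMessages(library(metadecay))

dat <- "results/data"; out <- "results"
est <- read.table(file.path(out, "half_lives.tsv"), header = TRUE,
                  sep = "\t")
cl_mi <- read.table(file.path(out, "clusters_miclip.tsv"), header = TRUE,
                    sep = "\t")
cl_gl <- read.table(file.path(out, "clusters_glori.tsv"), header = TRUE,
                    sep = "\t")
freqs <- read.table(file.path(out, "motif_frequencies.tsv"), header = TRUE,
                    sep = "\t")
names(freqs)[2:3] <- c("rrach_freq", "are_freq")
modules <- with(read.table(file.path(dat, "modules.tsv"), header = TRUE,
                           sep = "\t"), setNames(module, gene))

ft <- build_feature_table(est, cl_mi, cl_gl, modules, freqs)
sp <- split_train_test(ft, 0.75, seed = 21)
cv <- train_cv(ft[sp$train, , drop = FALSE], seed = 22)
cv_eval <- cv
cv_eval$table <- ft
rep_ <- evaluate_classifier(cv_eval, sp$test)
imp <- conditional_importance(cv, n_perm = 15, seed = 23)

write.table(cv$fold_metrics, file.path(out, "cv_fold_metrics.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(metric = names(rep_$metrics),
                       value = unname(rep_$metrics)),
            file.path(out, "test_metrics.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(rep_$roc, file.path(out, "roc_curve.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rep_$pr, file.path(out, "pr_curve.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(imp, file.path(out, "conditional_importance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf(
  "trained on %d rows (%d folds x metrics rows), test balanced accuracy %.0f%%, F1 %.0f%%, AUC-ROC %.2f; top conditional features: %s",
  length(sp$train), nrow(cv$fold_metrics),
  100 * rep_$metrics[["balanced_accuracy"]], 100 * rep_$metrics[["f1"]],
  rep_$auc_roc, paste(head(imp$feature, 3), collapse = ", ")))
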