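# Unstable-versus-stable transcript classification from m6A-signature
# features: percentile labelling, stratified splitting, repeated
# cross-validation with class down-sampling, conditional permutation
# importance, and the full confusion-matrix metric suite with ROC/PR curves.

#' Label transcripts by half-life percentile cuts
#'
#' Unstable strictly below `low_cut`, stable strictly above `high_cut`;
#' transcripts between the cuts are excluded (NA).
#'
#' @param half_lives numeric vector (hours).
#' @param low_cut,high_cut cut values (defaults 3.0 and 5.3 h).
#' @return factor with levels `unstable`, `stable` (NA = excluded).
#' @export
label_by_percentiles <- function(half_lives, low_cut = 3.0, high_cut = 5.3) {
  if (low_cut >= high_cut) stop("low_cut must be below high_cut")
  factor(ifelse(half_lives < low_cut, "unstable",
                ifelse(half_lives > high_cut, "stable", NA)),
         levels = c("unstable", "stable"))
}

#' Label transcripts by half-life log2 fold change
#'
#' Destabilised strictly below `low`, stabilised strictly above `high`;
#' boundary values are excluded.
#'
#' @param log2fc numeric vector of half-life log2 fold changes.
#' @param low,high cut values (defaults -0.73 and 0.30).
#' @return factor with levels `destabilised`, `stabilised` (NA = excluded).
#' @export
label_by_fold_change <- function(log2fc, low = -0.73, high = 0.30) {
  factor(ifelse(log2fc < low, "destabilised",
                ifelse(log2fc > high, "stabilised", NA)),
         levels = c("destabilised", "stabilised"))
}

#' Stratified train/test split
#'
#' @param table feature data.frame with a factor `label` column.
#' @param train_frac training fraction (default 0.75).
#' @param seed integer seed.
#' @return list with integer row indices `train` and `test` (disjoint,
#'   exhaustive, class proportions preserved within one transcript).
#' @export
split_train_test <- function(table, train_frac = 0.75, seed) {
  lab <- table$label
  if (nlevels(droplevels(lab)) < 2L) stop("both classes must be present")
  if (any(table(lab) < 4L)) stop("each class needs at least 4 members")
  set.seed(seed)
  train <- integer(0)
  for (lv in levels(lab)) {
    idx <- which(lab == lv)
    n_tr <- round(train_frac * length(idx))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(table)), train))
}

feature_matrix <- function(table) {
  # one-hot encoding of the predictor columns (label dropped)
  x <- table[, setdiff(names(table), "label"), drop = FALSE]
  for (j in names(x)) if (is.character(x[[j]])) x[[j]] <- factor(x[[j]])
  mm <- stats::model.matrix(~ . - 1, data = x)
  mm
}

downsample_idx <- function(lab, idx, seed) {
  # balance classes by down-sampling the majority class within idx
  set.seed(seed)
  tab <- table(lab[idx])
  n_min <- min(tab)
  unlist(lapply(names(tab), function(lv) {
    i <- idx[lab[idx] == lv]
    if (length(i) > n_min) sample(i, n_min) else i
  }), use.names = FALSE)
}

fit_rf <- function(table, idx, mtry, num_trees, seed) {
  mm <- feature_matrix(table[idx, , drop = FALSE])
  ranger::ranger(x = mm, y = droplevels(table$label[idx]),
                 num.trees = num_trees, mtry = min(mtry, ncol(mm)),
                 probability = TRUE, seed = seed)
}

predict_rf <- function(model, table, idx) {
  mm <- feature_matrix(table[idx, , drop = FALSE])
  pr <- stats::predict(model, data = mm)$predictions
  pr[, levels(table$label)[1]]  # probability of the positive (first) class
}

#' Repeated cross-validated random-forest training with down-sampling
#'
#' Runs `repeats` x `folds` cross-validation on the training rows: within
#' each fold's training part the majority class is down-sampled to the
#' minority size before fitting. The number of candidate features per split
#' (mtry) is tuned over `tune_length` random settings by mean
#' cross-validation accuracy, and the final model is refit on the full
#' (down-sampled) training set at the selected setting.
#'
#' @param table feature data.frame with a factor `label` column (the first
#'   level is treated as the positive class).
#' @param folds,repeats cross-validation design (defaults 10 and 3, i.e. 30
#'   fold models).
#' @param downsample balance classes in each fold's training part
#'   (default TRUE).
#' @param tune_length number of random mtry candidates (default 10).
#' @param num_trees trees per forest (default 300).
#' @param seed integer seed.
#' @return list of class `cv_rf`: `final` model, `mtry`, `fold_metrics`
#'   (one row per fold model: accuracy, balanced accuracy, ...),
#'   `fold_models`, `fold_holdout` (row indices), `table`, `seed`.
#' @export
train_cv <- function(table, folds = 10, repeats = 3, downsample = TRUE,
                     tune_length = 10, num_trees = 300, seed) {
  lab <- droplevels(table$label)
  table$label <- lab
  n <- nrow(table)
  p <- ncol(feature_matrix(table))
  set.seed(seed)
  cand <- sort(unique(sample.int(p, min(tune_length, p))))

  # stratified fold assignment per repeat
  assign_folds <- function(rep_seed) {
    set.seed(rep_seed)
    fa <- integer(n)
    for (lv in levels(lab)) {
      idx <- sample(which(lab == lv))
      fa[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fa
  }

  acc <- matrix(NA_real_, nrow = folds * repeats, ncol = length(cand))
  plans <- list()
  fi <- 0L
  for (r in seq_len(repeats)) {
    fa <- assign_folds(derive_seed(seed, r))
    for (f in seq_len(folds)) {
      fi <- fi + 1L
      hold <- which(fa == f)
      tr <- setdiff(seq_len(n), hold)
      if (downsample) tr <- downsample_idx(lab, tr, derive_seed(seed, 100 + fi))
      if (nlevels(droplevels(lab[tr])) < 2L || length(hold) == 0L) {
        tr <- setdiff(seq_len(n), hold)  # refold degenerate down-sample
      }
      plans[[fi]] <- list(train = tr, hold = hold)
      for (ci in seq_along(cand)) {
        m <- fit_rf(table, tr, cand[ci], num_trees,
                    derive_seed(seed, 1000 + fi * 31 + ci))
        pred <- predict_rf(m, table, hold) >= 0.5
        truth <- lab[hold] == levels(lab)[1]
        acc[fi, ci] <- mean(pred == truth)
      }
    }
  }
  best <- cand[which.max(colMeans(acc))]

  fold_models <- vector("list", length(plans))
  fold_metrics <- vector("list", length(plans))
  for (fi in seq_along(plans)) {
    m <- fit_rf(table, plans[[fi]]$train, best, num_trees,
                derive_seed(seed, 2000 + fi))
    fold_models[[fi]] <- m
    hold <- plans[[fi]]$hold
    cm <- confusion_metrics(lab[hold],
                            predict_rf(m, table, hold) >= 0.5,
                            positive = levels(lab)[1])
    fold_metrics[[fi]] <- cbind(fold = fi, as.data.frame(as.list(cm)))
  }

  tr_all <- seq_len(n)
  if (downsample) tr_all <- downsample_idx(lab, tr_all, derive_seed(seed, 7))
  final <- fit_rf(table, tr_all, best, num_trees, derive_seed(seed, 8))
  structure(list(final = final, mtry = best,
                 fold_metrics = do.call(rbind, fold_metrics),
                 fold_models = fold_models,
                 fold_holdout = lapply(plans, `[[`, "hold"),
                 table = table, num_trees = num_trees, seed = seed),
            class = "cv_rf")
}

confusion_metrics <- function(truth, pred_positive, positive) {
  truth_pos <- truth == positive
  tp <- sum(pred_positive & truth_pos)
  fp <- sum(pred_positive & !truth_pos)
  fn <- sum(!pred_positive & truth_pos)
  tn <- sum(!pred_positive & !truth_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && ppv + sens > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  c(accuracy = (tp + tn) / length(truth),
    balanced_accuracy = mean(c(sens, spec)),
    sensitivity = sens, specificity = spec, precision = ppv, recall = sens,
    ppv = ppv, npv = npv, f1 = f1)
}

#' Evaluate a fitted model on a held-out test partition
#'
#' Confusion-matrix metrics at the 0.5 vote threshold, plus ROC and
#' precision-recall curves over all score thresholds with their AUCs
#' (trapezoidal for ROC; step-interpolated average precision for PR).
#'
#' @param cv a `cv_rf` from [train_cv()].
#' @param test_idx integer row indices of the test partition.
#' @return list of class `classifier_report`: `metrics`, `roc`
#'   (fpr/tpr points), `pr` (recall/precision points), `auc_roc`, `auc_pr`.
#' @export
evaluate_classifier <- function(cv, test_idx) {
  table <- cv$table
  lab <- table$label[test_idx]
  if (nlevels(droplevels(lab)) < 2L) stop("test set has a single class")
  positive <- levels(table$label)[1]
  score <- predict_rf(cv$final, table, test_idx)
  metrics <- confusion_metrics(lab, score >= 0.5, positive)

  truth <- lab == positive
  thr <- sort(unique(c(-Inf, score, Inf)), decreasing = TRUE)
  tpr <- fpr <- prec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pp <- score >= thr[i]
    tpr[i] <- if (sum(truth)) sum(pp & truth) / sum(truth) else 0
    fpr[i] <- if (sum(!truth)) sum(pp & !truth) / sum(!truth) else 0
    prec[i] <- if (sum(pp)) sum(pp & truth) / sum(pp) else 1
  }
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  o <- order(tpr)
  rec_s <- tpr[o]; prec_s <- prec[o]
  auc_pr <- sum(diff(rec_s) * utils::tail(prec_s, -1))
  structure(list(metrics = metrics,
                 roc = data.frame(fpr = fpr, tpr = tpr),
                 pr = data.frame(recall = tpr, precision = prec),
                 auc_roc = auc_roc, auc_pr = auc_pr,
                 n_test = length(test_idx)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("classifier_report on", x$n_test, "held-out transcripts\n")
  print(round(x$metrics, 3))
  cat(sprintf("AUC-ROC %.3f, AUC-PR %.3f\n", x$auc_roc, x$auc_pr))
  invisible(x)
}

feature_association <- function(a, b) {
  # type-appropriate absolute association between two predictor columns:
  # numeric-numeric -> |Pearson|; numeric-categorical -> multiple-R
  # (point-biserial generalisation); categorical pairs -> Cramer's V
  num_a <- is.numeric(a); num_b <- is.numeric(b)
  if (num_a && num_b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    return(abs(stats::cor(a, b)))
  }
  if (xor(num_a, num_b)) {
    num <- if (num_a) a else b
    cat_ <- factor(if (num_a) b else a)
    if (stats::sd(num) == 0 || nlevels(droplevels(cat_)) < 2L) return(0)
    r2 <- summary(stats::lm(num ~ cat_))$r.squared
    return(sqrt(max(r2, 0)))
  }
  ta <- factor(a); tb <- factor(b)
  if (nlevels(droplevels(ta)) < 2L || nlevels(droplevels(tb)) < 2L) return(0)
  tab <- table(ta, tb)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  v <- sqrt(as.numeric(chi) / (sum(tab) * (min(dim(tab)) - 1)))
  if (is.finite(v)) v else 0
}

conditioning_strata <- function(table, cond_features, min_size = 2L) {
  # cross of conditioning features; continuous ones quartile-binned;
  # singleton strata merged into the largest stratum
  if (length(cond_features) == 0L) return(rep(1L, nrow(table)))
  binned <- lapply(cond_features, function(j) {
    x <- table[[j]]
    if (is.numeric(x) && length(unique(x)) > 4L) {
      qs <- unique(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
      cut(x, breaks = unique(c(-Inf, qs, Inf)))
    } else factor(x)
  })
  strat <- interaction(binned, drop = TRUE)
  sizes <- table(strat)
  small <- names(sizes)[sizes < min_size]
  if (length(small)) {
    biggest <- names(sizes)[which.max(sizes)]
    levels(strat)[levels(strat) %in% small] <- biggest
  }
  as.integer(strat)
}

#' Conditional permutation importance
#'
#' For each predictor, the features associated with it beyond
#' `assoc_threshold` (type-appropriate association: |Pearson|,
#' point-biserial multiple-R, or Cramer's V) define conditioning strata
#' (their cross, continuous features quartile-binned). The predictor is
#' permuted within those strata and the importance is the mean decrease in
#' held-out-fold accuracy over the fold models and `n_perm` permutations, so
#' information shared with correlated predictors is not double-credited.
#'
#' @param cv a `cv_rf` from [train_cv()].
#' @param n_perm permutations per feature per fold model (default 50).
#' @param assoc_threshold association cutoff for conditioning (default 0.2).
#' @param seed integer seed.
#' @return data.frame with `feature`, `importance` (mean accuracy decrease),
#'   `se`, and `conditioned_on`.
#' @export
conditional_importance <- function(cv, n_perm = 50, assoc_threshold = 0.2,
                                   seed) {
  table <- cv$table
  feats <- setdiff(names(table), "label")
  lab <- table$label
  positive <- levels(lab)[1]
  base_acc <- vapply(seq_along(cv$fold_models), function(fi) {
    hold <- cv$fold_holdout[[fi]]
    mean((predict_rf(cv$fold_models[[fi]], table, hold) >= 0.5) ==
           (lab[hold] == positive))
  }, numeric(1))

  out <- lapply(seq_along(feats), function(j) {
    fj <- feats[j]
    assoc <- vapply(setdiff(feats, fj), function(fk) {
      feature_association(table[[fj]], table[[fk]])
    }, numeric(1))
    cond <- names(assoc)[assoc > assoc_threshold]
    strat <- conditioning_strata(table, cond)
    drops <- matrix(NA_real_, length(cv$fold_models), n_perm)
    for (b in seq_len(n_perm)) {
      set.seed(derive_seed(seed, j * 1000 + b))
      perm <- table
      for (s in unique(strat)) {
        i <- which(strat == s)
        perm[[fj]][i] <- perm[[fj]][i][sample.int(length(i))]
      }
      for (fi in seq_along(cv$fold_models)) {
        hold <- cv$fold_holdout[[fi]]
        acc <- mean((predict_rf(cv$fold_models[[fi]], perm, hold) >= 0.5) ==
                      (lab[hold] == positive))
        drops[fi, b] <- base_acc[fi] - acc
      }
    }
    data.frame(feature = fj, importance = mean(drops),
               se = stats::sd(as.vector(drops)) / sqrt(length(drops)),
               conditioned_on = paste(cond, collapse = ","))
  })
  res <- do.call(rbind, out)
  res[order(-res$importance), ]
}
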