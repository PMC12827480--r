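# Configuration handling and the end-to-end synthetic run wiring all stages:
# generate -> motifs -> crosslink/conversion signal -> half-lives ->
# matrices/clusters -> stability statistics -> classifier.

#' Default pipeline configuration
#'
#' All defaults of the analysis in one place: crosslink thresholding
#' percentile 0.7; k-mer parameters k = 5, w = 10, dw = 150, s = 6;
#' conversion-site calling depth >= 15 and ratio >= 0.1; decay-fit
#' reliability R-squared > 0.5; top 1000 variable 3'UTRs; 10-fold x 3-repeat
#' cross-validation with a 0.75 training fraction; stability cuts 3.0/5.3 h
#' and fold-change cuts -0.73/0.30; distance windows 3/5/15/25/50 nt and the
#' +/-4 nt composite flank.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    stages = list(simulate = TRUE, motifs = TRUE, miclip = TRUE,
                  glori = TRUE, slam = TRUE, cluster = TRUE, stats = TRUE,
                  classify = TRUE),
    simulate = list(
      n_genes = 200, utr_length_range = c(400, 1200),
      archetype_mix = c(0.25, 0.25, 0.25, 0.25), minus_strand_frac = 0.3,
      enrichment_fold = 8, background_rate = 1, n_events = 2e5,
      n_miclip_per_state = 2, n_input_per_state = 2,
      depth_mean = 50, conversion_composite = 0.6,
      conversion_isolated = 0.45, noise_conversion = 0.02,
      mettl3i_factor = 0.3, glori_replicates = 2, noise_site_frac = 0.15,
      noise_cv = 0.1, timepoints = c(0, 0.5, 1, 3, 6, 16),
      baseline = 0.1, background = 0.005, sdlog = 0.35,
      module_informativeness = 0.5),
    miclip = list(percentile = 0.7, k = 5, w = 10, dw = 150, s = 6,
                  n_perm = 100),
    glori = list(min_depth = 15, min_ratio = 0.1, max_gene_dist = 2000,
                 composite_flank = 4),
    slam = list(r2_min = 0.5),
    cluster = list(attr_window = 10, composite_window = 50, input_min = 500,
                   nomiclip_max = 2, top_n = 1000, k_miclip = 4,
                   k_glori = 2, linkage = "ward.D2"),
    stats = list(windows = c(3, 5, 15, 25, 50)),
    classify = list(low_cut = 3.0, high_cut = 5.3, fc_low = -0.73,
                    fc_high = 0.30, train_frac = 0.75, folds = 10,
                    repeats = 3, tune_length = 10, n_perm = 50,
                    assoc_threshold = 0.2, num_trees = 300)
  )
}

merge_config <- function(defaults, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) stop("unknown config key: ", full)
    dv <- defaults[[key]]
    ov <- override[[key]]
    if (is.list(dv) && !is.null(names(dv))) {
      if (!is.list(ov)) stop("config key ", full, " must be a mapping")
      defaults[[key]] <- merge_config(dv, ov, full)
    } else {
      if (is.null(ov)) {
        defaults[key] <- list(NULL)   # keep the key; [[<- would drop it
        next
      }
      if (is.numeric(dv) && !is.numeric(ov)) {
        stop("config key ", full, " must be numeric")
      }
      if (is.logical(dv) && !is.logical(ov)) {
        stop("config key ", full, " must be logical")
      }
      defaults[[key]] <- ov
    }
  }
  defaults
}

#' Load and normalise a YAML pipeline configuration
#'
#' Unset keys take their defaults from [default_config()]; unknown keys and
#' type mismatches are errors. An empty file yields the full default
#' configuration.
#'
#' @param path YAML file.
#' @return Normalised configuration list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::yaml.load_file(path)
  if (is.null(user)) user <- list()
  merge_config(default_config(), user)
}

stage_log <- function(env, stage, t0, seed) {
  entry <- data.frame(stage = stage,
                      wall_s = round(as.numeric(Sys.time()) - t0, 3),
                      seed = seed)
  env$log <- rbind(env$log, entry)
  message(sprintf("[%s] done in %.2fs (seed %d)", stage, entry$wall_s, seed))
}

#' Build the classifier feature table
#'
#' One row per (transcript, state) with ten predictors: the six cluster
#' indicators (presence in each crosslink cluster c1-c4 and conversion
#' cluster ci/cii), the CD8 state and gene module as categorical features,
#' and the 3'UTR RRACH and ARE pentamer frequencies; plus the stability
#' `label` from the half-life percentile cuts.
#'
#' @param estimates data.frame with `state`, `transcript`, `t_half`,
#'   `reliable`.
#' @param clusters_miclip,clusters_glori data.frames
#'   (`transcript`, `cluster`).
#' @param modules named vector (transcript -> module).
#' @param motif_freqs data.frame with `transcript`, `rrach_freq`,
#'   `are_freq`.
#' @param low_cut,high_cut half-life cuts in hours (defaults 3.0, 5.3).
#' @return data.frame with the ten predictors and factor `label`
#'   (rows between the cuts or without a label dropped); transcript/state
#'   ids kept as attributes `transcript` and `state`.
#' @export
build_feature_table <- function(estimates, clusters_miclip, clusters_glori,
                                modules, motif_freqs, low_cut = 3.0,
                                high_cut = 5.3) {
  est <- estimates[estimates$reliable, , drop = FALSE]
  lab <- label_by_percentiles(est$t_half, low_cut, high_cut)
  keep <- !is.na(lab)
  est <- est[keep, , drop = FALSE]
  lab <- lab[keep]
  cm <- stats::setNames(clusters_miclip$cluster, clusters_miclip$transcript)
  cg <- stats::setNames(clusters_glori$cluster, clusters_glori$transcript)
  tf <- est$transcript
  ind <- function(map, lv) as.integer(!is.na(map[tf]) & map[tf] == lv)
  out <- data.frame(
    c1 = ind(cm, "c1"), c2 = ind(cm, "c2"), c3 = ind(cm, "c3"),
    c4 = ind(cm, "c4"),
    ci = ind(cg, "ci"), cii = ind(cg, "cii"),
    state = factor(est$state),
    module = factor(unname(modules[tf])),
    rrach_freq = motif_freqs$rrach_freq[match(tf, motif_freqs$transcript)],
    are_freq = motif_freqs$are_freq[match(tf, motif_freqs$transcript)],
    label = lab)
  ok <- stats::complete.cases(out)
  out <- out[ok, , drop = FALSE]
  attr(out, "transcript") <- tf[ok]
  attr(out, "state") <- est$state[ok]
  out
}

#' Run the full synthetic analysis pipeline
#'
#' Stages run in dependency order; disabling a stage skips it and every
#' stage that needs its outputs (with a logged notice). With `out_dir` set,
#' tables are written as TSV and a checksum manifest as JSON; reruns with
#' the same configuration are byte-identical for deterministic stages.
#'
#' @param config configuration list (see [default_config()] /
#'   [validate_config()]).
#' @return list of class `pipeline_result` with the per-stage outputs and a
#'   `log` data.frame.
#' @export
run_pipeline <- function(config = default_config()) {
  env <- new.env()
  env$log <- data.frame()
  seed <- config$seed
  res <- list(config = config)
  cs <- config$simulate

  stopifnot(config$stages$simulate)
  t0 <- as.numeric(Sys.time())
  sim <- generate_transcriptome(
    n_genes = cs$n_genes, utr_length_range = cs$utr_length_range,
    archetype_mix = cs$archetype_mix, seed = derive_seed(seed, 1),
    minus_strand_frac = cs$minus_strand_frac)
  xl <- simulate_crosslinks(
    sim, enrichment_fold = cs$enrichment_fold,
    background_rate = cs$background_rate, n_events = cs$n_events,
    n_miclip_per_state = cs$n_miclip_per_state,
    n_input_per_state = cs$n_input_per_state,
    seed = derive_seed(seed, 2))
  gl <- simulate_glori(
    sim, depth_mean = cs$depth_mean,
    conversion_by_class = c(composite = cs$conversion_composite,
                            isolated = cs$conversion_isolated),
    noise_conversion = cs$noise_conversion,
    mettl3i_factor = cs$mettl3i_factor,
    noise_site_frac = cs$noise_site_frac,
    replicates = cs$glori_replicates, seed = derive_seed(seed, 3))
  sl <- simulate_slam(sim, noise_cv = cs$noise_cv,
                      timepoints = cs$timepoints, baseline = cs$baseline,
                      background = cs$background, sdlog = cs$sdlog,
                      seed = derive_seed(seed, 4))
  modules <- assign_modules(sim, cs$module_informativeness,
                            seed = derive_seed(seed, 5))
  res$sim <- sim; res$crosslinks <- xl; res$glori_pileups <- gl
  res$slam <- sl; res$modules <- modules
  stage_log(env, "simulate", t0, seed)

  if (config$stages$motifs) {
    t0 <- as.numeric(Sys.time())
    res$motif_sites <- list(
      RRACH = motif_sites_in_3utrs(sim$annotation, sim$sequences, "RRACH"),
      WWAWW = motif_sites_in_3utrs(sim$annotation, sim$sequences, "WWAWW"),
      CRACH = motif_sites_in_3utrs(sim$annotation, sim$sequences, "CRACH"))
    utrs <- annotation_regions(sim$annotation, "3UTR")
    res$motif_freqs <- do.call(rbind, lapply(seq_len(nrow(utrs)), function(i) {
      u <- utrs[i, ]
      s <- interval_sequence(sim$sequences, u$contig, u$start, u$end,
                             u$strand)
      data.frame(transcript = u$transcript,
                 rrach_freq = motif_frequency(s, "RRACH")$per_kb,
                 are_freq = motif_frequency(s, "WWAWW")$per_kb)
    }))
    stage_log(env, "motifs", t0, seed)
  }

  if (config$stages$miclip && config$stages$motifs) {
    t0 <- as.numeric(Sys.time())
    cm <- config$miclip
    thr <- lapply(xl$tracks[vapply(xl$tracks, function(t) t$role,
                                   character(1)) == "miCLIP"],
                  threshold_crosslinks, peaks = xl$peaks,
                  percentile = cm$percentile)
    res$thresholded <- thr
    pooled_thr <- do.call(rbind, lapply(thr, `[[`, "thresholded"))
    pooled_bg <- do.call(rbind, lapply(thr, `[[`, "background"))
    res$peka <- peka_scores(pooled_thr, pooled_bg, sim$sequences,
                            k = cm$k, w = cm$w, dw = cm$dw, s = cm$s,
                            n_perm = cm$n_perm,
                            seed = derive_seed(seed, 11))
    stage_log(env, "miclip", t0, seed)
  } else if (config$stages$miclip) {
    message("[miclip] skipped: requires the motifs stage")
  }

  if (config$stages$glori && config$stages$motifs) {
    t0 <- as.numeric(Sys.time())
    cg <- config$glori
    called <- list()
    for (nm in names(gl)) {
      meta <- attr(gl[[nm]], "meta")
      rt <- conversion_ratio(gl[[nm]], sim$sequences)
      sites <- call_glori_sites(rt, cg$min_depth, cg$min_ratio)
      sites <- annotate_glori_sites(sites, sim$annotation, sim$sequences,
                                    cg$max_gene_dist)
      if (nrow(sites)) {
        sites$state <- meta$state; sites$condition <- meta$condition
        sites$replicate <- meta$replicate
        called[[nm]] <- sites
      }
    }
    res$glori_sites <- do.call(rbind, called)
    rownames(res$glori_sites) <- NULL
    are_centres <- res$motif_sites$WWAWW
    res$glori_metagene <- glori_metagene(
      res$glori_sites, are_centres, flank = 10,
      conditions = c("DMSO", "METTL3i"))
    dm <- res$glori_sites[res$glori_sites$condition == "DMSO", , drop = FALSE]
    res$fraction_near_are <- fraction_near_sites(dm, are_centres,
                                                 window = cg$composite_flank)
    stage_log(env, "glori", t0, seed)
  } else if (config$stages$glori) {
    message("[glori] skipped: requires the motifs stage")
  }

  if (config$stages$slam) {
    t0 <- as.numeric(Sys.time())
    ests <- lapply(split(sl$curves, sl$curves$state), function(cc) {
      e <- fit_decay_table(cc[, c("transcript", "time_h", "rate")],
                           background = sl$background,
                           r2_min = config$slam$r2_min)
      e$state <- cc$state[1]
      e
    })
    res$half_lives <- do.call(rbind, ests)
    rownames(res$half_lives) <- NULL
    res$half_life_summary <- lapply(
      split(res$half_lives, res$half_lives$state), summarize_half_lives)
    stage_log(env, "slam", t0, seed)
  }

  if (config$stages$cluster && config$stages$miclip &&
      config$stages$motifs) {
    t0 <- as.numeric(Sys.time())
    cc <- config$cluster
    thr_tracks <- lapply(names(res$thresholded), function(nm) {
      crosslink_track(res$thresholded[[nm]]$thresholded, sample_id = nm,
                      role = "miCLIP")
    })
    names(thr_tracks) <- names(res$thresholded)
    input_tracks <- xl$tracks[vapply(xl$tracks, function(t) t$role,
                                     character(1)) == "input"]
    mat <- build_count_matrix(
      c(thr_tracks, input_tracks),
      res$motif_sites[c("RRACH", "WWAWW")], sim$annotation,
      scheme = "miclip", attr_window = cc$attr_window)
    mat <- exclude_low_signal(mat, cc$input_min, cc$nomiclip_max)
    sf <- size_factors(mat)
    sel <- normalize_and_select(mat, sf, top_n = cc$top_n)
    res$miclip_matrix <- mat; res$miclip_factors <- sf
    res$clusters_miclip <- hierarchical_cluster(sel$z, k = cc$k_miclip,
                                                method = cc$linkage,
                                                prefix = "c")
    res$nomiclip <- names(which(mat$low_signal))

    if (config$stages$glori && !is.null(res$glori_sites)) {
      gsub_ <- res$glori_sites[res$glori_sites$condition == "DMSO", ,
                               drop = FALSE]
      gtracks <- lapply(split(gsub_, paste(gsub_$state, gsub_$replicate,
                                           sep = "_r")),
                        function(s) glori_track(s, paste0("glori_",
                                                          s$state[1])))
      names(gtracks) <- paste0("glori_", names(gtracks))
      gmat <- build_count_matrix(
        gtracks, res$motif_sites[c("RRACH", "WWAWW")], sim$annotation,
        scheme = "glori", attr_window = cc$attr_window,
        composite_window = cc$composite_window)
      gmat$low_signal <- rowMeans(gmat$counts) <= cc$nomiclip_max
      gsf <- size_factors2(gmat$counts)
      gsel <- normalize_and_select(gmat, gsf, top_n = cc$top_n)
      res$glori_matrix <- gmat
      res$clusters_glori <- hierarchical_cluster(
        gsel$z, k = cc$k_glori, method = cc$linkage, prefix = "c")
      res$clusters_glori$cluster <- c(c1 = "ci", c2 = "cii")[
        res$clusters_glori$cluster]
      res$noglori <- names(which(gmat$low_signal))
    }
    stage_log(env, "cluster", t0, seed)
  } else if (config$stages$cluster) {
    message("[cluster] skipped: requires the miclip and motifs stages")
  }

  if (config$stages$stats && config$stages$slam &&
      !is.null(res$clusters_miclip)) {
    t0 <- as.numeric(Sys.time())
    day5 <- res$half_lives[res$half_lives$state == "Day5" &
                             res$half_lives$reliable, ]
    hl <- stats::setNames(day5$t_half, day5$transcript)
    cl <- stats::setNames(res$clusters_miclip$cluster,
                          res$clusters_miclip$transcript)
    res$ks_clusters <- do.call(rbind, lapply(sort(unique(cl)), function(cc_) {
      g <- hl[names(cl)[cl == cc_]]
      ref <- hl[names(hl) %in% res$nomiclip]
      if (length(g) < 2 || length(ref) < 2) return(NULL)
      ks_compare(g[!is.na(g)], ref[!is.na(ref)], cc_, "nomiCLIP")
    }))

    if (!is.null(res$glori_sites)) {
      # sites at scanned RRACH motif centres (the RRACH-site analysis unit)
      rr_key <- paste(res$motif_sites$RRACH$contig,
                      res$motif_sites$RRACH$centre,
                      res$motif_sites$RRACH$strand)
      gs_ <- res$glori_sites
      dm <- gs_[gs_$condition == "DMSO" &
                  paste(gs_$contig, gs_$pos, gs_$strand) %in% rr_key, ]
      ares <- res$motif_sites$WWAWW
      dist_df <- do.call(rbind, lapply(seq_len(nrow(dm)), function(i) {
        ac <- ares$centre[ares$contig == dm$contig[i]]
        d <- if (length(ac)) min(abs(ac - dm$pos[i])) else Inf
        data.frame(transcript = dm$transcript[i], distance = d)
      }))
      dist_df <- dist_df[!is.na(dist_df$transcript), ]
      with_sites <- unique(dist_df$transcript)
      reference <- setdiff(names(hl), with_sites)
      res$distance_ks <- distance_binned_ks(dist_df, hl, reference,
                                            windows = config$stats$windows)
      res$site_distances <- dist_df
    }

    bins <- res$half_life_summary$Day5$categories
    res$flows <- flow_table(res$modules, bins,
                            stats::setNames(res$clusters_miclip$cluster,
                                            res$clusters_miclip$transcript))
    stage_log(env, "stats", t0, seed)
  } else if (config$stages$stats) {
    message("[stats] skipped: requires the slam and cluster stages")
  }

  if (config$stages$classify && !is.null(res$clusters_miclip) &&
      config$stages$slam) {
    t0 <- as.numeric(Sys.time())
    ck <- config$classify
    ft <- build_feature_table(
      res$half_lives, res$clusters_miclip,
      res$clusters_glori %||% data.frame(transcript = character(0),
                                         cluster = character(0)),
      res$modules, res$motif_freqs, ck$low_cut, ck$high_cut)
    sp <- split_train_test(ft, ck$train_frac, seed = derive_seed(seed, 21))
    cv <- train_cv(ft[sp$train, , drop = FALSE], folds = ck$folds,
                   repeats = ck$repeats, tune_length = ck$tune_length,
                   num_trees = ck$num_trees, seed = derive_seed(seed, 22))
    # evaluate on the held-out rows with the final model
    cv_eval <- cv
    cv_eval$table <- ft
    res$classifier <- cv
    res$feature_table <- ft
    res$split <- sp
    res$report <- evaluate_classifier(cv_eval, sp$test)
    res$importance <- conditional_importance(
      cv, n_perm = ck$n_perm, assoc_threshold = ck$assoc_threshold,
      seed = derive_seed(seed, 23))
    stage_log(env, "classify", t0, seed)
  } else if (config$stages$classify) {
    message("[classify] skipped: requires the cluster and slam stages")
  }

  res$log <- env$log
  class(res) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- character(0)
  if (!is.null(res$peka)) paths <- c(paths, wt(res$peka$scores, "peka_scores.tsv"))
  if (!is.null(res$half_lives)) paths <- c(paths, wt(res$half_lives, "half_lives.tsv"))
  if (!is.null(res$clusters_miclip)) paths <- c(paths, wt(res$clusters_miclip, "clusters_miclip.tsv"))
  if (!is.null(res$clusters_glori)) paths <- c(paths, wt(res$clusters_glori, "clusters_glori.tsv"))
  if (!is.null(res$distance_ks)) paths <- c(paths, wt(res$distance_ks, "distance_ks.tsv"))
  if (!is.null(res$flows)) paths <- c(paths, wt(res$flows$flows, "flow_table.tsv"))
  if (!is.null(res$importance)) paths <- c(paths, wt(res$importance, "importance.tsv"))
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "output_manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(paths)
}

# size factors with a pseudocount fallback for sparse conversion matrices
size_factors2 <- function(counts) {
  tryCatch(size_factors(counts),
           error = function(e) size_factors(counts + 1))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result with stages:\n")
  print(x$log, row.names = FALSE)
  invisible(x)
}
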