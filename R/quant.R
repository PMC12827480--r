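# Motif-partitioned 3'UTR count matrices, median-of-ratios size factors,
# variance stabilisation, top-variable selection and hierarchical clustering.

#' Build a 3'UTR x (sample, motif class) count matrix
#'
#' An event (thresholded crosslink or called m6A count) is attributed to a
#' motif class when its position lies within `attr_window` nt of a site
#' centre of that class; events matching sites of two classes go to the
#' nearer centre (exact ties are logged and go to the first class listed).
#' Counts are summed per 3'UTR. For the conversion-based (`"glori"`) scheme,
#' RRACH site centres are partitioned into `RRACH_only` versus
#' `ARE_flanking` (an ARE centre within +/-`composite_window` nt).
#'
#' @param tracks named list of [crosslink_track()] objects (names become
#'   column sample ids), or a single track. For the glori scheme, pass called
#'   site tables via [glori_track()].
#' @param motif_sites named list of site data.frames per class (each with
#'   `contig`, `centre`, `strand`, `transcript`), e.g. from
#'   [motif_sites_in_3utrs()].
#' @param annotation a `transcript_annotation`.
#' @param scheme `"miclip"` (classes as given) or `"glori"` (RRACH split by
#'   ARE proximity).
#' @param attr_window attribution half-width in nt (default 10, the proximal
#'   k-mer window).
#' @param composite_window ARE-flanking window for the glori scheme
#'   (default 50).
#' @return list of class `motif_count_matrix`: integer `counts` matrix
#'   (rows = 3'UTR transcripts, columns = sample.class), `samples`,
#'   `classes`, `roles` per column.
#' @export
build_count_matrix <- function(tracks, motif_sites, annotation,
                               scheme = c("miclip", "glori"),
                               attr_window = 10, composite_window = 50) {
  scheme <- match.arg(scheme)
  if (inherits(tracks, "crosslink_track")) {
    tracks <- stats::setNames(list(tracks), tracks$sample_id)
  }
  if (scheme == "glori") {
    rr <- motif_sites$RRACH
    are <- motif_sites$WWAWW
    flank <- vapply(seq_len(nrow(rr)), function(i) {
      ac <- are$centre[are$contig == rr$contig[i] & are$strand == rr$strand[i]]
      length(ac) > 0 && min(abs(ac - rr$centre[i])) <= composite_window
    }, logical(1))
    motif_sites <- list(ARE_flanking = rr[flank, , drop = FALSE],
                        RRACH_only = rr[!flank, , drop = FALSE])
  }
  classes <- names(motif_sites)
  utrs <- annotation_regions(annotation, "3UTR")
  txs <- utrs$transcript
  cols <- as.vector(outer(names(tracks), classes, paste, sep = "."))
  counts <- matrix(0L, nrow = length(txs), ncol = length(cols),
                   dimnames = list(txs, cols))
  n_outside <- 0L
  for (sm in names(tracks)) {
    ev <- tracks[[sm]]$events
    if (nrow(ev) == 0L) next
    # nearest site centre per class within the attribution window
    best_class <- rep(NA_character_, nrow(ev))
    best_dist <- rep(Inf, nrow(ev))
    best_tx <- rep(NA_character_, nrow(ev))
    for (cl in classes) {
      st <- motif_sites[[cl]]
      if (nrow(st) == 0L) next
      win <- data.frame(contig = st$contig, start = st$centre - attr_window,
                        end = st$centre + attr_window + 1L, strand = st$strand)
      hits <- overlap_hits(ev, win)
      if (nrow(hits) == 0L) next
      d <- abs(ev$pos[hits$pos_idx] - st$centre[hits$iv_idx])
      o <- order(hits$pos_idx, d)
      first <- !duplicated(hits$pos_idx[o])
      pi <- hits$pos_idx[o][first]; di <- d[o][first]
      ii <- hits$iv_idx[o][first]
      better <- di < best_dist[pi]
      tie <- di == best_dist[pi] & !is.na(best_class[pi])
      if (any(tie)) {
        message(sum(tie), " event(s) tie between motif classes; kept ",
                "first-listed class")
      }
      upd <- pi[better]
      best_dist[upd] <- di[better]
      best_class[upd] <- cl
      best_tx[upd] <- st$transcript[ii[better]]
    }
    attributed <- !is.na(best_class) & best_tx %in% txs
    n_outside <- n_outside + sum(!attributed)
    if (!any(attributed)) next
    agg <- stats::aggregate(
      ev$count[attributed],
      by = list(tx = best_tx[attributed], cl = best_class[attributed]),
      FUN = sum)
    for (i in seq_len(nrow(agg))) {
      counts[agg$tx[i], paste(sm, agg$cl[i], sep = ".")] <- agg$x[i]
    }
  }
  roles <- vapply(tracks, function(t) t$role, character(1))
  samples_col <- rep(names(tracks), times = length(classes))
  classes_col <- rep(classes, each = length(tracks))
  structure(list(
    counts = counts,
    samples = samples_col,
    classes = classes_col,
    roles = unname(roles[samples_col]),
    n_outside = n_outside), class = "motif_count_matrix")
}

#' Wrap called m6A sites as a count track
#'
#' Turns annotated called sites into a [crosslink_track()] whose counts are
#' the unconverted-read (m6A) counts, so conversion-based signal can flow
#' through [build_count_matrix()].
#'
#' @param sites annotated called sites.
#' @param sample_id sample label.
#' @return A [crosslink_track()] with role `"miCLIP"`.
#' @export
glori_track <- function(sites, sample_id) {
  fwd <- sites$strand == "+"
  cnt <- ifelse(fwd, sites$countA, sites$countT)
  keep <- cnt > 0
  crosslink_track(
    data.frame(contig = sites$contig[keep], pos = sites$pos[keep],
               strand = sites$strand[keep], count = cnt[keep]),
    sample_id = sample_id, role = "miCLIP")
}

#' Median-of-ratios size factors
#'
#' The reference for each row is its geometric mean over columns (rows with
#' any zero are excluded); the factor of a column is the median over rows of
#' count/reference.
#'
#' @param counts numeric matrix (rows = features, columns = samples) or a
#'   `motif_count_matrix`.
#' @return Named numeric vector of per-column size factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "motif_count_matrix")) counts <- counts$counts
  keep <- apply(counts > 0, 1, all)
  if (!any(keep)) {
    stop("no row is positive in all columns; consider a pseudocount")
  }
  m <- counts[keep, , drop = FALSE]
  ref <- exp(rowMeans(log(m)))
  apply(m / ref, 2, stats::median)
}

#' Drop low-count input columns and flag low-signal 3'UTRs
#'
#' Input-role columns whose 3'UTR count total is below `input_min` (strict)
#' are dropped. 3'UTRs whose mean signal count across signal-role columns is
#' at most `nomiclip_max` are flagged as the no-signal control group: they
#' are retained in the matrix but marked for exclusion from clustering.
#'
#' @param mat a `motif_count_matrix`.
#' @param input_min strict minimum 3'UTR total for input columns
#'   (default 500).
#' @param nomiclip_max inclusive maximum mean count for the no-signal flag
#'   (default 2).
#' @return `mat` with dropped input columns, plus `low_signal` (named
#'   logical per 3'UTR) and `dropped_inputs` fields.
#' @export
exclude_low_signal <- function(mat, input_min = 500, nomiclip_max = 2) {
  counts <- mat$counts
  is_input <- mat$roles == "input"
  totals <- colSums(counts)
  drop <- is_input & totals < input_min
  if (all(is_input) && all(drop)) {
    warning("all input columns dropped; proceeding without input contrasts")
  }
  mat$dropped_inputs <- colnames(counts)[drop]
  mat$counts <- counts[, !drop, drop = FALSE]
  mat$roles <- mat$roles[!drop]
  mat$classes <- mat$classes[!drop]
  mat$samples <- mat$samples[!drop]
  sig <- mat$counts[, mat$roles != "input", drop = FALSE]
  mat$low_signal <- rowMeans(sig) <= nomiclip_max
  mat
}

#' Normalise, variance-stabilise and select top-variable 3'UTRs
#'
#' Counts are divided by their column size factor, transformed with
#' log2(x + 1) (a monotone variance-stabilising transform), ranked by
#' pre-standardisation row variance, and the `top_n` most variable rows are
#' centred and scaled to unit variance. Constant rows are excluded from the
#' standardised output and flagged.
#'
#' @param mat a `motif_count_matrix` (after [exclude_low_signal()], the
#'   low-signal rows are excluded here).
#' @param factors size factors from [size_factors()].
#' @param top_n number of rows to keep (default 1000).
#' @return list: `z` standardized matrix (rows = selected 3'UTRs),
#'   `variances` (all rows, pre-standardisation), `constant_rows`.
#' @export
normalize_and_select <- function(mat, factors, top_n = 1000) {
  counts <- if (inherits(mat, "motif_count_matrix")) mat$counts else mat
  keep_rows <- rep(TRUE, nrow(counts))
  if (inherits(mat, "motif_count_matrix") && !is.null(mat$low_signal)) {
    keep_rows <- !mat$low_signal
  }
  norm <- sweep(counts, 2, factors, "/")
  vst <- log2(norm + 1)
  v <- apply(vst, 1, stats::var)
  constant <- v == 0
  pool <- which(keep_rows & !constant)
  if (top_n > length(pool)) {
    warning("top_n exceeds available rows; keeping all ", length(pool))
    top_n <- length(pool)
  }
  sel <- pool[order(-v[pool])][seq_len(top_n)]
  z <- t(scale(t(vst[sel, , drop = FALSE])))
  list(z = z, variances = v, constant_rows = rownames(counts)[constant])
}

#' Hierarchical clustering of a standardized 3'UTR table
#'
#' Agglomerative clustering on Euclidean distance (Ward linkage by
#' default; complete linkage is available but chains badly on standardized
#' count patterns), cut to `k` groups. Cluster labels are renumbered by decreasing
#' cluster size, then by row id for ties, so the labelling is independent of
#' input order.
#'
#' @param z standardized matrix from [normalize_and_select()].
#' @param k number of clusters.
#' @param method linkage method (default `"ward.D2"`).
#' @param prefix label prefix (default "c": labels c1..ck).
#' @return data.frame with `transcript` and `cluster`.
#' @export
hierarchical_cluster <- function(z, k, method = "ward.D2", prefix = "c") {
  if (k > nrow(z)) stop("k exceeds the number of rows")
  z <- z[order(rownames(z)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = method)
  raw <- stats::cutree(hc, k = k)
  size <- table(raw)
  first <- tapply(seq_along(raw), raw, min)
  o <- order(-as.integer(size), as.integer(first))
  relabel <- stats::setNames(seq_len(k), names(size)[o])
  data.frame(transcript = rownames(z),
             cluster = paste0(prefix, relabel[as.character(raw)]),
             row.names = NULL)
}
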