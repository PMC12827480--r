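# Crosslink thresholding, positional k-mer enrichment scoring, metagene and
# scaled-region density profiles, and CIMS-style substitution profiling.

#' Partition crosslinks into thresholded (high-confidence) and background sets
#'
#' A crosslink is "thresholded" when it lies inside a peak and its count is at
#' least the empirical `percentile` quantile (inverse-ECDF definition) of the
#' counts over all crosslink positions of its enclosing annotated region.
#' Background crosslinks are the positions outside all peaks.
#'
#' @param track a [crosslink_track()].
#' @param peaks data.frame of peak intervals (`contig`, `start`, `end`,
#'   `strand`, 0-based half-open).
#' @param regions optional data.frame of annotated regions used to compute
#'   per-region count quantiles; default: one region per (contig, strand)
#'   spanning that contig's crosslinks.
#' @param percentile quantile level, default 0.7.
#' @return list with `thresholded` and `background` event data.frames and the
#'   `percentile` used; the two sets are disjoint.
#' @export
threshold_crosslinks <- function(track, peaks, regions = NULL,
                                 percentile = 0.7) {
  ev <- track$events
  if (is.null(peaks) || nrow(peaks) == 0L) {
    warning("no peaks supplied: thresholded set is empty")
    return(list(thresholded = ev[0, ], background = ev,
                percentile = percentile))
  }
  if (is.null(regions)) {
    key <- paste(ev$contig, ev$strand)
    regions <- do.call(rbind, lapply(unique(key), function(k) {
      e <- ev[key == k, ]
      data.frame(contig = e$contig[1], start = min(e$pos),
                 end = max(e$pos) + 1L, strand = e$strand[1])
    }))
  }
  in_peak <- rep(FALSE, nrow(ev))
  hits <- overlap_hits(ev, peaks)
  in_peak[unique(hits$pos_idx)] <- TRUE

  pass <- rep(FALSE, nrow(ev))
  rhits <- overlap_hits(ev, regions)
  for (r in unique(rhits$iv_idx)) {
    idx <- rhits$pos_idx[rhits$iv_idx == r]
    thr <- stats::quantile(ev$count[idx], percentile, type = 1, names = FALSE)
    pass[idx] <- pass[idx] | ev$count[idx] >= thr
  }
  list(thresholded = ev[in_peak & pass, , drop = FALSE],
       background = ev[!in_peak, , drop = FALSE],
       percentile = percentile)
}

#' Naive peak caller for synthetic tracks
#'
#' Marks crosslink positions whose count reaches `min_fold` times the mean
#' count of their (contig, strand) group and merges qualifying positions
#' within `merge_gap` bases into peak intervals. Intended for synthetic runs;
#' real data should come with peaks from a dedicated caller.
#'
#' @param track a [crosslink_track()].
#' @param min_fold fold over the per-group mean count, default 3.
#' @param merge_gap merge distance in nt, default 10.
#' @return data.frame of peak intervals.
#' @export
call_peaks_naive <- function(track, min_fold = 3, merge_gap = 10) {
  ev <- track$events
  key <- paste(ev$contig, ev$strand)
  out <- list()
  for (k in unique(key)) {
    e <- ev[key == k, ]
    q <- e[e$count >= min_fold * mean(e$count), , drop = FALSE]
    if (nrow(q) == 0L) next
    p <- sort(q$pos)
    brk <- c(0L, which(diff(p) > merge_gap), length(p))
    for (i in seq_len(length(brk) - 1L)) {
      seg <- p[(brk[i] + 1L):brk[i + 1L]]
      out[[length(out) + 1L]] <- data.frame(
        contig = e$contig[1], start = min(seg), end = max(seg) + 1L,
        strand = e$strand[1])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  do.call(rbind, out)
}

# per-contig k-mer id vectors: fwd[g+1] = 4-ary id of the k-mer starting at
# 0-based position g; rev[g+1] = id of its reverse complement (NA where the
# window contains a non-ACGT base)
contig_kmer_ids <- function(seq, k) {
  v <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  n <- length(v)
  if (n < k) return(list(fwd = integer(0), rev = integer(0)))
  m <- n - k + 1L
  fwd <- numeric(m); rev <- numeric(m); bad <- logical(m)
  for (j in 0:(k - 1L)) {
    vj <- v[(1L + j):(m + j)]
    bad <- bad | is.na(vj)
    vj[is.na(vj)] <- 0L
    fwd <- fwd + vj * 4^(k - 1L - j)
    rev <- rev + (3L - vj) * 4^j
  }
  fwd <- as.integer(fwd) + 1L; rev <- as.integer(rev) + 1L
  fwd[bad] <- NA_integer_; rev[bad] <- NA_integer_
  list(fwd = fwd, rev = rev)
}

kmer_ids_around <- function(sites, sequences, k, w, cache = new.env()) {
  # integer k-mer id at transcript-orientation offsets -w..w for each site;
  # NA where the window leaves the contig or contains N
  n_off <- 2L * w + 1L
  ids <- matrix(NA_integer_, nrow(sites), n_off)
  offs <- -w:w
  for (i in seq_len(nrow(sites))) {
    ctg <- sites$contig[i]
    ck <- cache[[ctg]]
    if (is.null(ck)) {
      if (is.null(sequences[[ctg]])) next
      ck <- contig_kmer_ids(sequences[[ctg]], k)
      cache[[ctg]] <- ck
    }
    m <- length(ck$fwd)
    p <- sites$pos[i]
    if (sites$strand[i] == "+") {
      idx <- p + offs + 1L
      ok <- idx >= 1L & idx <= m
      ids[i, ok] <- ck$fwd[idx[ok]]
    } else {
      idx <- p - offs - (k - 1L) + 1L
      ok <- idx >= 1L & idx <= m
      ids[i, ok] <- ck$rev[idx[ok]]
    }
  }
  ids
}

smooth_rows <- function(m, s) {
  if (s <= 1L) return(m)
  f <- t(as.matrix(stats::filter(t(m), rep(1 / s, s), sides = 2)))
  f[is.na(f)] <- m[is.na(f)]
  f
}

all_kmers <- function(k) {
  g <- do.call(expand.grid,
               rev(replicate(k, c("A", "C", "G", "T"), simplify = FALSE)))
  apply(g[, k:1, drop = FALSE], 1, paste0, collapse = "")
}

profile_from_ids <- function(ids, n_kmer, n_off) {
  # occurrence count per (kmer, offset), normalised per site
  keep <- !is.na(ids)
  off <- col(ids)[keep]
  id <- ids[keep]
  tab <- tabulate((id - 1L) * n_off + off, nbins = n_kmer * n_off)
  matrix(tab, nrow = n_kmer, ncol = n_off, byrow = TRUE) / nrow(ids)
}

#' Positional k-mer enrichment scores around thresholded crosslinks
#'
#' For every k-mer, the occurrence-frequency profile at transcript-orientation
#' offsets within +/-`w` of the thresholded crosslinks is smoothed with a
#' moving window of `s` positions and summarised as its mean relative
#' occurrence. The same summary is computed for `n_perm` resamplings of
#' equally many background crosslinks drawn from the distal region (background
#' positions between `w` and `dw` of the nearest thresholded crosslink), and
#' the score is the z-score (observed minus resampling mean, over resampling
#' standard deviation). Deterministic under `seed`.
#'
#' @param thresholded,background event data.frames
#'   (from [threshold_crosslinks()]).
#' @param sequences named character vector of contig sequences.
#' @param k k-mer length (default 5).
#' @param w proximal window, nt (default 10).
#' @param dw distal window bounding the background draw, nt (default 150).
#' @param s smoothing window, positions (default 6).
#' @param n_perm number of background resamplings (default 100).
#' @param seed integer seed (required).
#' @return list of class `peka_result`: `scores` data.frame
#'   (`kmer`, `score`, `rank`), and the parameters.
#' @export
peka_scores <- function(thresholded, background, sequences, k = 5, w = 10,
                        dw = 150, s = 6, n_perm = 100, seed) {
  if (nrow(thresholded) < 10L) {
    stop("fewer than 10 thresholded crosslinks: k-mer enrichment would be ",
         "unstable")
  }
  if (nrow(background) == 0L) stop("background crosslink set is empty")
  n_off <- 2L * w + 1L
  kmers <- all_kmers(k)
  n_kmer <- length(kmers)

  cache <- new.env()
  ids_thr <- kmer_ids_around(thresholded, sequences, k, w, cache)
  obs_prof <- profile_from_ids(ids_thr, n_kmer, n_off)
  obs <- rowMeans(smooth_rows(obs_prof, s))

  # distal eligibility: background positions with nearest thresholded
  # crosslink (same contig/strand) between w and dw away
  dist_near <- rep(Inf, nrow(background))
  kb <- paste(background$contig, background$strand)
  kt <- paste(thresholded$contig, thresholded$strand)
  for (key in unique(kb)) {
    bi <- which(kb == key); ti <- which(kt == key)
    if (length(ti) == 0L) next
    tp <- sort(thresholded$pos[ti])
    bp <- background$pos[bi]
    j <- findInterval(bp, tp)
    d1 <- ifelse(j >= 1L, abs(bp - tp[pmax(j, 1L)]), Inf)
    d2 <- ifelse(j < length(tp), abs(tp[pmin(j + 1L, length(tp))] - bp), Inf)
    dist_near[bi] <- pmin(d1, d2)
  }
  eligible <- background[dist_near > w & dist_near <= dw, , drop = FALSE]
  if (nrow(eligible) < 10L) eligible <- background
  ids_bg <- kmer_ids_around(eligible, sequences, k, w, cache)

  n_draw <- nrow(thresholded)
  set.seed(seed)
  perm <- matrix(0, n_kmer, n_perm)
  for (b in seq_len(n_perm)) {
    take <- sample.int(nrow(eligible), n_draw, replace = TRUE)
    prof <- profile_from_ids(ids_bg[take, , drop = FALSE], n_kmer, n_off)
    perm[, b] <- rowMeans(smooth_rows(prof, s))
  }
  mu <- rowMeans(perm)
  # the comparison is against the finite background pool's mean, whose own
  # sampling error adds n/m of the resampling variance; without this factor
  # null scores are overdispersed
  sg <- apply(perm, 1, stats::sd) * sqrt(1 + n_draw / nrow(eligible))
  score <- ifelse(sg > 0, (obs - mu) / sg, 0)
  scores <- data.frame(kmer = kmers, score = score)
  scores <- scores[order(-scores$score), ]
  scores$rank <- seq_len(nrow(scores))
  structure(list(scores = scores, k = k, w = w, dw = dw, s = s,
                 n_perm = n_perm, seed = seed),
            class = "peka_result")
}

#' @export
print.peka_result <- function(x, ...) {
  cat(sprintf("peka_result: k=%d w=%d dw=%d s=%d n_perm=%d; top k-mers:\n",
              x$k, x$w, x$dw, x$s, x$n_perm))
  print(utils::head(x$scores, 5), row.names = FALSE)
  invisible(x)
}

#' Metagene profile of crosslink signal around motif centres
#'
#' Offsets run -`flank`..+`flank` in transcript orientation. With
#' `normalize_per_utr`, each 3'UTR's contribution is divided by its total
#' crosslink count in the track before averaging across centres (requires a
#' `transcript` column on `centres` and the `annotation`).
#'
#' @param track a [crosslink_track()].
#' @param centres data.frame with `contig`, `centre`, `strand` and optionally
#'   `transcript`.
#' @param flank window half-width in nt.
#' @param normalize_per_utr logical, default FALSE.
#' @param annotation `transcript_annotation`, needed for per-UTR totals.
#' @param contig_lengths optional named vector; centres whose window leaves
#'   the contig are dropped (the number dropped is reported as an attribute).
#' @return data.frame with `offset` and `value` (mean signal per centre);
#'   attribute `n_dropped`.
#' @export
metagene_profile <- function(track, centres, flank, normalize_per_utr = FALSE,
                             annotation = NULL, contig_lengths = NULL) {
  stopifnot(flank >= 1)
  ev <- track$events
  lookup <- stats::setNames(ev$count, paste(ev$contig, ev$strand, ev$pos))
  n_dropped <- 0L
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[centres$contig]
    keep <- centres$centre - flank >= 0 & centres$centre + flank < len
    n_dropped <- sum(!keep)
    centres <- centres[keep, , drop = FALSE]
  }
  offs <- -flank:flank
  if (nrow(centres) == 0L) {
    out <- data.frame(offset = offs, value = 0)
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  wt <- rep(1, nrow(centres))
  if (normalize_per_utr) {
    if (is.null(annotation) || is.null(centres$transcript)) {
      stop("normalize_per_utr needs an annotation and centres$transcript")
    }
    utrs <- annotation_regions(annotation, "3UTR")
    hits <- overlap_hits(
      data.frame(contig = ev$contig, pos = ev$pos, strand = ev$strand), utrs)
    totals <- tapply(ev$count[hits$pos_idx], utrs$transcript[hits$iv_idx], sum)
    tot <- totals[centres$transcript]
    keep <- !is.na(tot) & tot > 0
    n_dropped <- n_dropped + sum(!keep)
    centres <- centres[keep, , drop = FALSE]
    wt <- 1 / as.numeric(tot[keep])
  }
  sign_ <- ifelse(centres$strand == "+", 1L, -1L)
  vals <- vapply(offs, function(o) {
    key <- paste(centres$contig, centres$strand, centres$centre + sign_ * o)
    cnt <- lookup[key]
    cnt[is.na(cnt)] <- 0
    sum(cnt * wt) / nrow(centres)
  }, numeric(1))
  out <- data.frame(offset = offs, value = vals)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Signal density over scaled 5'UTR/CDS/3'UTR metatranscript regions
#'
#' Each region of each transcript carrying all three regions is rescaled to
#' `bins_per_region` bins; event counts are accumulated into the bins and the
#' whole profile is normalised to sum to one.
#'
#' @param track a [crosslink_track()].
#' @param annotation a `transcript_annotation`.
#' @param bins_per_region bins per region (default 50).
#' @return data.frame with `region`, `bin` (1-based within region), and
#'   `density`.
#' @export
scaled_region_density <- function(track, annotation, bins_per_region = 50) {
  df <- as.data.frame(annotation)
  complete <- names(which(table(unique(df[, c("transcript", "region")])$transcript) == 3L))
  df <- df[df$transcript %in% complete & df$end > df$start, , drop = FALSE]
  regions <- c("5UTR", "CDS", "3UTR")
  dens <- matrix(0, nrow = 3, ncol = bins_per_region,
                 dimnames = list(regions, NULL))
  ev <- track$events
  hits <- overlap_hits(
    data.frame(contig = ev$contig, pos = ev$pos, strand = ev$strand), df)
  if (nrow(hits)) {
    for (h in seq_len(nrow(hits))) {
      e <- ev[hits$pos_idx[h], ]; r <- df[hits$iv_idx[h], ]
      tx <- genomic_to_tx(e$pos, r$start, r$end, r$strand)
      b <- min(bins_per_region,
               floor(tx / (r$end - r$start) * bins_per_region) + 1L)
      dens[r$region, b] <- dens[r$region, b] + e$count
    }
  }
  total <- sum(dens)
  if (total > 0) dens <- dens / total
  data.frame(region = rep(regions, each = bins_per_region),
             bin = rep(seq_len(bins_per_region), times = 3),
             density = as.vector(t(dens)))
}

#' Substitution-rate profiles around motif centres (CIMS-style)
#'
#' For each substitution type, the per-offset rate is the number of
#' substitutions of that type divided by the read depth at the offset,
#' averaged over motif sites (offsets without a record contribute rate 0).
#'
#' @param substitutions data.frame with `contig`, `pos`, `strand`, `from`,
#'   `to`, `sub_count`, `depth`.
#' @param motif_sites data.frame with `contig`, `centre`, `strand`.
#' @param types subset of `"C>T"`, `"T>A"`, `"A>T"`.
#' @param flank window half-width in nt.
#' @return data.frame with `type`, `offset`, `rate`.
#' @export
cims_profile <- function(substitutions, motif_sites,
                         types = c("C>T", "T>A", "A>T"), flank = 10) {
  allowed <- c("C>T", "T>A", "A>T")
  if (!all(types %in% allowed)) {
    stop("substitution type must be one of ", paste(allowed, collapse = ", "))
  }
  offs <- -flank:flank
  sub_type <- paste0(substitutions$from, ">", substitutions$to)
  out <- list()
  sign_ <- ifelse(motif_sites$strand == "+", 1L, -1L)
  for (ty in types) {
    rec <- substitutions[sub_type == ty, , drop = FALSE]
    lookup <- stats::setNames(
      ifelse(rec$depth > 0, rec$sub_count / rec$depth, 0),
      paste(rec$contig, rec$strand, rec$pos))
    rate <- vapply(offs, function(o) {
      key <- paste(motif_sites$contig, motif_sites$strand,
                   motif_sites$centre + sign_ * o)
      r <- lookup[key]
      r[is.na(r)] <- 0
      mean(r)
    }, numeric(1))
    out[[ty]] <- data.frame(type = ty, offset = offs, rate = rate)
  }
  do.call(rbind, out)
}
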