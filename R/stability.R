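# Half-life distribution comparisons: two-sample KS tests, distance-binned
# KS statistics versus a no-signal reference, and module/half-life-bin/
# cluster flow tables.

#' Two-sample two-sided Kolmogorov-Smirnov comparison
#'
#' @param half_lives_a,half_lives_b numeric vectors (hours).
#' @param label_a,label_b group labels.
#' @return One-row data.frame: labels, sizes, `D`, `p`, and `small_n`
#'   (flagged when either group has fewer than 5 values).
#' @export
ks_compare <- function(half_lives_a, half_lives_b,
                       label_a = "A", label_b = "B") {
  if (length(half_lives_a) == 0L || length(half_lives_b) == 0L) {
    stop("both groups must be non-empty")
  }
  kt <- suppressWarnings(
    stats::ks.test(half_lives_a, half_lives_b, alternative = "two.sided"))
  data.frame(group_a = label_a, group_b = label_b,
             n_a = length(half_lives_a), n_b = length(half_lives_b),
             D = unname(kt$statistic), p = kt$p.value,
             small_n = length(half_lives_a) < 5L || length(half_lives_b) < 5L)
}

#' Distance-binned KS statistics for RRACH sites versus a no-site reference
#'
#' Transcripts carrying called m6A sites at RRACH motifs are assigned to
#' distance bins by their smallest RRACH-to-nearest-ARE distance; each bin's
#' half-life distribution is compared with the reference group (transcripts
#' without called sites) by a two-sided KS test. Both disjoint shells
#' (smallest containing window) and cumulative windows are reported, plus a
#' "no ARE within the largest window" bin.
#'
#' @param site_distances data.frame with `transcript` and `distance`
#'   (absolute nt distance from a called RRACH site to its nearest ARE
#'   centre; `NA`/`Inf` when no ARE exists within reach).
#' @param half_lives named numeric vector (names = transcript ids).
#' @param reference_transcripts character vector of no-signal transcripts.
#' @param windows increasing window edges (default c(3, 5, 15, 25, 50)).
#' @return data.frame with `framing` ("shell"/"cumulative"), `bin`, `n`,
#'   `D`, `p` (NA for empty bins), and the reference size.
#' @export
distance_binned_ks <- function(site_distances, half_lives,
                               reference_transcripts,
                               windows = c(3, 5, 15, 25, 50)) {
  ref <- half_lives[names(half_lives) %in% reference_transcripts]
  ref <- ref[!is.na(ref)]
  if (length(ref) == 0L) stop("reference group has no half-lives")
  dmin <- tapply(site_distances$distance, site_distances$transcript,
                 function(d) if (all(is.na(d))) Inf else min(d, na.rm = TRUE))
  dmin <- dmin[names(dmin) %in% names(half_lives)]
  th <- half_lives[names(dmin)]
  ok <- !is.na(th)
  dmin <- dmin[ok]; th <- th[ok]
  wmax <- max(windows)
  rows <- list()
  add <- function(framing, bin, values) {
    if (length(values) == 0L) {
      rows[[length(rows) + 1L]] <<- data.frame(
        framing = framing, bin = bin, n = 0L, D = NA_real_, p = NA_real_,
        n_ref = length(ref))
    } else {
      kc <- ks_compare(values, ref)
      rows[[length(rows) + 1L]] <<- data.frame(
        framing = framing, bin = bin, n = length(values), D = kc$D, p = kc$p,
        n_ref = length(ref))
    }
  }
  lo <- c(-1, windows[-length(windows)])
  for (i in seq_along(windows)) {
    add("shell", sprintf("(%d,%d]", max(lo[i], 0), windows[i]),
        th[dmin > lo[i] & dmin <= windows[i]])
    add("cumulative", sprintf("<=%d", windows[i]), th[dmin <= windows[i]])
  }
  add("shell", sprintf("no ARE within %d", wmax), th[dmin > wmax])
  add("cumulative", sprintf("no ARE within %d", wmax), th[dmin > wmax])
  do.call(rbind, rows)
}

#' Three-way module x half-life-bin x cluster flow table
#'
#' @param modules named character vector (transcript -> gene module A-G).
#' @param halflife_bins named factor/character (transcript -> half-life
#'   category).
#' @param cluster_labels named character vector (transcript -> cluster).
#' @return list: `flows` data.frame (`module`, `bin`, `cluster`, `count`)
#'   covering transcripts present in all three labellings, and `n_excluded`.
#' @export
flow_table <- function(modules, halflife_bins, cluster_labels) {
  common <- Reduce(intersect, list(names(modules), names(halflife_bins),
                                   names(cluster_labels)))
  n_excluded <- length(unique(c(names(modules), names(halflife_bins),
                                names(cluster_labels)))) - length(common)
  tab <- table(module = as.character(modules[common]),
               bin = as.character(halflife_bins[common]),
               cluster = as.character(cluster_labels[common]))
  flows <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(flows)[4] <- "count"
  flows <- flows[flows$count > 0, , drop = FALSE]
  rownames(flows) <- NULL
  list(flows = flows, n = length(common), n_excluded = n_excluded)
}
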