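# Conversion-based m6A site calling from deamination pileups and
# treatment-versus-control metagenes around motif centres.
#
# Chemistry read-out: unmethylated adenosines are deaminated and sequenced as
# G, so the unconverted fraction A/(A+G) on the forward strand (T/(T+C) on
# the reverse strand, in plus-strand base space) estimates the methylation
# level at each adenosine.

#' Conversion ratios for a pileup table
#'
#' The relevant depth is A+G on the forward strand and T+C on the reverse
#' strand; the conversion ratio is A/(A+G) and T/(T+C) respectively. Rows
#' whose reference base is not A (forward) or T (reverse, plus-strand space)
#' are rejected; rows with zero relevant depth are flagged undefined.
#'
#' @param pileup data.frame from [load_pileup()].
#' @param sequences optional named character vector of contig sequences used
#'   to check the reference base; omit to skip the check.
#' @return The pileup with `depth_rel`, `ratio` and `defined` columns;
#'   rejected rows are dropped and their number reported as attribute
#'   `n_rejected`.
#' @export
conversion_ratio <- function(pileup, sequences = NULL) {
  df <- pileup
  fwd <- df$strand == "+"
  n_rejected <- 0L
  if (!is.null(sequences)) {
    ref <- substr(vapply(df$contig, function(ct) sequences[[ct]], character(1)),
                  df$pos + 1L, df$pos + 1L)
    ok <- (fwd & ref == "A") | (!fwd & ref == "T")
    n_rejected <- sum(!ok)
    df <- df[ok, , drop = FALSE]
    fwd <- df$strand == "+"
  }
  df$depth_rel <- ifelse(fwd, df$countA + df$countG, df$countT + df$countC)
  df$ratio <- ifelse(df$depth_rel > 0,
                     ifelse(fwd, df$countA, df$countT) / df$depth_rel,
                     NA_real_)
  df$defined <- df$depth_rel > 0
  attr(df, "n_rejected") <- n_rejected
  df
}

#' Call m6A sites from conversion ratios
#'
#' A position is called when its relevant read depth is at least `min_depth`
#' and its conversion ratio at least `min_ratio`; both thresholds are
#' inclusive. Undefined ratios are never called.
#'
#' @param ratio_table output of [conversion_ratio()].
#' @param min_depth inclusive depth threshold (default 15).
#' @param min_ratio inclusive ratio threshold (default 0.1).
#' @return The called rows.
#' @export
call_glori_sites <- function(ratio_table, min_depth = 15, min_ratio = 0.1) {
  keep <- ratio_table$defined &
    ratio_table$depth_rel >= min_depth &
    ratio_table$ratio >= min_ratio
  ratio_table[keep, , drop = FALSE]
}

#' Annotate called m6A sites with motif and region context
#'
#' Sites farther than `max_gene_dist` from any annotated gene are dropped.
#' The motif annotation is taken from the transcript-orientation local
#' sequence: GAC when the site's A is the A of a GAC trinucleotide, GAAC when
#' it is the second A of GAAC, `other` otherwise. The region class is
#' assigned with priority 3UTR > CDS > 5UTR on overlap ties. Duplicate
#' (contig, position, strand) records collapse to one via a unique position
#' id.
#'
#' @param sites called rows from [call_glori_sites()].
#' @param annotation a `transcript_annotation`.
#' @param sequences named character vector of contig sequences.
#' @param max_gene_dist maximum distance to a gene in nt (default 2000).
#' @return Annotated sites with `position_id`, `motif`, `region_class`,
#'   `transcript`; attribute `n_dropped` counts sites outside gene
#'   neighbourhoods or on unannotated contigs.
#' @export
annotate_glori_sites <- function(sites, annotation, sequences,
                                 max_gene_dist = 2000) {
  df <- as.data.frame(annotation)
  genes <- do.call(rbind, lapply(split(df, df$gene), function(g) {
    data.frame(gene = g$gene[1], contig = g$contig[1],
               start = min(g$start), end = max(g$end), strand = g$strand[1])
  }))
  gene_win <- transform(genes, start = pmax(0L, start - max_gene_dist),
                        end = end + max_gene_dist)
  hits <- overlap_hits(sites, gene_win)
  keep <- sort(unique(hits$pos_idx))
  n_dropped <- nrow(sites) - length(keep)
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) == 0L) {
    sites$position_id <- character(0)
    sites$motif <- character(0)
    sites$region_class <- character(0)
    sites$transcript <- character(0)
    attr(sites, "n_dropped") <- n_dropped
    return(sites)
  }

  sites$position_id <- paste0(sites$contig, ":", sites$pos, ":", sites$strand)
  dup <- duplicated(sites$position_id)
  sites <- sites[!dup, , drop = FALSE]

  sites$motif <- vapply(seq_len(nrow(sites)), function(i) {
    ctg <- sites$contig[i]; p <- sites$pos[i]; st <- sites$strand[i]
    seq <- sequences[[ctg]]
    if (is.null(seq)) return("other")
    pb <- p + 1L                      # 1-based position of the site base
    lo <- max(1L, pb - 3L); hi <- min(nchar(seq), pb + 3L)
    win <- substr(seq, lo, hi)
    off <- pb - lo + 1L               # 1-based offset of the site within win
    if (st == "-") {
      win <- revcomp(win)
      off <- nchar(win) - off + 1L
    }
    # site base must be the A of GAC / the second A of GAAC
    if (off >= 2L && substr(win, off - 1L, off + 1L) == "GAC") return("GAC")
    if (off >= 3L && substr(win, off - 2L, off + 1L) == "GAAC") return("GAAC")
    "other"
  }, character(1))

  region_of <- rep("other", nrow(sites))
  for (rg in c("5UTR", "CDS", "3UTR")) {  # later assignments win: 3UTR top
    iv <- df[df$region == rg, , drop = FALSE]
    h <- overlap_hits(sites, iv)
    region_of[unique(h$pos_idx)] <- rg
  }
  sites$region_class <- region_of

  tx <- rep(NA_character_, nrow(sites))
  utr <- annotation_regions(annotation, "3UTR")
  h <- overlap_hits(sites, utr)
  tx[h$pos_idx] <- utr$transcript[h$iv_idx]
  gb <- df  # fall back to any region of the transcript
  h2 <- overlap_hits(sites, gb)
  fill <- is.na(tx)
  tx[h2$pos_idx[fill[h2$pos_idx]]] <- gb$transcript[h2$iv_idx[fill[h2$pos_idx]]]
  sites$transcript <- tx

  attr(sites, "n_dropped") <- n_dropped
  sites
}

#' m6A-count metagene around motif centres, per condition
#'
#' The "m6A count" at a called site is its unconverted-read count (A on the
#' forward strand, T on the reverse strand); set `use_ratio = TRUE` to
#' profile the conversion ratio instead. Profiles average across replicates
#' first, then across sites, at transcript-orientation offsets
#' -`flank`..+`flank`.
#'
#' @param sites annotated called sites with a `condition` column (and
#'   optionally `replicate`).
#' @param centres data.frame with `contig`, `centre`, `strand`.
#' @param flank window half-width (>= 4).
#' @param conditions conditions to profile; default all present.
#' @param use_ratio profile conversion ratio instead of counts.
#' @return data.frame with `condition`, `offset`, `value`.
#' @export
glori_metagene <- function(sites, centres, flank = 10, conditions = NULL,
                           use_ratio = FALSE) {
  stopifnot(flank >= 4)
  have <- unique(sites$condition)
  if (is.null(conditions)) conditions <- have
  if (!all(conditions %in% have)) {
    stop("condition(s) absent: ",
         paste(setdiff(conditions, have), collapse = ", "),
         "; available: ", paste(have, collapse = ", "))
  }
  if (is.null(sites$replicate)) sites$replicate <- 1L
  fwd <- sites$strand == "+"
  sites$m6a_value <- if (use_ratio) sites$ratio else
    ifelse(fwd, sites$countA, sites$countT)
  offs <- -flank:flank
  sign_ <- ifelse(centres$strand == "+", 1L, -1L)
  out <- list()
  for (cond in conditions) {
    sc <- sites[sites$condition == cond, , drop = FALSE]
    # average across replicates at each position first
    agg <- stats::aggregate(m6a_value ~ contig + pos + strand, data = sc, FUN = mean)
    lookup <- stats::setNames(agg$m6a_value,
                              paste(agg$contig, agg$strand, agg$pos))
    vals <- vapply(offs, function(o) {
      key <- paste(centres$contig, centres$strand, centres$centre + sign_ * o)
      v <- lookup[key]
      v[is.na(v)] <- 0
      mean(v)
    }, numeric(1))
    out[[cond]] <- data.frame(condition = cond, offset = offs, value = vals)
  }
  do.call(rbind, out)
}

#' Fraction of called m6A counts within a window of reference sites
#'
#' Computed exactly as (m6A counts at positions within +/-`window` nt of any
#' reference centre) / (all m6A counts).
#'
#' @param sites annotated called sites (with counts).
#' @param ref_centres data.frame with `contig`, `centre`, `strand`.
#' @param window half-width in nt (default 4).
#' @return Numeric fraction in [0, 1].
#' @export
fraction_near_sites <- function(sites, ref_centres, window = 4) {
  fwd <- sites$strand == "+"
  counts <- ifelse(fwd, sites$countA, sites$countT)
  total <- sum(counts)
  if (total == 0) return(0)
  win <- data.frame(contig = ref_centres$contig,
                    start = ref_centres$centre - window,
                    end = ref_centres$centre + window + 1L,
                    strand = ref_centres$strand)
  hits <- overlap_hits(sites, win)
  sum(counts[unique(hits$pos_idx)]) / total
}
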