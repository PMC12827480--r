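#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile median var sd setNames aggregate ks.test
#'   rbinom rpois rnorm runif rlnorm complete.cases predict cor dist hclust
#'   cutree model.matrix coef fitted resid lm chisq.test
#' @importFrom utils read.table write.table head tail
NULL

# Internal: strand-aware transcript-orientation helpers. All genomic
# coordinates are 0-based half-open; a "position" is the 0-based offset of a
# single base.

tx_to_genomic <- function(offset, start, end, strand) {
  n <- max(length(offset), length(start), length(end), length(strand))
  offset <- rep_len(as.integer(offset), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  plus <- rep_len(strand == "+", n)
  out <- integer(n)
  out[plus] <- start[plus] + offset[plus]
  out[!plus] <- end[!plus] - 1L - offset[!plus]
  out
}

genomic_to_tx <- function(pos, start, end, strand) {
  n <- max(length(pos), length(start), length(end), length(strand))
  pos <- rep_len(as.integer(pos), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  plus <- rep_len(strand == "+", n)
  out <- integer(n)
  out[plus] <- pos[plus] - start[plus]
  out[!plus] <- end[!plus] - 1L - pos[!plus]
  out
}

# Interval overlap via IRanges; df columns start/end are 0-based half-open.
overlap_hits <- function(pos_df, iv_df) {
  if (nrow(pos_df) == 0L || nrow(iv_df) == 0L) {
    return(data.frame(pos_idx = integer(0), iv_idx = integer(0)))
  }
  key_p <- paste(pos_df$contig, pos_df$strand)
  key_i <- paste(iv_df$contig, iv_df$strand)
  out_p <- integer(0); out_i <- integer(0)
  for (k in unique(key_p)) {
    pi <- which(key_p == k); ii <- which(key_i == k)
    if (length(ii) == 0L) next
    q <- IRanges::IRanges(start = pos_df$pos[pi] + 1L, width = 1L)
    s <- IRanges::IRanges(start = iv_df$start[ii] + 1L, end = iv_df$end[ii])
    h <- IRanges::findOverlaps(q, s)
    out_p <- c(out_p, pi[S4Vectors::queryHits(h)])
    out_i <- c(out_i, ii[S4Vectors::subjectHits(h)])
  }
  data.frame(pos_idx = out_p, iv_idx = out_i)
}

# Moving mean over a window of `s` consecutive values (even windows allowed;
# the window is anchored as in stats::filter, sides = 2). Edges keep the raw
# value where the window does not fit.
moving_mean <- function(x, s) {
  if (s <= 1L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / s, s), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

# Deterministic child seeds below 2^31, derived from a master seed.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147480000)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
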