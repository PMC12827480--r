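# Pentamer motif engine: scan sequences for the three motif classes and call
# composite (ARE-flanking m6A) sites by centre-to-centre proximity.
#
# Classes (DNA alphabet; U mapped to T on input):
#   RRACH  = [AG][AG]AC[ACT]   canonical m6A consensus
#   WWAWW  = [AT][AT]A[AT][AT] AU-rich element pentamer
#   CRACH  = C[AG]AC[ACT]      non-substrate negative-control consensus
# The three classes are pairwise disjoint as string sets: position 4 of
# WWAWW is A/T while RRACH/CRACH fix C there, and position 1 separates
# CRACH (C) from RRACH (A/G).

MOTIF_CLASSES <- list(
  RRACH = list(c("A", "G"), c("A", "G"), "A", "C", c("A", "C", "T")),
  WWAWW = list(c("A", "T"), c("A", "T"), "A", c("A", "T"), c("A", "T")),
  CRACH = list("C", c("A", "G"), "A", "C", c("A", "C", "T"))
)

motif_class_regex <- function(motif_class) {
  spec <- MOTIF_CLASSES[[motif_class]]
  paste0(vapply(spec, function(ch) {
    if (length(ch) == 1L) ch else paste0("[", paste(ch, collapse = ""), "]")
  }, character(1)), collapse = "")
}

normalize_seq <- function(sequence) {
  s <- toupper(sequence)
  s <- gsub("U", "T", s, fixed = TRUE)
  if (grepl("[^ACGTN]", s)) stop("sequence contains characters outside ACGTUN")
  s
}

#' Scan a sequence for all occurrences of a pentamer motif class
#'
#' All overlapping occurrences are reported (the scan window slides by one
#' base). The centre of a site is the offset of its third base, the
#' methylatable 'A' of RRACH/CRACH and the central 'A' of WWAWW. The
#' ambiguity code N never matches.
#'
#' @param sequence character scalar over A/C/G/T/U/N.
#' @param motif_class one of `"RRACH"`, `"WWAWW"`, `"CRACH"`.
#' @param region_id optional identifier recorded with each site.
#' @return data.frame with `motif_class`, `pentamer`, `start` (0-based offset
#'   of the first base), `centre` (0-based offset of the third base), and
#'   `region_id`, ordered by position.
#' @export
scan_pentamers <- function(sequence, motif_class, region_id = NA_character_) {
  if (!motif_class %in% names(MOTIF_CLASSES)) {
    stop("unknown motif class: ", motif_class,
         " (expected RRACH, WWAWW or CRACH)")
  }
  s <- normalize_seq(sequence)
  n <- nchar(s)
  empty <- data.frame(motif_class = character(0), pentamer = character(0),
                      start = integer(0), centre = integer(0),
                      region_id = character(0))
  if (n < 5L) return(empty)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  spec <- MOTIF_CLASSES[[motif_class]]
  ok <- rep(TRUE, n - 4L)
  for (j in 1:5) {
    ok <- ok & chars[seq.int(j, n - 5L + j)] %in% spec[[j]]
  }
  starts <- which(ok) - 1L
  if (length(starts) == 0L) return(empty)
  data.frame(motif_class = motif_class,
             pentamer = substring(s, starts + 1L, starts + 5L),
             start = starts, centre = starts + 2L,
             region_id = region_id)
}

#' Count motif occurrences and per-kilobase density in a sequence
#'
#' @inheritParams scan_pentamers
#' @return list with `count` and `per_kb` (count / (length/1000)).
#' @export
motif_frequency <- function(utr_sequence, motif_class) {
  if (is.na(utr_sequence) || nchar(utr_sequence) == 0L) {
    stop("motif_frequency: empty sequence")
  }
  n <- nrow(scan_pentamers(utr_sequence, motif_class))
  list(count = n, per_kb = n / (nchar(utr_sequence) / 1000))
}

#' Call composite (ARE-flanking m6A) sites by motif proximity
#'
#' Each ARE (WWAWW) site is paired with its nearest RRACH site by
#' centre-to-centre distance between the methylatable 'A' positions, signed
#' in transcript orientation (positive = RRACH downstream of the ARE). Ties
#' in |distance| are broken in favour of the downstream (+) partner. An ARE
#' is labelled `composite` when a RRACH centre lies within `window_nt` of its
#' centre, `isolated` otherwise.
#'
#' @param are_sites,rrach_sites data.frames from [scan_pentamers()] (same
#'   region, transcript-orientation coordinates). A `strand` column, if
#'   present, must be constant across both inputs.
#' @param window_nt composite-calling window in nt (the analyses use
#'   3, 5, 15, 25 and 50).
#' @return data.frame with `are_centre`, `rrach_centre` (NA if no RRACH),
#'   `distance`, `label`, `window`.
#' @export
call_composites <- function(are_sites, rrach_sites, window_nt = 50) {
  strands <- c(are_sites$strand, rrach_sites$strand)
  if (!is.null(strands) && length(unique(strands)) > 1L) {
    stop("call_composites: mixed-strand input")
  }
  if (nrow(are_sites) == 0L) {
    return(data.frame(are_centre = integer(0), rrach_centre = integer(0),
                      distance = integer(0), label = character(0),
                      window = integer(0)))
  }
  rc <- rrach_sites$centre
  res <- lapply(are_sites$centre, function(ac) {
    if (length(rc) == 0L) {
      return(data.frame(are_centre = ac, rrach_centre = NA_integer_,
                        distance = NA_integer_, label = "isolated",
                        window = window_nt))
    }
    d <- rc - ac
    o <- order(abs(d), -sign(d))  # nearest first; ties favour downstream
    best <- d[o[1]]
    lab <- if (abs(best) <= window_nt) "composite" else "isolated"
    data.frame(are_centre = ac, rrach_centre = ac + best, distance = best,
               label = lab, window = window_nt)
  })
  do.call(rbind, res)
}

#' Sample number-matched control motif sites from 3'UTRs
#'
#' Draws `n` motif occurrences uniformly without replacement from the pool of
#' all occurrences of the class across the 3'UTRs of the annotation,
#' reproducibly under `seed`.
#'
#' @param annotation a `transcript_annotation`.
#' @param sequences named character vector of contig sequences.
#' @param motif_class motif class to sample.
#' @param n number of control sites.
#' @param seed integer seed.
#' @return data.frame of sites in genomic coordinates: `contig`, `centre`
#'   (0-based genomic offset of the central base), `strand`, `transcript`,
#'   `pentamer`.
#' @export
sample_control_sites <- function(annotation, sequences, motif_class, n, seed) {
  pool <- motif_sites_in_3utrs(annotation, sequences, motif_class)
  if (n > nrow(pool)) {
    stop("requested ", n, " control sites but the 3'UTR pool holds only ",
         nrow(pool))
  }
  set.seed(seed)
  pool[sort(sample.int(nrow(pool), n)), , drop = FALSE]
}

#' Locate all 3'UTR occurrences of a motif class in genomic coordinates
#'
#' Scans each annotated 3'UTR in transcript orientation and maps the site
#' centres back to genomic positions.
#'
#' @inheritParams sample_control_sites
#' @return data.frame with `contig`, `centre`, `strand`, `transcript`,
#'   `pentamer`, `tx_centre` (offset within the 3'UTR).
#' @export
motif_sites_in_3utrs <- function(annotation, sequences, motif_class) {
  utrs <- annotation_regions(annotation, "3UTR")
  out <- vector("list", nrow(utrs))
  for (i in seq_len(nrow(utrs))) {
    u <- utrs[i, ]
    seq_tx <- interval_sequence(sequences, u$contig, u$start, u$end, u$strand)
    hits <- scan_pentamers(seq_tx, motif_class, region_id = u$transcript)
    if (nrow(hits) == 0L) next
    out[[i]] <- data.frame(
      contig = u$contig,
      centre = tx_to_genomic(hits$centre, u$start, u$end, u$strand),
      strand = u$strand, transcript = u$transcript,
      pentamer = hits$pentamer, tx_centre = hits$centre)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(contig = character(0), centre = integer(0),
                      strand = character(0), transcript = character(0),
                      pentamer = character(0), tx_centre = integer(0)))
  }
  do.call(rbind, out)
}
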