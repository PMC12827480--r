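# Readers/writers for the plain-text formats the pipeline exchanges, plus the
# shared coordinate convention.
#
# Conventions used throughout the package:
#   * genomic intervals are 0-based, half-open [start, end), strand "+"/"-"
#     (BED-native); readers for 1-based dialects convert at the boundary;
#   * sequences are DNA internally; "U" on input is mapped to "T";
#   * a crosslink position is a single base: for a +-strand read it is the
#     read start minus one, for a --strand read the base just past the read
#     end, i.e. the nucleotide 5' of the cDNA in transcript orientation.

#' Construct a crosslink track
#'
#' A crosslink track holds strand-aware per-position event counts (crosslink
#' events or read starts) together with the sample identity and its role in
#' the experimental design.
#'
#' @param events data.frame with columns `contig`, `pos` (0-based base
#'   offset), `strand` ("+"/"-"), `count` (positive integer).
#' @param sample_id character scalar.
#' @param role one of `"miCLIP"`, `"input"`, `"noUV"`.
#' @return An object of class `crosslink_track`.
#' @export
crosslink_track <- function(events, sample_id = "sample", role = "miCLIP") {
  role <- match.arg(role, c("miCLIP", "input", "noUV"))
  events <- as.data.frame(events)
  need <- c("contig", "pos", "strand", "count")
  if (!all(need %in% names(events))) {
    stop("events must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(events) > 0) {
    if (any(events$count <= 0)) stop("crosslink counts must be positive")
    if (!all(events$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  events$contig <- as.character(events$contig)
  events$pos <- as.integer(events$pos)
  events$count <- as.integer(events$count)
  structure(
    list(events = events, total = sum(events$count),
         sample_id = sample_id, role = role),
    class = "crosslink_track"
  )
}

#' @export
print.crosslink_track <- function(x, ...) {
  cat(sprintf("crosslink_track '%s' (%s): %d positions, %d events\n",
              x$sample_id, x$role, nrow(x$events), x$total))
  invisible(x)
}

#' Read a crosslink track from a BED6 file
#'
#' One record per crosslink position; the BED score column carries the event
#' count. Records must be single-base (`end == start + 1`).
#'
#' @param path BED6 file.
#' @inheritParams crosslink_track
#' @return A [crosslink_track()].
#' @export
load_crosslink_bed <- function(path, sample_id = basename(path), role = "miCLIP") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(crosslink_track(
      data.frame(contig = character(0), pos = integer(0),
                 strand = character(0), count = integer(0)),
      sample_id = sample_id, role = role))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("malformed BED line ", which(nf < 6L)[1], ": expected 6 fields")
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  count <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | is.na(count))
  if (length(bad)) stop("malformed BED line ", bad[1], ": non-numeric field")
  if (any(end != start + 1L)) {
    stop("crosslink BED records must be single-base (end == start + 1)")
  }
  if (any(count <= 0)) stop("crosslink BED counts must be positive")
  crosslink_track(
    data.frame(contig = m[, 1], pos = start, strand = m[, 6],
               count = as.integer(count)),
    sample_id = sample_id, role = role)
}

#' Write a crosslink track as BED6
#'
#' @param track a [crosslink_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_crosslink_bed <- function(track, path) {
  ev <- track$events
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   ev$contig, ev$pos, ev$pos + 1L, track$sample_id,
                   ev$count, ev$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write genomic intervals as BED6
#'
#' @param iv data.frame with `contig`, `start`, `end`, `strand` and optional
#'   `name`, `score` columns (0-based half-open).
#' @param path output file.
#' @export
write_bed <- function(iv, path) {
  name <- if ("name" %in% names(iv)) iv$name else "."
  score <- if ("score" %in% names(iv)) iv$score else 0
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", iv$contig, iv$start, iv$end,
                     name, score, iv$strand), path)
  invisible(path)
}

#' Read a BED6 file of intervals
#'
#' @param path BED6 file.
#' @return data.frame with `contig`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open).
#' @export
load_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  }
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(contig = m[, 1], start = as.integer(m[, 2]),
             end = as.integer(m[, 3]), name = m[, 4],
             score = as.numeric(m[, 5]), strand = m[, 6])
}

#' Read a transcript annotation table
#'
#' The annotation is a TSV with one row per transcript region:
#' `gene`, `transcript`, `region` (5UTR/CDS/3UTR), `contig`, `start`, `end`
#' (0-based half-open), `strand`, and optional `module` (A-G or "none").
#' For a minus-strand transcript the 3'UTR is the leftmost genomic block.
#'
#' @param path TSV file.
#' @return A `transcript_annotation`: the region table with per-transcript
#'   strand consistency enforced; transcripts lacking a 3'UTR are kept but
#'   flagged (and excluded from 3'UTR analyses downstream).
#' @export
load_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_annotation(df)
}

#' Validate an in-memory annotation table
#'
#' @param df data.frame as described in [load_annotation()].
#' @return The validated `transcript_annotation` object.
#' @export
as_annotation <- function(df) {
  need <- c("gene", "transcript", "region", "contig", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (!"module" %in% names(df)) df$module <- "none"
  if (!all(df$region %in% c("5UTR", "CDS", "3UTR"))) {
    stop("region must be one of 5UTR, CDS, 3UTR")
  }
  for (tx in unique(df$transcript)) {
    rows <- df[df$transcript == tx, ]
    if (length(unique(rows$strand)) != 1L) {
      stop("transcript ", tx, " has inconsistent strands")
    }
    if (anyDuplicated(rows$region)) {
      stop("transcript ", tx, " has duplicated region tags")
    }
    o <- order(rows$start)
    s <- rows$start[o]; e <- rows$end[o]
    if (any(s[-1] < e[-length(e)])) {
      stop("transcript ", tx, " has overlapping regions")
    }
  }
  no3 <- setdiff(unique(df$transcript),
                 unique(df$transcript[df$region == "3UTR"]))
  if (length(no3)) {
    warning(length(no3), " transcript(s) lack a 3'UTR and are excluded from ",
            "3'UTR analyses")
  }
  structure(df, class = c("transcript_annotation", "data.frame"))
}

#' Write a transcript annotation table
#'
#' @param annotation a `transcript_annotation`.
#' @param path output TSV.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the regions of one class from an annotation
#'
#' @param annotation a `transcript_annotation`.
#' @param region region tag, default `"3UTR"`.
#' @return data.frame of intervals (one per transcript having the region).
#' @export
annotation_regions <- function(annotation, region = "3UTR") {
  df <- as.data.frame(annotation)
  df[df$region == region, , drop = FALSE]
}

#' Read a strand-specific base-count pileup
#'
#' TSV with columns `contig`, `pos` (1-based in the file, converted to
#' 0-based on load), `strand`, `countA`, `countC`, `countG`, `countT`.
#' Rows are keyed by (contig, pos, strand); the two strands at one position
#' are distinct records.
#'
#' @param path TSV file.
#' @return data.frame with the counts, 0-based `pos`, and `depth` (sum of the
#'   four counts).
#' @export
load_pileup <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("contig", "pos", "strand", "countA", "countC", "countG", "countT")
  if (!all(need %in% names(df))) {
    stop("pileup must have columns: ", paste(need, collapse = ", "))
  }
  cnt <- df[, c("countA", "countC", "countG", "countT")]
  if (any(as.matrix(cnt) < 0)) stop("pileup counts must be non-negative")
  df$pos <- as.integer(df$pos) - 1L  # 1-based file dialect -> 0-based
  key <- paste(df$contig, df$pos, df$strand)
  if (anyDuplicated(key)) {
    stop("duplicate pileup key: ", key[anyDuplicated(key)])
  }
  df$depth <- df$countA + df$countC + df$countG + df$countT
  df
}

#' Write a pileup table (1-based file dialect)
#'
#' @param pileup data.frame as returned by [load_pileup()] (0-based `pos`).
#' @param path output TSV.
#' @export
write_pileup <- function(pileup, path) {
  out <- pileup[, c("contig", "pos", "strand",
                    "countA", "countC", "countG", "countT")]
  out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' RNA alphabet is accepted; U is mapped to T.
#'
#' @param path FASTA file.
#' @return Named character vector of DNA sequences.
#' @export
load_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Extract transcript-orientation sequence of an interval
#'
#' @param seqs named character vector of contig sequences.
#' @param contig,start,end,strand interval (0-based half-open).
#' @return Character scalar in transcript orientation (reverse-complemented
#'   for minus-strand intervals).
#' @export
interval_sequence <- function(seqs, contig, start, end, strand) {
  s <- substr(seqs[[contig]], start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}
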