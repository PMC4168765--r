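#' Measure an oligo(dA) tail
#'
#' Length of the maximal A-rich suffix: the longest suffix beginning with
#' `A` that contains at most `max_interruptions` non-`A` bases. Suffixes
#' shorter than `min_run` report 0.
#'
#' @param x DNA string or [seq_record] (an insert, or an EST read).
#' @param min_run Minimum qualifying length (default 8).
#' @param max_interruptions Maximum interruptions inside the run (default
#'   1).
#' @return Integer tail length (0 when no qualifying tail).
#' @export
measure_polya_tail <- function(x, min_run = 8L, max_interruptions = 1L) {
  if (inherits(x, "seq_record")) x <- x$residues
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n == 0) return(0L)
  nonA <- rev(cumsum(rev(ch != "A"))) # non-A count in suffix starting at i
  ok <- which(nonA <= max_interruptions & ch == "A")
  if (length(ok) == 0) return(0L)
  len <- n - min(ok) + 1L
  if (len >= min_run) as.integer(len) else 0L
}

#' Detect a target-site duplication around an insert
#'
#' Retrotransposon insertion duplicates a short stretch of the target so
#' that one copy ends immediately 5' of the insert and the other begins
#' immediately 3' of it. The longest direct repeat (within the configured
#' length bounds) with at most `max_mismatch` mismatches is reported;
#' absence is a null call with `found = FALSE`, not an error.
#'
#' @param host DNA string or [seq_record] containing the insert.
#' @param insert_interval `c(start, end)`: 1-based insert interval,
#'   strictly inside the host.
#' @param min_len,max_len TSD length bounds (defaults 5 and 25 — the
#'   typical retrotransposition range).
#' @param max_mismatch Maximum mismatches between the two copies (default
#'   1).
#' @return A list with `found`, `tsd_length`, `tsd_sequence` (the 5'
#'   copy), `tsd_mismatches`.
#' @export
detect_tsd <- function(host, insert_interval, min_len = 5L, max_len = 25L,
                       max_mismatch = 1L) {
  if (inherits(host, "seq_record")) host <- host$residues
  host <- toupper(host)
  s <- insert_interval[1]; e <- insert_interval[2]
  n <- nchar(host)
  if (s <= 1 || e >= n || s > e)
    stop("insert interval must lie strictly inside the host sequence")
  top <- min(max_len, s - 1, n - e)
  for (L in (if (top >= min_len) seq(top, min_len) else integer(0))) {
    left <- substr(host, s - L, s - 1)
    right <- substr(host, e + 1, e + L)
    mm <- sum(strsplit(left, "")[[1]] != strsplit(right, "")[[1]])
    if (mm <= max_mismatch)
      return(list(found = TRUE, tsd_length = as.integer(L),
                  tsd_sequence = left, tsd_mismatches = as.integer(mm)))
  }
  list(found = FALSE, tsd_length = 0L, tsd_sequence = "",
       tsd_mismatches = NA_integer_)
}

#' Compare an insert against a repeat consensus
#'
#' Global free-end-gaps alignment of the insert against the consensus,
#' followed by substitution-spectrum counting. Because the oligo(dA) tail
#' and flanking TSD copies are not part of the consensus, the spectrum is
#' reported both over the full alignment and restricted to the
#' consensus-covered span (columns between the first and last non-gap
#' consensus position).
#'
#' @param insert DNA string or [seq_record].
#' @param consensus A [seq_record] holding the consensus element (e.g. an
#'   AluY consensus).
#' @param params [align_params()] (global mode enforced).
#' @return A list with `alignment`, `spectrum_full`,
#'   `spectrum_consensus_span`, and `consensus_span` (alignment-column
#'   interval).
#' @export
compare_to_consensus <- function(insert, consensus, params = align_params()) {
  if (!inherits(insert, "seq_record"))
    insert <- seq_record("insert", insert, type = "dna")
  stopifnot(inherits(consensus, "seq_record"))
  if (params$mode != "global") params$mode <- "global"
  aln <- align(insert, consensus, params)
  gb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  nong <- which(gb != "-")
  span <- c(min(nong), max(nong))
  list(alignment = aln,
       spectrum_full = substitution_spectrum(aln),
       spectrum_consensus_span = substitution_spectrum(aln, span),
       consensus_span = span)
}

#' Characterize a candidate inserted element
#'
#' Bundles TSD detection, oligo(dA)-tail measurement, the distance from an
#' upstream polyadenylation signal to the 5' TSD copy, and (when a
#' consensus is supplied) the substitution spectrum against it.
#'
#' @param host [seq_record] containing the insert (host coordinates).
#' @param insert_interval `c(start, end)` of the insert on the host.
#' @param consensus Optional consensus [seq_record].
#' @param polya_motifs Motif set scanned upstream of the insert (default
#'   `AATAAA`).
#' @param tsd_min,tsd_max,tsd_max_mismatch TSD search bounds.
#' @param tail_min_run,tail_max_interruptions Oligo(dA) parameters.
#' @param align_params Alignment parameters for the consensus comparison.
#' @return An object of class `insertion_call`.
#' @export
characterize_insertion <- function(host, insert_interval, consensus = NULL,
                                   polya_motifs = "AATAAA",
                                   tsd_min = 5L, tsd_max = 25L,
                                   tsd_max_mismatch = 1L,
                                   tail_min_run = 8L,
                                   tail_max_interruptions = 1L,
                                   align_params = intronret::align_params()) {
  stopifnot(inherits(host, "seq_record"))
  s <- insert_interval[1]; e <- insert_interval[2]
  tsd <- detect_tsd(host, insert_interval, tsd_min, tsd_max, tsd_max_mismatch)
  insert_seq <- substr(host$residues, s, e)
  tail_len <- measure_polya_tail(insert_seq, tail_min_run,
                                 tail_max_interruptions)
  # distance from the nearest upstream signal's hexamer end to the 5' TSD start
  tsd5_start <- s - tsd$tsd_length
  upstream <- substr(host$residues, 1, tsd5_start - 1)
  sig <- find_polya_signals(upstream, polya_motifs)
  signal_to_tsd <- if (nrow(sig) > 0) {
    last <- sig$position[nrow(sig)]
    tsd5_start - (last + 6L)
  } else NA_integer_
  cons <- if (!is.null(consensus))
    compare_to_consensus(seq_record("insert", insert_seq, type = "dna"),
                         consensus, align_params) else NULL
  structure(list(insert_interval = c(s, e), tsd = tsd,
                 polyA_tail_length = tail_len,
                 signal_to_tsd_distance = signal_to_tsd,
                 consensus_comparison = cons),
            class = "insertion_call")
}

#' @export
print.insertion_call <- function(x, ...) {
  cat(sprintf("insertion_call: insert %d-%d (%d nt)\n", x$insert_interval[1],
              x$insert_interval[2],
              x$insert_interval[2] - x$insert_interval[1] + 1))
  if (x$tsd$found)
    cat(sprintf("  TSD %d nt ('%s'), %d mismatch(es)\n", x$tsd$tsd_length,
                x$tsd$tsd_sequence, x$tsd$tsd_mismatches))
  else cat("  no TSD detected\n")
  cat(sprintf("  oligo(dA) tail: %d nt\n", x$polyA_tail_length))
  if (!is.na(x$signal_to_tsd_distance))
    cat(sprintf("  polyA signal to 5' TSD: %d nt\n", x$signal_to_tsd_distance))
  if (!is.null(x$consensus_comparison)) {
    sp <- x$consensus_comparison$spectrum_consensus_span
    cat(sprintf("  vs consensus: %d transitions, %d transversions, %d gap event(s) (%d nt)\n",
                sp$transitions, sp$transversions, sp$gap_events, sp$gap_nt))
  }
  invisible(x)
}

#' Export an insertion call as BED features
#'
#' Insert, the two TSD copies and the oligo(dA) tail as 0-based half-open
#' BED records on the host sequence.
#'
#' @param call An `insertion_call`.
#' @param path Output path.
#' @param chrom_label Sequence name for column 1.
#' @return Invisibly, the BED data frame.
#' @export
export_insertion_bed <- function(call, path, chrom_label = "host") {
  s <- call$insert_interval[1]; e <- call$insert_interval[2]
  rows <- list(data.frame(chrom = chrom_label, start = s - 1L, end = e,
                          name = "insert"))
  if (call$tsd$found) {
    L <- call$tsd$tsd_length
    rows[[length(rows) + 1]] <- data.frame(chrom = chrom_label,
                                           start = s - L - 1L, end = s - 1L,
                                           name = "TSD_5prime")
    rows[[length(rows) + 1]] <- data.frame(chrom = chrom_label,
                                           start = e, end = e + L,
                                           name = "TSD_3prime")
  }
  if (call$polyA_tail_length > 0)
    rows[[length(rows) + 1]] <- data.frame(
      chrom = chrom_label, start = e - call$polyA_tail_length, end = e,
      name = "oligo_dA_tail")
  bed <- do.call(rbind, rows)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(bed)
}
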