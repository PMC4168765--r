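#' Scan a sequence for polyadenylation signals
#'
#' Exact occurrences of the hexamer motif set (default `AATAAA` only;
#' variant hexamers such as `ATTAAA` are opt-in), in ascending position
#' order. Overlapping occurrences are reported.
#'
#' @param seq A DNA string or [seq_record] (typically a retained intron).
#' @param motifs Character vector of hexamer motifs.
#' @return A data frame with columns `motif`, `position` (1-based start).
#' @export
find_polya_signals <- function(seq, motifs = "AATAAA") {
  if (inherits(seq, "seq_record")) seq <- seq$residues
  if (any(nchar(motifs) != 6L)) stop("polyA motifs must be hexamers")
  seq <- toupper(seq)
  hits <- do.call(rbind, lapply(motifs, function(m) {
    mp <- Biostrings::matchPattern(m, Biostrings::DNAString(seq))
    if (length(mp) == 0) return(NULL)
    data.frame(motif = m, position = Biostrings::start(mp))
  }))
  if (is.null(hits))
    return(data.frame(motif = character(0), position = integer(0)))
  hits[order(hits$position), , drop = FALSE]
}

#' Trim a trailing oligo(dA) run from a sequence
#'
#' The qualifying run is the longest suffix beginning with `A` that
#' contains at most `max_interruptions` non-`A` bases; runs shorter than
#' `min_run` are not trimmed.
#'
#' @param x DNA string.
#' @param min_run Minimum qualifying run length (default 8).
#' @param max_interruptions Maximum non-`A` bases inside the run (default 1).
#' @return A list with `trimmed` (string without the tail) and
#'   `tail_length`.
#' @keywords internal
trim_polya_tail <- function(x, min_run = 8L, max_interruptions = 1L) {
  tl <- measure_polya_tail(x, min_run = min_run,
                           max_interruptions = max_interruptions)
  list(trimmed = substr(x, 1, nchar(x) - tl), tail_length = tl)
}

#' EST support for transcription through an intron
#'
#' Trims a trailing oligo(dA) run from the EST (evidence of the polyA tail
#' added at the cleavage site), locally aligns the remainder against the
#' intron, and reports the covered intron interval together with a
#' transcription-termination-site (TTS) call at its 3' end. An alignment
#' scoring below `min_score` yields a no-support result rather than an
#' error.
#'
#' @param est A [seq_record] (EST / cDNA read).
#' @param intron A [seq_record] (retained intron, intron-relative
#'   coordinates).
#' @param params [align_params()] for the local alignment.
#' @param min_score Minimum alignment score for support (default 50, i.e.
#'   roughly ten matched bases under default scoring).
#' @param min_tail_run,max_tail_interruptions Oligo(dA) trimming
#'   parameters (defaults 8 and 1).
#' @return A list with `supported`, `covered` (`c(start, end)` on the
#'   intron), `tts` (list: `intron_relative_position`, `evidence`,
#'   `supporting_est_id`), `tail_trimmed`, and the `alignment`.
#' @export
est_support <- function(est, intron, params = align_params(mode = "local"),
                        min_score = 50, min_tail_run = 8L,
                        max_tail_interruptions = 1L) {
  stopifnot(inherits(est, "seq_record"), inherits(intron, "seq_record"))
  tr <- trim_polya_tail(est$residues, min_tail_run, max_tail_interruptions)
  if (!nzchar(tr$trimmed))
    return(list(supported = FALSE, covered = NULL, tts = NULL,
                tail_trimmed = tr$tail_length, alignment = NULL))
  if (params$mode != "local") params$mode <- "local"
  aln <- align(seq_record(est$id, tr$trimmed, type = "dna"), intron, params)
  if (aln$score < min_score)
    return(list(supported = FALSE, covered = NULL, tts = NULL,
                tail_trimmed = tr$tail_length, alignment = aln))
  covered <- aln$b_range
  list(supported = TRUE, covered = covered,
       tts = list(intron_relative_position = covered[2], evidence = "est",
                  supporting_est_id = est$id),
       tail_trimmed = tr$tail_length, alignment = aln)
}

#' Signal-only TTS window
#'
#' Without EST evidence the termination site cannot be pinpointed; the call
#' is reported as an interval downstream of the signal end. The window
#' width is a configuration choice, not a cleavage model.
#'
#' @param signal_position 1-based start of the polyA hexamer.
#' @param window Window width in nt (default 40).
#' @return A list with `interval` and `evidence = "signal-only"`.
#' @export
tts_signal_window <- function(signal_position, window = 40L) {
  end6 <- signal_position + 5L
  list(interval = c(end6, end6 + window), evidence = "signal-only")
}

#' Summarize the 3' region of a type II transcript
#'
#' Distances between the premature stop codon, the polyA signal, and the
#' TTS, all in intron-relative coordinates. Distances are reported as
#' simple differences of the given positions; a feature ordering other
#' than stop < signal < TTS is flagged `atypical_ordering` rather than
#' raising an error.
#'
#' @param stop_position Intron-relative stop-codon position.
#' @param signal_position Intron-relative polyA-signal start.
#' @param tts_position Intron-relative TTS.
#' @return A list with `stop_to_signal`, `signal_to_tts`,
#'   `predicted_3utr_length` (stop to TTS) and `atypical_ordering`.
#' @export
characterize_3prime_region <- function(stop_position, signal_position,
                                       tts_position) {
  d1 <- signal_position - stop_position
  d2 <- tts_position - signal_position
  list(stop_to_signal = d1, signal_to_tts = d2,
       predicted_3utr_length = tts_position - stop_position,
       atypical_ordering = (d1 < 0 || d2 < 0))
}

#' Export polyA signals and TTS calls as BED
#'
#' BED is 0-based half-open; intron-relative features can be lifted to
#' genomic coordinates through a retained `transcript_build`.
#'
#' @param signals Data frame from [find_polya_signals()] (intron-relative).
#' @param tts Optional TTS call list (with `intron_relative_position`).
#' @param path Output BED path.
#' @param build Optional retained `transcript_build` for genomic
#'   projection; when supplied, genomic records are appended.
#' @param chrom_label Name used for the intron-relative coordinate system.
#' @return Invisibly, the BED data frame.
#' @export
export_polya_bed <- function(signals, tts = NULL, path, build = NULL,
                             chrom_label = "intron") {
  rows <- list()
  if (nrow(signals) > 0) {
    rows[[length(rows) + 1]] <- data.frame(
      chrom = chrom_label, start = signals$position - 1L,
      end = signals$position + 5L,
      name = paste0("polyA_", signals$motif))
  }
  if (!is.null(tts)) {
    p <- tts$intron_relative_position
    rows[[length(rows) + 1]] <- data.frame(
      chrom = chrom_label, start = p - 1L, end = p,
      name = paste0("TTS_", tts$evidence))
  }
  if (!is.null(build)) {
    seg <- retained_segment(build)
    lift <- function(df) {
      g1 <- map_transcript_to_genomic(build, seg$t_start + df$start)
      g2 <- map_transcript_to_genomic(build, seg$t_start + df$end - 1L)
      data.frame(chrom = build$chrom, start = pmin(g1, g2) - 1,
                 end = pmax(g1, g2), name = paste0(df$name, "_genomic"))
    }
    rows <- c(rows, lapply(rows, lift))
  }
  bed <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(bed)
}
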