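#' Translate DNA in a fixed frame
#'
#' Standard nuclear genetic code. Stop codons are rendered `*`; any codon
#' containing `N` (or another ambiguity code) is rendered `X` and never
#' treated as a stop — a conservative choice for ambiguous genome bases.
#' Trailing bases short of a full codon are ignored.
#'
#' @param dna A DNA string (or [seq_record]).
#' @param frame_offset 0, 1 or 2: number of bases skipped before the first
#'   codon.
#' @return The amino-acid string (possibly empty).
#' @export
translate_dna <- function(dna, frame_offset = 0L) {
  if (inherits(dna, "seq_record")) dna <- dna$residues
  stopifnot(frame_offset %in% 0:2)
  dna <- toupper(dna)
  n <- nchar(dna) - frame_offset
  k <- n %/% 3
  if (is.na(k) || k <= 0) return("")
  starts <- frame_offset + seq(1, by = 3, length.out = k)
  codons <- substring(dna, starts, starts + 2)
  aa <- GENETIC_CODE_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# codon -> single-letter amino acid, '*' for stops (built from Biostrings)
GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' In-frame stop codon scan
#'
#' Reports the 1-based start positions of every stop codon (`TAA`, `TAG`,
#' `TGA`) lying in the reading frame given by `frame_offset`.
#'
#' @inheritParams translate_dna
#' @return Integer vector of codon-start positions, strictly increasing.
#' @export
scan_inframe_stops <- function(dna, frame_offset = 0L) {
  if (inherits(dna, "seq_record")) dna <- dna$residues
  stopifnot(frame_offset %in% 0:2)
  dna <- toupper(dna)
  k <- (nchar(dna) - frame_offset) %/% 3
  if (is.na(k) || k <= 0) return(integer(0))
  starts <- frame_offset + seq(1, by = 3, length.out = k)
  codons <- substring(dna, starts, starts + 2)
  as.integer(starts[codons %in% STOP_CODONS])
}

#' Predict the truncated protein of an intron-retained transcript
#'
#' Continues the reading frame from the frame anchor across the exon/intron
#' boundary into the retained intron and reports: the boundary-codon
#' composition (exonic vs intronic bases), the novel C-terminal peptide
#' (operationally, the residues encoded by codons containing at least one
#' intronic nucleotide, up to but excluding the stop), the stop codon and
#' its position, and the number of residues shared with the reference
#' protein before divergence.
#'
#' If no in-frame stop occurs before the transcript end, the report is
#' flagged `no_stop` and the peptide runs to the last complete codon.
#'
#' @param build A retained `transcript_build` (see
#'   [build_intron_retained()]).
#' @param frame_anchor 1-based transcript position of a known codon start,
#'   upstream of the retained intron. Defaults to the gene model's
#'   `cds_start_in_transcript`.
#' @return An object of class `truncation_report`.
#' @export
predict_truncation <- function(build, frame_anchor = build$frame_anchor) {
  seg <- retained_segment(build)
  is_ <- seg$t_start; ie_ <- seg$t_end
  if (frame_anchor < 1 || frame_anchor >= is_)
    stop("frame anchor ", frame_anchor,
         " must lie upstream of the retained segment (starts at ", is_, ")")
  L <- nchar(build$sequence)
  # first codon start overlapping the retained segment
  n_before <- (is_ - frame_anchor) %/% 3 # codons fully or partly exonic before boundary codon
  first_c <- frame_anchor + 3 * n_before
  if (first_c + 2 < is_) first_c <- first_c + 3
  n_exonic <- max(0L, is_ - first_c)
  boundary <- if (n_exonic == 0L) NULL else
    c(n_exonic_nt = as.integer(n_exonic), n_intronic_nt = as.integer(3 - n_exonic))
  shared_prefix <- (is_ - frame_anchor) %/% 3

  starts <- seq.int(first_c, L - 2, by = 3)
  if (first_c > L - 2) starts <- integer(0)
  codons <- substring(build$sequence, starts, starts + 2)
  aa <- unname(GENETIC_CODE_TABLE[codons])
  aa[is.na(aa)] <- "X"
  has_n <- grepl("[^ACGT]", codons)
  is_stop <- (aa == "*") & !has_n
  aa[has_n] <- "X"
  stop_i <- unname(which(is_stop)[1])
  no_stop <- is.na(stop_i)
  if (no_stop) {
    novel <- paste(aa, collapse = "")
    stop_codon <- NULL
  } else {
    novel <- if (stop_i > 1) paste(aa[seq_len(stop_i - 1)], collapse = "") else ""
    sp <- starts[stop_i]
    stop_codon <- list(triplet = codons[stop_i],
                       transcript_position = sp,
                       intron_relative_position = sp - is_ + 1)
  }
  structure(list(
    gene_id = build$gene_id,
    frame_anchor = frame_anchor,
    boundary_codon = boundary,
    novel_peptide = novel,
    novel_length = nchar(novel),
    stop_codon = stop_codon,
    no_stop = no_stop,
    shared_prefix_length = shared_prefix,
    retained_intron = build$retained_intron,
    intron_t_start = is_, intron_t_end = ie_),
    class = "truncation_report")
}

#' @export
print.truncation_report <- function(x, ...) {
  cat(sprintf("truncation_report for '%s' (intron %s retained)\n", x$gene_id,
              x$retained_intron))
  if (is.null(x$boundary_codon))
    cat("  exon ends on a codon boundary\n")
  else
    cat(sprintf("  boundary codon: %d exonic + %d intronic nt\n",
                x$boundary_codon[1], x$boundary_codon[2]))
  cat(sprintf("  shared prefix: %d aa; novel C-terminal: %d aa%s\n",
              x$shared_prefix_length, x$novel_length,
              if (x$no_stop) " (no stop before transcript end)" else ""))
  if (x$novel_length > 0) cat("  novel peptide: ", x$novel_peptide, "\n", sep = "")
  if (!is.null(x$stop_codon))
    cat(sprintf("  stop codon %s at transcript %d (intron-relative %d)\n",
                x$stop_codon$triplet, x$stop_codon$transcript_position,
                x$stop_codon$intron_relative_position))
  invisible(x)
}

#' Full predicted protein of a build
#'
#' Translation from the frame anchor to the first in-frame stop (exclusive)
#' or transcript end.
#'
#' @param build A `transcript_build`.
#' @param frame_anchor Codon-start transcript position.
#' @return Amino-acid string.
#' @export
predict_protein <- function(build, frame_anchor = build$frame_anchor) {
  aa <- translate_dna(substr(build$sequence, frame_anchor,
                             nchar(build$sequence)), 0L)
  sub("\\*.*$", "", aa)
}

#' Compare a predicted C-terminal tail against a motif
#'
#' Deterministic best local alignment (see [align()]) between the novel
#' C-terminal region and a user-supplied motif (e.g. a TIR-domain "Box 1"
#' segment). An empty tail yields an empty alignment with score 0.
#'
#' @param predicted Amino-acid string (the novel tail).
#' @param motif Non-empty amino-acid motif.
#' @param params [align_params()]; defaults to local protein scoring
#'   (match +5 / mismatch -4).
#' @return A `pairwise_alignment` (local), or a zero-score empty alignment
#'   when `predicted` is empty.
#' @export
compare_cterminal <- function(predicted, motif,
                              params = align_params(mode = "local")) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (!nzchar(predicted)) {
    out <- structure(list(aligned_a = "", aligned_b = "", id_a = "tail",
                          id_b = "motif", score = 0, mode = "local",
                          a_range = c(1L, 0L), b_range = c(1L, 0L),
                          params = params), class = "pairwise_alignment")
    out$stats <- alignment_stats(out)
    return(out)
  }
  if (params$mode != "local") params$mode <- "local"
  align(seq_record("tail", predicted, type = "protein"),
        seq_record("motif", motif, type = "protein"), params)
}

#' Write a truncation report to JSON and FASTA
#'
#' The FASTA holds two records: the full predicted protein and the novel
#' peptide.
#'
#' @param report A `truncation_report`.
#' @param build The `transcript_build` the report was computed from.
#' @param json_path,fasta_path Output paths (`NULL` to skip either).
#' @return Invisibly, `report`.
#' @export
write_truncation_report <- function(report, build, json_path = NULL,
                                    fasta_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
  }
  if (!is.null(fasta_path)) {
    prot <- predict_protein(build, report$frame_anchor)
    recs <- list(seq_record(paste0(report$gene_id, "_predicted_protein"),
                            prot, type = "protein"))
    if (report$novel_length > 0)
      recs <- c(recs, list(seq_record(paste0(report$gene_id, "_novel_peptide"),
                                      report$novel_peptide, type = "protein")))
    write_fasta(recs, fasta_path)
  }
  invisible(report)
}
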