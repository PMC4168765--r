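#' Transcript builds
#'
#' A `transcript_build` is a spliced ("type I") or intron-retained
#' ("type II") transcript sequence together with an exact bidirectional
#' transcript/genomic segment map. Segments are contiguous on the
#' transcript, start at position 1, and carry labels `exon_i` or `intron_k`.
#' On the minus strand, genomic coordinates within a segment run backwards
#' (the map stores `g_start > g_end` never; instead strand is recorded and
#' position arithmetic is strand-aware).
#'
#' @name transcript_build
#' @rdname transcript_build
NULL

lookup_genome <- function(genome, chrom) {
  if (inherits(genome, "seq_record")) {
    if (genome$id != chrom)
      stop("genome record id '", genome$id, "' does not match chrom '", chrom, "'")
    return(genome)
  }
  if (is.list(genome)) {
    if (!chrom %in% names(genome)) stop("chrom '", chrom, "' not in genome")
    return(genome[[chrom]])
  }
  stop("genome must be a seq_record or named list of seq_records")
}

segment_seq <- function(genome_rec, start, end, strand) {
  s <- record_slice(genome_rec, start, end)
  if (strand == "-") revcomp(s) else s
}

new_build <- function(variant, sequence, segments, gene) {
  stopifnot(sum(segments$t_end - segments$t_start + 1) == nchar(sequence))
  structure(list(variant = variant, sequence = sequence, segments = segments,
                 gene_id = gene$gene_id, chrom = gene$chrom,
                 strand = gene$strand,
                 frame_anchor = gene$cds_start_in_transcript),
            class = "transcript_build")
}

#' @export
print.transcript_build <- function(x, ...) {
  cat(sprintf("transcript_build '%s' [%s], %d nt, %d segment(s) on %s(%s)\n",
              x$gene_id, x$variant, nchar(x$sequence), nrow(x$segments),
              x$chrom, x$strand))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Build the spliced (type I) transcript
#'
#' Concatenates exon sequences in transcript orientation
#' (reverse-complemented for minus-strand genes).
#'
#' @param gene A [gene_model].
#' @param genome A [seq_record] (or named list of them) covering the gene's
#'   coordinates; records may carry an `offset` when they are chromosome
#'   slices.
#' @return A `transcript_build` with `variant = "spliced"`.
#' @export
build_spliced <- function(gene, genome) {
  rec <- lookup_genome(genome, gene$chrom)
  n <- nrow(gene$exons)
  seqs <- character(n)
  segs <- vector("list", n)
  t0 <- 0
  for (i in seq_len(n)) {
    e <- gene$exons[i, ]
    seqs[i] <- segment_seq(rec, e$start, e$end, gene$strand)
    w <- e$end - e$start + 1
    segs[[i]] <- data.frame(t_start = t0 + 1, t_end = t0 + w,
                            chrom = gene$chrom, g_start = e$start,
                            g_end = e$end, label = paste0("exon_", i))
    t0 <- t0 + w
  }
  new_build("spliced", paste(seqs, collapse = ""), do.call(rbind, segs), gene)
}

#' Build an intron-retained (type II) transcript
#'
#' The transcript consists of exons `1..k`, intron `k`, then exons
#' `k+1..n`, all in transcript orientation. The retained segment's genomic
#' interval is exactly the inter-exon gap.
#'
#' @param gene A [gene_model].
#' @param genome Genome lookup as in [build_spliced()].
#' @param intron_index Index `k` of the intron to retain
#'   (`1 <= k <= n_exons - 1`).
#' @return A `transcript_build` with `variant = "retained"` and a
#'   `retained_intron` element.
#' @export
build_intron_retained <- function(gene, genome, intron_index) {
  n <- nrow(gene$exons)
  k <- intron_index
  if (k < 1 || k > n - 1)
    stop("intron index ", k, " out of range [1, ", n - 1, "]")
  rec <- lookup_genome(genome, gene$chrom)
  iv <- intron_interval(gene, k)
  pieces <- character(0)
  segs <- list()
  t0 <- 0
  add <- function(gs, ge, label) {
    s <- segment_seq(rec, gs, ge, gene$strand)
    segs[[length(segs) + 1]] <<- data.frame(
      t_start = t0 + 1, t_end = t0 + nchar(s), chrom = gene$chrom,
      g_start = gs, g_end = ge, label = label)
    t0 <<- t0 + nchar(s)
    pieces[length(pieces) + 1] <<- s
  }
  for (i in seq_len(k)) add(gene$exons$start[i], gene$exons$end[i],
                            paste0("exon_", i))
  add(iv$start, iv$end, paste0("intron_", k))
  for (i in (k + 1):n) add(gene$exons$start[i], gene$exons$end[i],
                           paste0("exon_", i))
  b <- new_build("retained", paste(pieces, collapse = ""), do.call(rbind, segs),
                 gene)
  b$retained_intron <- k
  b
}

retained_segment <- function(build) {
  seg <- build$segments[grepl("^intron_", build$segments$label), , drop = FALSE]
  if (nrow(seg) == 0) stop("build has no retained intron segment")
  seg[1, ]
}

#' Map transcript positions to genomic coordinates
#'
#' Vectorized; inverse of [map_genomic_to_transcript()] and monotone within
#' each segment (increasing on `+`, decreasing on `-`).
#'
#' @param build A `transcript_build`.
#' @param pos 1-based transcript position(s).
#' @return Numeric vector of genomic coordinates.
#' @export
map_transcript_to_genomic <- function(build, pos) {
  L <- nchar(build$sequence)
  if (any(pos < 1 | pos > L))
    stop("transcript position out of range [1, ", L, "]")
  segs <- build$segments
  idx <- findInterval(pos, segs$t_start)
  off <- pos - segs$t_start[idx]
  if (build$strand == "+") segs$g_start[idx] + off else segs$g_end[idx] - off
}

#' Map genomic coordinates to transcript positions
#'
#' Vectorized. Positions not covered by any segment are an error.
#'
#' @param build A `transcript_build`.
#' @param gpos Genomic coordinate(s).
#' @return Numeric vector of 1-based transcript positions.
#' @export
map_genomic_to_transcript <- function(build, gpos) {
  segs <- build$segments
  out <- vapply(gpos, function(g) {
    hit <- which(segs$g_start <= g & segs$g_end >= g)
    if (length(hit) == 0)
      stop("genomic position ", format(g, big.mark = ","),
           " not covered by any transcript segment")
    i <- hit[1]
    if (build$strand == "+") segs$t_start[i] + (g - segs$g_start[i])
    else segs$t_start[i] + (segs$g_end[i] - g)
  }, numeric(1))
  out
}

#' Export a transcript build
#'
#' Writes the sequence as FASTA and the segment map as a TSV
#' (`transcript_start`, `transcript_end`, `chrom`, `genomic_start`,
#' `genomic_end`, `label`).
#'
#' @param build A `transcript_build`.
#' @param fasta_path,map_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, `build`.
#' @export
export_build <- function(build, fasta_path = NULL, map_path = NULL) {
  if (!is.null(fasta_path)) {
    write_fasta(seq_record(paste0(build$gene_id, "_", build$variant),
                           build$sequence), fasta_path)
  }
  if (!is.null(map_path)) {
    m <- build$segments
    names(m) <- c("transcript_start", "transcript_end", "chrom",
                  "genomic_start", "genomic_end", "label")
    write.table(m, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(build)
}
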