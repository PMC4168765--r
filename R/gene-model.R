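#' Gene models
#'
#' A `gene_model` holds the exon structure of a gene: an ordered set of
#' genomic exon intervals (5'-to-3' in transcript orientation), the
#' chromosome and strand, and a frame anchor — the 1-based transcript
#' position known to be the first base of a codon. The anchor, rather than
#' GFF phase fields, propagates the reading frame into a retained intron;
#' this matches how reference transcripts are typically anchored by a
#' printed (transcript position, protein residue) pair.
#'
#' Introns are indexed by the exon they follow: intron `k` lies between exon
#' `k` and exon `k + 1` (so "intron 8-9" is intron index 8).
#'
#' @param gene_id Gene/transcript identifier.
#' @param chrom Chromosome (must match a genome record id).
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end` (1-based inclusive
#'   genomic coordinates), ordered 5'-to-3' in transcript orientation
#'   (ascending genomic for `+`, descending for `-`).
#' @param cds_start_in_transcript 1-based transcript position of the first
#'   base of a codon (frame anchor). Default 1.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand = "+", exons,
                       cds_start_in_transcript = 1L) {
  strand <- match.arg(strand, c("+", "-"))
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            nrow(exons) >= 1, cds_start_in_transcript >= 1)
  exons <- data.frame(start = as.numeric(exons$start),
                      end = as.numeric(exons$end))
  if (any(exons$start > exons$end)) stop("exon start > end")
  g5 <- if (strand == "+") exons else exons[rev(seq_len(nrow(exons))), ]
  if (nrow(g5) > 1) {
    if (any(diff(g5$start) <= 0)) stop("exons out of transcript order for strand ", strand)
    if (any(g5$start[-1] - g5$end[-nrow(g5)] < 2))
      stop("exons overlap or are separated by < 1 nt of intron")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons,
                 cds_start_in_transcript = as.numeric(cds_start_in_transcript)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s' %s(%s): %d exon(s), frame anchor %d\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$cds_start_in_transcript))
  invisible(x)
}

exon_lengths <- function(gene) gene$exons$end - gene$exons$start + 1

#' Intron interval of a gene model
#'
#' @param gene A [gene_model].
#' @param k Intron index (intron `k` follows exon `k`).
#' @return A list with `start`, `end` (genomic, 1-based inclusive) and
#'   `length`.
#' @export
intron_interval <- function(gene, k) {
  n <- nrow(gene$exons)
  if (k < 1 || k > n - 1) stop("intron index ", k, " out of range [1, ", n - 1, "]")
  e1 <- gene$exons[k, ]; e2 <- gene$exons[k + 1, ]
  if (gene$strand == "+") {
    out <- list(start = e1$end + 1, end = e2$start - 1)
  } else {
    out <- list(start = e2$end + 1, end = e1$start - 1)
  }
  out$length <- out$end - out$start + 1
  out
}

#' Read gene models from GFF3
#'
#' Exon features are grouped by their `Parent` attribute; one `gene_model`
#' is returned per parent. Phase fields are ignored: frame anchoring is by
#' `cds_start_in_transcript`, supplied separately (default 1).
#'
#' @param path Path to a GFF3 file.
#' @param cds_start_in_transcript Frame anchor applied to every model
#'   (single value or named vector keyed by parent id).
#' @return A named list of [gene_model] objects.
#' @export
read_gene_models_gff3 <- function(path, cds_start_in_transcript = 1L) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0) stop("no exon features in ", path)
  parents <- vapply(as.list(ex$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  if (anyNA(parents)) stop("exon feature without Parent attribute in ", path)
  out <- lapply(split(seq_along(ex), parents), function(idx) {
    e <- ex[idx]
    strand <- as.character(GenomicRanges::strand(e))[1]
    if (strand == "*") strand <- "+"
    df <- data.frame(start = GenomicRanges::start(e), end = GenomicRanges::end(e))
    df <- df[order(df$start * ifelse(strand == "+", 1, -1)), ]
    pid <- parents[idx][1]
    anchor <- if (length(cds_start_in_transcript) > 1)
      cds_start_in_transcript[[pid]] else cds_start_in_transcript
    gene_model(pid, as.character(GenomicRanges::seqnames(e))[1], strand, df,
               anchor)
  })
  out
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and exon features (1-based inclusive, per the GFF3
#' standard) via rtracklayer.
#'
#' @param genes A [gene_model] or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  grs <- lapply(genes, function(g) {
    n <- nrow(g$exons)
    mrna_id <- paste0(g$gene_id, ".t1")
    GenomicRanges::GRanges(
      seqnames = g$chrom,
      ranges = IRanges::IRanges(
        start = c(min(g$exons$start), min(g$exons$start), g$exons$start),
        end = c(max(g$exons$end), max(g$exons$end), g$exons$end)),
      strand = g$strand,
      type = c("gene", "mRNA", rep("exon", n)),
      ID = c(g$gene_id, mrna_id, paste0(mrna_id, ".exon", seq_len(n))),
      Parent = c(NA, g$gene_id, rep(mrna_id, n)))
  })
  gr <- do.call(c, grs)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a 4-column exon TSV
#'
#' Columns: `gene_id`, `chrom`, `strand`, `start`, `end`; rows in transcript
#' order within each gene.
#'
#' @param path Path to the TSV.
#' @param cds_start_in_transcript Frame anchor (single value or named by
#'   gene id).
#' @return A named list of [gene_model] objects.
#' @export
read_exon_tsv <- function(path, cds_start_in_transcript = 1L) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(df)))
    stop("exon TSV must have columns: ", paste(req, collapse = ", "))
  lapply(split(df, df$gene_id), function(d) {
    anchor <- if (length(cds_start_in_transcript) > 1)
      cds_start_in_transcript[[d$gene_id[1]]] else cds_start_in_transcript
    gene_model(d$gene_id[1], d$chrom[1], d$strand[1],
               data.frame(start = d$start, end = d$end), anchor)
  })
}
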