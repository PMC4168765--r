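#' Packaged IL18R1 fixtures
#'
#' The package ships the sequences and coordinates that were published for
#' the human *IL18R1* type II (intron-8-9-retained) transcript: the 362-nt
#' expected-sequence query (the coding portion of the two exons upstream of
#' the boundary followed by the first 60 nt of intron 8-9), the primer
#' details table (sequences, binding coordinates and expected product
#' sizes for the human reference/type II pairs and the rat type II and
#' *Actb* controls), and the locus coordinate set (hg19).
#'
#' @return `il18r1_query()`: a [seq_record] of length 362.
#'   `il18r1_table1()`: a data frame of primer details.
#'   `il18r1_locus_coords()`: a named list of published coordinates.
#' @name il18r1_fixtures
NULL

extdata_path <- function(...) {
  system.file("extdata", ..., package = "intronret", mustWork = TRUE)
}

#' @rdname il18r1_fixtures
#' @export
il18r1_query <- function() {
  read_fasta(extdata_path("il18r1_type2_query.fasta"))[[1]]
}

#' @rdname il18r1_fixtures
#' @export
il18r1_table1 <- function() {
  read.delim(extdata_path("table1_primers.tsv"), stringsAsFactors = FALSE)
}

#' @rdname il18r1_fixtures
#' @export
il18r1_locus_coords <- function() {
  jsonlite::read_json(extdata_path("human_locus.json"), simplifyVector = TRUE)
}

#' Synthetic surrogate of the human IL18R1 type II locus
#'
#' The genuine hg19 chromosome 2 sequence is not shipped; instead this
#' function assembles, at run time, a synthetic locus slice on which every
#' published sequence is planted at its published coordinate:
#'
#' * a surrogate "exon A" of length 1135 standing for the spliced exons
#'   1-8 (so transcript coordinates match the reference transcript), with
#'   the 302 exonic nt of the 362-nt query as its 3' end and the forward
#'   primer site at transcript 545-568;
#' * intron 8-9 with the published genomic extent
#'   (chr2:103,006,678-103,010,928; 4,251 nt), whose first 60 nt are the
#'   query's intronic portion, whose nt 61-68 are synthetic codons chosen
#'   so the continued reading frame yields the reported 22-residue novel
#'   C-terminal followed by a stop, with the type II reverse-primer site
#'   planted at chr2:103,006,939-103,006,960 and an `AATAAA` signal planted
#'   (synthetically) at intron position 290, upstream of the reported
#'   357-nt termination point;
#' * a surrogate "exon B" carrying the reference reverse-primer site at
#'   transcript 1,209-1,231 of the spliced transcript.
#'
#' All remaining background is random (seeded). The slice is a
#' [seq_record] with `offset` set so genomic coordinates are genuine hg19
#' numbers. The frame anchor is transcript nt 1132 (the published codon
#' start of residue 370).
#'
#' @param seed Seed for the background sequence (default 42).
#' @return A list with `genome` (offset [seq_record] named `chr2`),
#'   `gene` ([gene_model] `IL18R1_surrogate`), `frame_anchor`, `primers`
#'   (named list of [primer]s: `forward`, `reverse_reference`,
#'   `reverse_typeII`), `est` (synthetic EST covering intron nt 1-357 with
#'   an oligo(dA) tail), and `coords` (see [il18r1_locus_coords()]).
#' @export
il18r1_surrogate <- function(seed = 42L) {
  co <- il18r1_locus_coords()
  query <- il18r1_query()$residues
  t1 <- il18r1_table1()
  prm <- function(nm) t1$sequence[t1$name == nm]
  exonA_len <- co$exon8_end_transcript              # 1135
  intron_len <- co$intron89_genomic_end - co$intron89_genomic_start + 1 # 4251
  exonB_len <- 200L
  offset <- co$intron89_genomic_start - exonA_len - 1 # genomic pos of base 0

  withr::with_seed(as.integer(seed), {
    ch <- strsplit(paste0(
      sample(c("A", "C", "G", "T"), exonA_len + intron_len + exonB_len,
             replace = TRUE), collapse = ""), "", fixed = TRUE)[[1]]
    plant <- function(at, s) {
      sch <- strsplit(s, "", fixed = TRUE)[[1]]
      ch[seq.int(at, at + length(sch) - 1L)] <<- sch
      invisible(NULL)
    }
    qe <- co$query_exonic_nt # 302
    plant(exonA_len - qe + 1L, substr(query, 1, qe))          # exon-8 3' end
    plant(exonA_len + 1L, substr(query, qe + 1L, nchar(query))) # intron nt 1-60
    # intron nt 61-68: two synthetic sense codons completing the reported
    # 22-residue novel peptide, then the stop codon at intron nt 66-68
    plant(exonA_len + 61L, "GCGGATAA")
    plant(co$forward_transcript_start, prm("hIL18R1_F"))
    plant(exonA_len + (co$typeII_reverse_genomic_start -
                       co$intron89_genomic_start + 1L),
          revcomp(prm("hIL18R1_typeII_R")))
    plant(exonA_len + intron_len +
            (co$reference_reverse_transcript_start - exonA_len),
          revcomp(prm("hIL18R1_R")))
    plant(exonA_len + 290L, "AATAAA") # synthetic signal placement
    # non-A bases at the TTS boundary so EST oligo(dA) trimming is exact
    for (pos in exonA_len + c(356L, 357L))
      if (ch[pos] == "A") ch[pos] <- sample(c("C", "G", "T"), 1)
    # scrub accidental AATAAA within the transcribed intron (nt 1..357)
    protected <- c(seq.int(exonA_len + 1L, exonA_len + 68L),
                   seq.int(exonA_len + 262L, exonA_len + 283L),
                   seq.int(exonA_len + 290L, exonA_len + 295L),
                   exonA_len + c(356L, 357L))
    repeat {
      intr357 <- paste(ch[seq.int(exonA_len + 1L, exonA_len + 357L)],
                       collapse = "")
      hits <- find_polya_signals(intr357)$position
      extra <- setdiff(hits, 290L)
      if (length(extra) == 0) break
      for (pp in extra) {
        cols <- setdiff(seq.int(exonA_len + pp, exonA_len + pp + 5L), protected)
        if (length(cols) == 0) next
        tgt <- cols[[1]]
        ch[tgt] <- sample(setdiff(c("C", "G"), ch[tgt]), 1)
      }
    }
    genome <- seq_record("chr2", paste(ch, collapse = ""),
                         description = "synthetic surrogate locus slice (hg19 coordinates)",
                         offset = offset)
    gene <- gene_model("IL18R1_surrogate", "chr2", "+",
                       data.frame(
                         start = c(offset + 1, co$intron89_genomic_end + 1),
                         end = c(co$intron89_genomic_start - 1,
                                 co$intron89_genomic_end + exonB_len)),
                       cds_start_in_transcript = co$frame_anchor_transcript)
    est <- seq_record("synthetic_EST_357",
                      paste0(paste(ch[seq.int(exonA_len + 1L, exonA_len + 357L)],
                                   collapse = ""), strrep("A", 20)),
                      description = "synthetic EST mirroring 357-nt intron coverage")
    list(genome = genome, gene = gene,
         frame_anchor = co$frame_anchor_transcript,
         primers = list(
           forward = primer("hIL18R1_F", prm("hIL18R1_F"), "forward"),
           reverse_reference = primer("hIL18R1_R", prm("hIL18R1_R"), "reverse"),
           reverse_typeII = primer("hIL18R1_typeII_R", prm("hIL18R1_typeII_R"),
                                   "reverse")),
         est = est, coords = co)
  })
}
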